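Package: pdcnet
Title: Directed EEG Source Connectivity, Graph Metrics and Classification for Stroke Rehabilitation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for source-level resting-state EEG
    connectivity studies of motor recovery after stroke. Generates seeded synthetic
    cohorts as stable multivariate autoregressive (MVAR) source networks over 28
    homotopic cortical regions, projects them to a 64-channel sensor montage,
    reconstructs sources with an LCMV beamformer, estimates frequency-banded
    directed connectivity with partial directed coherence (PDC), binarizes networks
    with orthogonal minimum spanning trees (OMST), computes node strength, degree,
    local efficiency and a hemispheric laterality index, runs normality-gated group
    statistics with effect sizes (including a Fugl-Meyer clinical summary and a
    two-way mixed ANOVA), and classifies cohorts from connectivity features with
    Relief selection and an RBF-SVM under leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    e1071,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
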