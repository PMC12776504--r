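---
title: "Directed source-level EEG connectivity for stroke rehabilitation cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed source-level EEG connectivity for stroke rehabilitation cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`pdcnet` implements a complete analysis chain for resting-state EEG studies of
motor recovery after stroke, together with a synthetic-cohort generator that
stands in for raw recordings:

1. **Simulation** — seeded cohorts (healthy controls, stroke pre- and
   post-intervention) as stable multivariate autoregressive (MVAR) source
   networks over 28 cortical regions, projected to a 64-channel montage with
   additive sensor noise.
2. **Preprocessing** — 1–50 Hz zero-phase band-pass, common-average
   reference, epoching into the canonical 28 × 2000 × 29 layout (4-second
   epochs at 500 Hz, 29 epochs), and hemisphere flipping so the affected
   hemisphere is always canonical-left.
3. **Source reconstruction** — LCMV beamforming with 5% diagonal loading.
4. **Connectivity** — partial directed coherence (PDC) from a pooled MVAR
   fit, averaged within the five canonical bands (delta, theta, alpha, beta,
   gamma).
5. **Network analysis** — orthogonal-minimum-spanning-tree (OMST)
   binarization, node strength / degree / local efficiency, and a laterality
   index over homotopic region pairs.
6. **Statistics** — Shapiro–Wilk-gated paired/unpaired tests with Cohen's d
   at a planned-comparison threshold of 0.01, a clinical score summary with a
   two-way mixed ANOVA, and a change–change correlation.
7. **Classification** — Relief-selected connectivity features into an
   RBF-SVM under leave-one-subject-out cross-validation with a nested 5-fold
   grid search.

This vignette records the model assumptions, the tunable parameters, and the
design decisions taken where the method left genuine freedom.

# The synthetic cohort generator

Raw clinical recordings are not distributed with the package, so all
quantitative guarantees are established on simulated cohorts with known
ground truth. The generator is first-class, tested code, and its defaults
define the study conditions: 22 subjects per group, 3-minute recordings at
500 Hz, 64 sensors, 10 dB sensor SNR, and an 11/11 left/right lesion split
that exercises hemisphere flipping.

## Source model

Each of the 14 base regions (in both hemispheres) carries a damped AR(2)
resonance with pole radius $\rho = 0.97$, centred in one of the five bands
(2.5, 6, 10.5, 21, 40 Hz, cycling over the base regions; homotopes share
their centre). Directed coupling between regions is a lag-1 MVAR coefficient.
Couplings follow a seeded acyclic rank order over base regions, mirrored
across hemispheres, so that

* the healthy-control template is hemisphere-symmetric to machine precision,
  and
* the companion-matrix spectral radius equals the pole radius regardless of
  coupling strength (an acyclic coupling graph cannot create feedback), so
  every template is stable by construction. Stability is still asserted
  numerically on every build.

Because PDC is defined through the MVAR coefficients, an edge's spectral
signature is inherited from its **source's** resonance: the PDC denominator
dips where the source's own dynamics resonate, so each edge concentrates in
the band of its source region. The ground-truth band of an edge is therefore
the band of its source.

Three choices deserve explanation, because naive variants fail in
instructive ways:

* **Innovation scaling.** Innovations are scaled so every region's own
  resonance has unit stationary variance. Without this, slow resonators
  carry orders of magnitude more variance than fast ones, and white sensor
  noise at any overall SNR buries the gamma-band sources completely.
* **Spectral compatibility of couplings.** A coupling from a source whose
  spectrum overlaps the target's resonance is amplified by the target's
  resonant gain; the driven component can then dominate the target and turn
  it into a near-copy of the source. Near-duplicate sources are (i) almost
  collinear, which makes MVAR estimation ill-conditioned, and (ii)
  correlated, which an LCMV beamformer partially cancels. The generator
  therefore couples only pairs whose driven-amplification factor (computed
  by spectral integration of the two resonator transfer functions) is at
  most 17.5.
* **Edge-weight calibration.** Each edge weight is scaled so that the driven
  variance it injects into the target is a fixed modest fraction
  (sd ≈ 0.35 of the target's unit own-variance, jittered ±20%). This keeps
  all edges simultaneously *separable* (sources stay weakly correlated) and
  *detectable* (weights stay well above the MVAR estimation error at the
  default data size, roughly 0.004).

Stroke effects are multiplicative ±40% changes on the outgoing couplings of
targeted regions — affected SMA and unaffected vPM down, affected INS and
dorsal area 6 up before the intervention; unaffected M1 and affected PoG up
after it — large enough for recovery at n = 22 but structurally incapable of
destabilizing the system. The six targeted regions are placed at the head of
the acyclic rank order so each always has outgoing edges to modulate.

## What the generator does *not* emulate

Real EEG features deliberately out of scope: 1/f background spectra and
cross-frequency coupling, non-Gaussian and nonstationary dynamics, ocular and
myogenic artifacts, volume-conduction geometry from a head model (the lead
field is a random unit-norm mixing matrix), and spatially correlated sensor
noise. Passing tests therefore demonstrate the correctness and calibration
of the *pipeline*, not performance claims about clinical recordings.

# Preprocessing decisions

* **Filters** are 4th-order Butterworth per pass, applied forward-backward
  (zero phase). The band-pass is a cascade of a high-pass and a low-pass,
  which is numerically safer near DC than a single narrow band-pass design.
* **Delta band**: the canonical definition starts at 0.1 Hz, but the
  broadband front-end already removed content below 1 Hz, so delta is
  filtered as 1–4 Hz.
* **Epoch selection**: a 3-minute recording yields 45 candidate epochs and
  29 are retained. The default keeps the first 29; a seeded random subset is
  available (`selection = "random"`), since nothing in the method constrains
  which epochs are kept.
* **Flip convention**: the canonical affected hemisphere is the LEFT one;
  right-lesion subjects have each region's data swapped with its homotope.

# Beamforming

The LCMV filter for source $j$ with lead-field column $l_j$ is
$w_j = (l_j^\top C_\varepsilon^{-1} l_j)^{-1} l_j^\top C_\varepsilon^{-1}$
with $C_\varepsilon = C + \varepsilon\,\overline{\mathrm{diag}(C)}\, I$ and
$\varepsilon = 0.05$ — the regularization scale is the mean of the
covariance diagonal, the common convention behind the "5%" phrasing. The
covariance is pooled over the whole recording. The beamformer is scalar
(one orientation per region) because the synthetic lead field has one column
per region. Because the data is re-referenced to the common average, the
lead field is projected into the same average-referenced space before the
filters are computed; omitting this breaks the unit-gain constraint in the
recording's actual sensor space.

Known limitation, inherited from LCMV itself: strongly correlated sources
partially cancel. The localization-fidelity guarantee (reconstruction
correlation ≥ 0.99 noiselessly) is therefore stated for uncoupled sources;
the generator's calibration keeps realistic cohorts far from the
pathological regime.

# PDC estimation

One MVAR model is fitted per subject on the broadband epochs, pooling
least-squares regressions across epochs without crossing epoch boundaries
(segments enter as separate regression blocks). The fit uses a QR
factorization of the design matrix; the normal equations are avoided
deliberately — near-resonant dynamics make the design's Gram matrix
numerically singular even when the regression itself is well posed. An
estimated condition number beyond 1e12 is an error.

From the coefficients, $\bar{A}(f) = I - \sum_r A_r e^{-i 2 \pi f r / f_s}$
and
$\pi_{ij}(f) = |\bar{A}_{ij}(f)| \big/ \sqrt{\sum_k |\bar{A}_{kj}(f)|^2}$,
evaluated on a 0.5 Hz grid from 1 to 50 Hz (at least six points in the
narrowest band). Entry $(i, j)$ is flow from $j$ to $i$; each source column
satisfies $\sum_i \pi_{ij}^2(f) = 1$ identically.

Open choices, fixed as follows and exposed in the interface:

* **Magnitude vs squared PDC** in band averages: magnitude by default,
  squared via `squared = TRUE`.
* **Pooled vs per-epoch estimation**: pooled, since the canonical
  28 × 2000 × 29 array feeds a single estimate and pooling stabilizes
  28-dimensional fits.
* **Model order**: BIC over candidates 2–10, ties to the smallest order.
  To bound the selection cost, the criterion is evaluated on the first six
  epochs and the final model is refitted on all epochs; at the default data
  size the criterion is insensitive to this subsampling.

# OMST binarization

The cited OMST construction is defined for undirected graphs, so the
directed PDC matrix is symmetrized by the mean of the two directions for
tree extraction, and direction is restored afterwards: a directed edge
survives iff its undirected edge was selected and its directed weight is
positive. Successive MSTs (distances $1/w$) are extracted, each excluding
all previously selected edges; after each round the aggregated selection is
scored by the global cost-efficiency $J = E_{glob}/E_{glob}^{full} - cost$,
and the aggregation maximizing $J$ is kept. Rounds stop at $R-1$, when the
residual graph disconnects, or after three consecutive declines of $J$.

Graph metrics are computed on the OMST-masked weighted matrix (strength,
local efficiency) and on its boolean support (degree); the weighted choice
for local efficiency is a documented decision — the method's description
("binarized maps and graph measures") does not fix it, and both variants are
reachable through the mask argument.

# Laterality and group statistics

The laterality index per homotopic pair is
$LI = (U - A)/(U + A)$ on outward (column-sum) strength of the OMST-masked
weighted matrix, with the affected hemisphere canonical-left; $U + A = 0$ is
flagged undefined rather than forced to zero. Group-level lateralization is
a one-sample test of mean LI against zero at 0.05, t or signed-rank per the
Shapiro–Wilk gate; a zero-variance sample is degenerate and is declared
significant exactly when its common value is non-zero.

All group contrasts use the same gate (parametric iff Shapiro–Wilk
$p \ge 0.05$), two-sided tests, and Cohen's d (paired:
$\bar{d}/s_d$; unpaired: pooled-SD). The 0.01 declaration threshold for
connectivity contrasts implements the planned-comparison correction as a
fixed threshold, exactly as operationalized in the study design; no
per-family recomputation is performed. Under the nonparametric branch the
effect size is still reported as Cohen's d on raw values, flagged in the
output. The change–change correlation is Pearson by default (Spearman by
option). The mixed ANOVA is the standard split-plot decomposition via
`aov(score ~ group * time + Error(subject))`.

# Classification

Features are the 756 off-diagonal directed edges of one band's matrix,
row-major. The leakage rules are strict: z-scoring is fitted on training
folds only; Relief re-ranks features inside every inner training split; and
the outer loop holds out whole *subjects*, so in the pre-vs-post comparison
both sessions of the held-out subject leave together — holding out single
recordings would leak subject identity, and nothing in the method's
description rules that variant out, so the leakage-safe variant is the
default and `sample_wise = TRUE` exposes the other for comparison.

Grids: cost {0.1, 1, 10}, kernel scale {auto, 1, 0.1, 0.01} with the
Gaussian kernel $\exp(-\|u-v\|^2/s^2)$ and "auto" meaning
$1/s^2 = 1/(d \cdot \overline{\mathrm{Var}})$, and — because the number of
Relief-selected features is otherwise unspecified — the feature count
{20, 50, 100} is searched in the same inner CV, keeping the choice
data-driven and leakage-safe. ReliefF uses 3 neighbours (the original k = 1
is noise-sensitive). AUC is computed from decision values by the rank
statistic. Inner folds are stratified and seeded.

Grid selection uses a one-standard-error rule anchored at the canonical
configuration (C = 1, kernel scale auto, smallest feature count — the
combination this class of analyses reports selecting): the anchor is kept
unless some other combination beats it by more than one standard error of
the best combination's inner accuracy. A plain argmax is unstable in
exactly the situation where honesty matters most — under weak or absent
signal all combinations tie near chance and whichever wins by noise may be
degenerate: a very sharp kernel (scale 0.01) makes the Gram matrix
near-identity and a very small cost under-fits, and either way the SVM
collapses toward majority voting. Under leave-one-out, majority voting
*anti-predicts*, because the held-out subject is always the minority of its
own training fold, which drags a permutation null far below 50%. The
anchored rule keeps the null behaviour near chance while losing nothing
when real signal is present (the anchor then ties with the best and is
kept).

# Numerical and degenerate-input conventions

* Zero-variance feature columns: centred, never divided.
* Constant samples in the normality gate: flagged degenerate; paired tests
  on identical inputs report d = 0, p = 1.
* PDC frequencies must lie strictly inside $(0, f_s/2)$; band averages use
  the half-open window $[low, high)$.
* Unreachable node pairs contribute zero efficiency ($1/\infty$).
* All randomness flows from explicit integer seeds; identical seeds yield
  bit-identical cohorts, fits and cross-validation splits.

# Problem sizes used in the shipped checks

The test-suite and acceptance script rerun the pipeline at the full study
width (22 subjects per group, 28 regions, 29 × 2000-sample epochs) for the
edge-recovery and classification checks, evaluating PDC on source-level
epochs where the claim under test concerns the estimator itself, and at
reduced sizes (2–6 subjects, shorter recordings) where the claim concerns
plumbing rather than statistics. Statistical calibrations use 10⁴ null
replicates for the 1% tests, 10³ for the 5% laterality test, and 2 × 10³
for the power comparison against the noncentral-t closed form.

# Known limitations

* On strongly separable cohorts, the permutation null of leave-one-out
  classification is biased *below* chance. The synthetic effects make the
  two groups near-perfect clusters in feature space; with labels permuted,
  Relief still surfaces the cluster-separating edges, the SVM's decision
  reduces to the majority permuted label within the test point's cluster,
  and leave-one-out turns near-even label splits into systematic
  anti-prediction. This below-chance behaviour of leave-one-out under the
  null is well documented for neuroimaging classifiers; the anchored
  selection rule removes the degenerate-kernel part of it but not the
  cluster-majority part, which is intrinsic to the design. Permutation
  nulls on weakly separable (real-world) features centre much closer to
  50%.

* The synthetic lead field carries no anatomy; depth bias, orientation
  handling and realistic channel covariance are untested here.
* LCMV cancellation of strongly correlated sources bounds how much coupling
  the generator can inject while remaining analyzable — a real property of
  the method, not only of the simulation.
* The OMST cost-efficiency curve can peak at a single tree on sparse PDC
  matrices; the selection trace is returned so users can audit the curve.
* Printed clinical inconsistencies in the source material (a t statistic
  inconsistent with its p-value and the underlying table; group-level mean
  changes that do not match the table's group labels) are resolved in favour
  of recomputation from the table; the affected printed values are not used
  as oracles.
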