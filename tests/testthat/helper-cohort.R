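# Shared source-level synthetic cohort, built once per test run and reused
# by the edge-recovery and classification tests.

.cohort_cache <- new.env(parent = emptyenv())

cohort_source_connectivity <- function(seed = 7, n_per_group = 22,
                                       conditions = c("HC", "stroke_pre")) {
  key <- paste(seed, n_per_group, paste(conditions, collapse = "+"))
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  set.seed(seed)
  template_seed <- sample.int(2^31 - 2, 1)
  sub_seeds <- matrix(sample.int(2^31 - 2, 3L * n_per_group), n_per_group)
  sides <- rep(c("left", "right"), length.out = n_per_group)
  cond_idx <- stats::setNames(1:3, c("HC", "stroke_pre", "stroke_post"))
  conn <- list(); truth <- list(); subject <- character(0)
  for (cond in conditions) {
    for (i in seq_len(n_per_group)) {
      side <- if (cond == "HC") "none" else sides[i]
      sid <- if (cond == "HC") sprintf("HC%02d", i) else sprintf("P%02d", i)
      sess <- switch(cond, HC = "single", stroke_pre = "pre", stroke_post = "post")
      tpl <- build_cohort_template(cond, side, seed = template_seed)
      x <- simulate_mvar(tpl, duration_s = 120, fs = 500,
                         seed = sub_seeds[i, cond_idx[[cond]]])
      ep <- segment_epochs(x, fs = 500, epoch_seconds = 4, n_epochs = 29,
                           meta = list(subject_id = sid, group = cond,
                                       session = sess, lesion_side = side))
      ep <- flip_hemispheres(ep, side)
      k <- paste(sid, sess, sep = "_")
      conn[[k]] <- subject_connectivity(ep)
      truth[[k]] <- tpl
      subject[k] <- sid
    }
  }
  res <- list(conn = conn, truth = truth, subject = subject,
              template_seed = template_seed)
  .cohort_cache[[key]] <- res
  res
}

# ground-truth edge indicator per band for a template, in the canonical
# (flipped) frame: templates are expressed in anatomical labels, so for
# right-lesion subjects the truth is flipped like the data
truth_band_matrices <- function(template, flip = FALSE) {
  atlas <- region_atlas()
  lab <- atlas$labels
  bands <- default_bands()$name
  out <- lapply(bands, function(b) {
    M <- matrix(FALSE, 28, 28, dimnames = list(lab, lab))
    e <- template$edges[template$edges$band == b, ]
    if (nrow(e))
      M[cbind(match(e$target, lab), match(e$source, lab))] <- TRUE
    if (flip) {
      perm <- atlas$homotope
      M <- M[perm, perm]
      dimnames(M) <- list(lab, lab)
    }
    M
  })
  names(out) <- bands
  out
}
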