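test_that("atlas has 28 unique labels forming a perfect homotopic matching", {
  atlas <- region_atlas()
  expect_length(atlas$labels, 28)
  expect_false(anyDuplicated(atlas$labels) > 0)
  expect_true(all(atlas$homotope[atlas$homotope] == seq_len(28)))
  expect_true(all(atlas$hemisphere != atlas$hemisphere[atlas$homotope]))
})

test_that("healthy-control template is exactly hemisphere-symmetric", {
  tpl <- build_cohort_template("HC", "none", seed = 1)
  mirror <- function(lbl) ifelse(grepl("_L$", lbl),
                                 sub("_L$", "_R", lbl), sub("_R$", "_L", lbl))
  e <- tpl$edges
  key <- paste(e$source, e$target)
  mkey <- paste(mirror(e$source), mirror(e$target))
  expect_setequal(key, mkey)
  w <- setNames(e$weight, key)
  expect_equal(unname(w[mkey]), e$weight)
})

test_that("stroke templates shift outgoing weight of the targeted regions", {
  hc <- build_cohort_template("HC", "none", seed = 1)
  pre <- build_cohort_template("stroke_pre", "left", seed = 1)
  post <- build_cohort_template("stroke_post", "left", seed = 1)
  out_w <- function(tpl, lbl) sum(tpl$edges$weight[tpl$edges$source == lbl])
  # affected (left) SMA outflow reduced pre-intervention; INS/dorsalA6 raised
  expect_lt(out_w(pre, "SMA_L"), out_w(hc, "SMA_L"))
  expect_lt(out_w(pre, "vPM_R"), out_w(hc, "vPM_R"))
  expect_gt(out_w(pre, "INS_L"), out_w(hc, "INS_L"))
  expect_gt(out_w(pre, "dorsalA6_L"), out_w(hc, "dorsalA6_L"))
  # post-intervention increases from unaffected M1 and affected PoG
  expect_gt(out_w(post, "PoG_L"), out_w(pre, "PoG_L"))
  expect_gt(out_w(post, "M1_R"), out_w(pre, "M1_R"))
  # right-lesion template mirrors the modifications
  pre_r <- build_cohort_template("stroke_pre", "right", seed = 1)
  expect_lt(out_w(pre_r, "SMA_R"), out_w(hc, "SMA_R"))
})

test_that("template validation rejects inconsistent condition / lesion pairs", {
  expect_error(build_cohort_template("HC", "left", seed = 1), "none")
  expect_error(build_cohort_template("stroke_pre", "none", seed = 1), "lesion_side")
  expect_error(build_cohort_template("recovered", "none", seed = 1))
})

test_that("every emitted template is stable (companion spectral radius < 1)", {
  for (s in 1:5) {
    for (spec in list(c("HC", "none"), c("stroke_pre", "left"),
                      c("stroke_post", "right"))) {
      tpl <- build_cohort_template(spec[1], spec[2], seed = s)
      expect_lt(mvar_spectral_radius(template_coefficients(tpl)), 1)
    }
  }
})

test_that("simulation is deterministic and decoupled regions stay uncorrelated", {
  tpl <- build_cohort_template("HC", "none", seed = 3)
  x1 <- simulate_mvar(tpl, duration_s = 20, fs = 500, seed = 9)
  x2 <- simulate_mvar(tpl, duration_s = 20, fs = 500, seed = 9)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(28, 10000))
  # zero cross-couplings: independent processes
  tpl0 <- tpl
  tpl0$edges <- tpl0$edges[0, ]
  x <- simulate_mvar(tpl0, duration_s = 120, fs = 500, seed = 5)
  cors <- cor(t(x[c(1, 5, 9, 20), ]))
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.05))
})

test_that("MVAR parameters are recoverable from simulated data", {
  # 2-region AR(2) with known coefficients, long series, compared against a
  # direct normal-equations solve as the independent estimator
  tpl <- build_cohort_template("HC", "none", seed = 2)
  x <- simulate_mvar(tpl, duration_s = 200, fs = 500, seed = 4)
  sub <- x[c("M1_L", "SMA_L"), ]
  truth <- template_coefficients(tpl)[c("M1_L", "SMA_L"), c("M1_L", "SMA_L"), ]
  est <- oracle_mvar_fit(sub, 5)
  # self-dynamics of a near-decoupled pair recovered within 0.05
  expect_lt(max(abs(est[1, 1, 1:2] - truth[1, 1, 1:2])), 0.05)
  expect_lt(max(abs(est[2, 2, 1:2] - truth[2, 2, 1:2])), 0.05)
})

test_that("lead fields are unit-norm, full rank and seed-dependent", {
  lf <- make_leadfield(64, seed = 7)
  expect_equal(dim(lf$gain), c(64, 28))
  expect_equal(qr(lf$gain)$rank, 28)
  expect_equal(colSums(lf$gain^2), rep(1, 28), tolerance = 1e-12)
  lf2 <- make_leadfield(64, seed = 8)
  expect_false(isTRUE(all.equal(lf$gain, lf2$gain)))
  expect_error(make_leadfield(20, seed = 1), ">=")
})

test_that("sensor projection honours the requested SNR", {
  tpl <- build_cohort_template("HC", "none", seed = 1)
  x <- simulate_mvar(tpl, duration_s = 30, fs = 500, seed = 2)
  lf <- make_leadfield(64, seed = 3)
  # noiseless: exact forward model
  rec <- project_to_sensors(x, lf, snr_db = Inf, seed = 1)
  expect_equal(rec$data, lf$gain %*% x)
  # 0 dB: empirical SNR within 0.5 dB
  rec0 <- project_to_sensors(x, lf, snr_db = 0, seed = 1)
  noise <- rec0$data - lf$gain %*% x
  snr_emp <- 10 * log10(mean((lf$gain %*% x)^2) / mean(noise^2))
  expect_lt(abs(snr_emp), 0.5)
  # zero sources: pure noise with unit variance
  recn <- project_to_sensors(matrix(0, 28, 5000), lf, snr_db = 10, seed = 1)
  expect_equal(stats::var(as.vector(recn$data)), 1, tolerance = 0.05)
})

test_that("cohort generation is deterministic with paired stroke sessions", {
  ch <- generate_cohort(3, c("stroke_pre", "stroke_post"), seed = 3,
                        duration_s = 10, n_sensors = 30)
  expect_length(ch$recordings, 6)
  pre_ids <- vapply(ch$recordings[grep("_pre$", names(ch$recordings))],
                    `[[`, "", "subject_id")
  post_ids <- vapply(ch$recordings[grep("_post$", names(ch$recordings))],
                     `[[`, "", "subject_id")
  expect_setequal(unname(pre_ids), unname(post_ids))
  sides <- vapply(ch$recordings, `[[`, "", "lesion_side")
  expect_setequal(unique(sides), c("left", "right"))
  ch_hc <- generate_cohort(3, "HC", seed = 3, duration_s = 10, n_sensors = 30)
  expect_true(all(vapply(ch_hc$recordings, `[[`, "", "lesion_side") == "none"))
  ch2 <- generate_cohort(3, c("stroke_pre", "stroke_post"), seed = 3,
                         duration_s = 10, n_sensors = 30)
  expect_identical(ch$recordings, ch2$recordings)
  expect_error(generate_cohort(3, character(0), seed = 1), "non-empty")
})
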