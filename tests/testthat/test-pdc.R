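ar2_epochs <- function(n_regions = 3, n_epochs = 29, spe = 2000, seed = 1) {
  # stable 3-region AR(2) with known coefficients
  A <- array(0, c(n_regions, n_regions, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[3, 3, 1] <- -0.2
  A[1, 1, 2] <- -0.3; A[2, 2, 2] <- 0.2; A[3, 3, 2] <- 0.1
  A[2, 1, 1] <- 0.4; A[3, 2, 1] <- 0.35; A[1, 3, 2] <- 0.25
  set.seed(seed)
  n <- n_epochs * spe + 500
  x <- matrix(0, n_regions, n)
  for (t in 3:n) x[, t] <- A[, , 1] %*% x[, t - 1] + A[, , 2] %*% x[, t - 2] + rnorm(n_regions)
  x <- x[, -(1:500)]
  rownames(x) <- paste0("R", seq_len(n_regions))
  list(epochs = array(x, c(n_regions, spe, n_epochs)), truth = A)
}

test_that("pooled least squares recovers known AR(2) coefficients", {
  sim <- ar2_epochs()
  fit <- fit_mvar(sim$epochs, order = 2)
  rmse <- sqrt(mean((fit$coefficients - sim$truth)^2))
  expect_lt(rmse, 0.02)
  expect_true(isSymmetric(fit$noise_covariance, tol = 1e-10))
  expect_lt(max(abs(fit$noise_covariance - diag(3))), 0.1)
  expect_error(fit_mvar(sim$epochs, order = 0), "order")
})

test_that("white noise yields near-zero cross-coefficients", {
  set.seed(2)
  ep <- array(rnorm(4 * 2000 * 20), c(4, 2000, 20))
  fit <- fit_mvar(ep, order = 2)
  off <- fit$coefficients
  for (r in 1:2) diag(off[, , r]) <- 0
  expect_lt(max(abs(off)), 0.02)
})

test_that("order selection finds the generating order and breaks ties downward", {
  sim <- ar2_epochs()
  sel <- select_order(sim$epochs, candidates = 1:8)
  expect_equal(sel$order, 2)
  expect_equal(nrow(sel$table), 8)
  expect_equal(select_order(sim$epochs, candidates = 3)$order, 3)
  set.seed(3)
  wn <- array(rnorm(3 * 1500 * 10), c(3, 1500, 10))
  expect_equal(select_order(wn, candidates = 1:5)$order, 1)
})

test_that("PDC of the identity model is diagonal at all frequencies", {
  model <- structure(list(order = 1L,
                          coefficients = array(0, c(3, 3, 1),
                                               dimnames = list(paste0("R", 1:3), paste0("R", 1:3), NULL)),
                          noise_covariance = diag(3), fs = 500,
                          n_samples_used = 1000, labels = paste0("R", 1:3)),
                     class = "mvar_model")
  map <- pdc_spectrum(model, freqs = c(2, 10, 40))
  for (k in 1:3) {
    expect_equal(unname(diag(map$values[, , k])), rep(1, 3), tolerance = 1e-12)
    off <- map$values[, , k]; diag(off) <- 0
    expect_true(all(off == 0))
  }
  expect_error(pdc_spectrum(model, numeric(0)), "empty")
  expect_error(pdc_spectrum(model, c(10, 300)), "fs/2")
})

test_that("PDC matches an independent direct-formula evaluation", {
  # 2-region model: flow only 1 -> 2; reverse direction identically zero
  A <- array(0, c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5; A[2, 1, 1] <- 0.4
  model <- structure(list(order = 1L, coefficients = A, noise_covariance = diag(2),
                          fs = 500, n_samples_used = 1000, labels = c("a", "b")),
                     class = "mvar_model")
  freqs <- seq(1, 249, by = 4)
  map <- pdc_spectrum(model, freqs)
  for (k in seq_along(freqs)) {
    expect_lt(max(abs(map$values[, , k] - oracle_pdc(A, freqs[k], 500))), 1e-10)
    expect_gt(map$values[2, 1, k], 0)       # 1 -> 2 present
    expect_equal(map$values[1, 2, k], 0)    # 2 -> 1 absent at every frequency
  }
  # random higher-order models against the same oracle
  set.seed(4)
  for (rep in 1:5) {
    Ar <- array(rnorm(2 * 2 * 3, sd = 0.2), c(2, 2, 3),
                dimnames = list(c("a", "b"), c("a", "b"), NULL))
    m2 <- structure(list(order = 3L, coefficients = Ar, noise_covariance = diag(2),
                         fs = 250, n_samples_used = 1000, labels = c("a", "b")),
                    class = "mvar_model")
    f <- runif(1, 1, 120)
    expect_lt(max(abs(pdc_spectrum(m2, f)$values[, , 1] - oracle_pdc(Ar, f, 250))), 1e-10)
  }
})

test_that("PDC columns are normalized for random stable models", {
  set.seed(5)
  for (rep in 1:20) {
    R <- sample(3:6, 1)
    repeat {
      Ar <- array(rnorm(R * R * 2, sd = 0.25), c(R, R, 2))
      if (mvar_spectral_radius(Ar) < 0.98) break
    }
    dimnames(Ar) <- list(paste0("R", 1:R), paste0("R", 1:R), NULL)
    m <- structure(list(order = 2L, coefficients = Ar, noise_covariance = diag(R),
                        fs = 500, n_samples_used = 1000, labels = paste0("R", 1:R)),
                   class = "mvar_model")
    map <- pdc_spectrum(m, freqs = c(3, 11, 27, 44))
    sq <- apply(map$values^2, c(2, 3), sum)
    expect_lt(max(abs(sq - 1)), 1e-8)
    expect_true(all(map$values >= 0 & map$values <= 1))
  }
})

test_that("permuting regions permutes the PDC map consistently", {
  sim <- ar2_epochs()
  fit <- fit_mvar(sim$epochs, order = 2, fs = 500)
  perm <- c(3, 1, 2)
  ep_p <- sim$epochs[perm, , ]
  fit_p <- fit_mvar(ep_p, order = 2, fs = 500)
  m1 <- pdc_spectrum(fit, freqs = c(5, 20))$values
  m2 <- pdc_spectrum(fit_p, freqs = c(5, 20))$values
  expect_equal(m2, m1[perm, perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("band averaging windows [low, high) and zeroes the diagonal", {
  sim <- ar2_epochs()
  fit <- fit_mvar(sim$epochs, order = 2, fs = 500)
  freqs <- seq(1, 50, by = 0.5)
  map <- pdc_spectrum(fit, freqs)
  cm <- band_average(map, "alpha")
  sel <- freqs >= 8 & freqs < 13
  manual <- apply(map$values[, , sel], c(1, 2), mean); diag(manual) <- 0
  expect_equal(unname(cm$weights), unname(manual))
  expect_true(all(diag(cm$weights) == 0))
  # constant-in-frequency map averages to that constant
  cm2 <- band_average(map, c(10, 10.5))
  expect_equal(unname(cm2$weights[2, 1]), unname(map$values[2, 1, freqs == 10]))
  expect_error(band_average(map, c(60, 70)), "no grid")
  expect_error(band_average(map, "ripple"), "unknown band")
})

test_that("subject connectivity returns one matrix per band, deterministically", {
  sim <- ar2_epochs()
  ep <- structure(list(data = sim$epochs, fs = 500,
                       region_labels = paste0("R", 1:3), band = "broadband",
                       meta = list(subject_id = "T")), class = "source_epochs")
  out1 <- subject_connectivity(ep, order = 2)
  out2 <- subject_connectivity(ep, order = 2)
  expect_named(out1, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_identical(lapply(out1, `[[`, "weights"), lapply(out2, `[[`, "weights"))
  expect_equal(out1$alpha$meta$order, 2)
})
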