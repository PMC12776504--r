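as_epoch_array <- function(source_epochs) {
  if (inherits(source_epochs, "source_epochs")) return(source_epochs$data)
  if (is.matrix(source_epochs)) return(array(source_epochs, c(dim(source_epochs), 1L)))
  if (length(dim(source_epochs)) == 3) return(source_epochs)
  stop("expected a source_epochs, a matrix, or a 3D array")
}

#' Fit a multivariate autoregressive model to epoched data
#'
#' Pooled least squares: each epoch contributes the regressions of samples
#' `p+1..T` on their `p` predecessors, and epochs are stacked without
#' crossing epoch boundaries. Solved by QR; an ill-conditioned design
#' (estimated condition number beyond `1/tol`) is an error that reports the
#' condition number. Each epoch is mean-centred per region before fitting.
#'
#' @param source_epochs a `source_epochs`, matrix (`regions x samples`), or
#'   3D array (`regions x samples x epochs`)
#' @param order MVAR lag order `p >= 1`
#' @param fs sampling rate in Hz (taken from `source_epochs` when available)
#' @param tol reciprocal condition number below which the fit fails
#' @return an `mvar_model`: list with `order`, `coefficients` (array
#'   `R x R x p`; entry `(i, j, r)` drives region `i` from region `j` at lag
#'   `r`), `noise_covariance`, `fs`, `n_samples_used`, `labels`, `logdet_sigma`
#' @export
fit_mvar <- function(source_epochs, order, fs = NULL, tol = 1e-12) {
  if (order < 1) stop("order must be >= 1")
  arr <- as_epoch_array(source_epochs)
  if (is.null(fs)) fs <- if (inherits(source_epochs, "source_epochs")) source_epochs$fs else 1
  labels <- if (inherits(source_epochs, "source_epochs")) source_epochs$region_labels else rownames(arr)
  R <- dim(arr)[1]; Tn <- dim(arr)[2]; E <- dim(arr)[3]
  if (is.null(labels)) labels <- paste0("R", seq_len(R))
  if (Tn <= order * R)
    stop("per-epoch samples (", Tn, ") must exceed order * regions (", order * R, ")")
  Xs <- vector("list", E); Ys <- vector("list", E)
  for (e in seq_len(E)) {
    S <- arr[, , e] - rowMeans(arr[, , e])
    Ys[[e]] <- t(S[, (order + 1):Tn, drop = FALSE])
    Xs[[e]] <- do.call(cbind, lapply(seq_len(order), function(r)
      t(S[, (order + 1 - r):(Tn - r), drop = FALSE])))
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  qx <- qr(X, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qx)))
  if (min(rdiag) / max(rdiag) < tol)
    stop("ill-conditioned MVAR regression: estimated condition number ",
         format(max(rdiag) / min(rdiag), digits = 3))
  B <- qr.coef(qx, Y)                       # (R*order) x R
  res <- Y - X %*% B
  n <- nrow(Y)
  Sigma <- crossprod(res) / (n - ncol(X))
  coefs <- array(0, c(R, R, order))
  for (r in seq_len(order))
    coefs[, , r] <- t(B[((r - 1) * R + 1):(r * R), , drop = FALSE])
  dimnames(coefs) <- list(labels, labels, NULL)
  sig_mle <- crossprod(res) / n
  model <- list(order = as.integer(order), coefficients = coefs,
                noise_covariance = Sigma, fs = fs, n_samples_used = n,
                labels = labels,
                logdet_sigma = as.numeric(determinant(sig_mle, logarithm = TRUE)$modulus))
  class(model) <- "mvar_model"
  rad <- mvar_spectral_radius(coefs)
  if (rad >= 1)
    warning("fitted MVAR is non-stationary (spectral radius ", signif(rad, 4), ")")
  model
}

#' @export
print.mvar_model <- function(x, ...) {
  cat("mvar_model: ", length(x$labels), " regions, order ", x$order,
      ", ", x$n_samples_used, " pooled samples\n", sep = "")
  invisible(x)
}

#' Select the MVAR order by information criterion
#'
#' Fits each candidate order and returns the one minimizing the criterion
#' (BIC by default; AIC available). Ties go to the smallest order, since
#' candidates are evaluated in ascending order.
#'
#' @param source_epochs input accepted by [fit_mvar()]
#' @param candidates integer vector of candidate orders
#' @param criterion `"bic"` (default) or `"aic"`
#' @return list with `order` (chosen) and `table` (data.frame of order,
#'   criterion value, log-determinant of the innovation covariance)
#' @export
select_order <- function(source_epochs, candidates = 2:10,
                         criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0) stop("candidates must be non-empty")
  candidates <- sort(unique(as.integer(candidates)))
  arr <- as_epoch_array(source_epochs)
  R <- dim(arr)[1]
  vals <- rep(NA_real_, length(candidates))
  lds <- rep(NA_real_, length(candidates))
  for (k in seq_along(candidates)) {
    p <- candidates[k]
    fit <- tryCatch(fit_mvar(source_epochs, p), error = function(e) NULL)
    if (is.null(fit)) next
    n <- fit$n_samples_used
    npar <- p * R^2
    lds[k] <- fit$logdet_sigma
    vals[k] <- n * fit$logdet_sigma +
      if (criterion == "bic") log(n) * npar else 2 * npar
  }
  if (all(is.na(vals))) stop("all candidate orders failed to fit")
  tab <- data.frame(order = candidates, criterion = vals, logdet_sigma = lds)
  list(order = candidates[which.min(vals)], table = tab)
}

#' Partial directed coherence spectrum of an MVAR model
#'
#' Evaluates `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)` and the PDC
#' `pi_ij(f) = |Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)` on a frequency
#' grid. Entry `(i, j)` quantifies directed flow from region `j` to region
#' `i`; each source column satisfies `sum_i pi_ij(f)^2 = 1` at every
#' frequency by construction.
#'
#' @param model an `mvar_model`
#' @param freqs evaluation frequencies in Hz, inside `(0, fs/2)`
#' @return a `pdc_map`: list with `values` (`R x R x F` array in `[0, 1]`),
#'   `freqs`, `fs`, `labels`
#' @export
pdc_spectrum <- function(model, freqs = seq(1, 50, by = 0.5)) {
  if (length(freqs) == 0) stop("empty frequency grid")
  if (any(freqs <= 0) || any(freqs >= model$fs / 2))
    stop("frequencies must lie strictly inside (0, fs/2)")
  R <- length(model$labels); p <- model$order
  vals <- array(NA_real_, c(R, R, length(freqs)),
                dimnames = list(model$labels, model$labels, NULL))
  for (k in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[k] * seq_len(p) / model$fs)
    Abar <- diag(R) + 0i
    for (r in seq_len(p)) Abar <- Abar - model$coefficients[, , r] * z[r]
    m <- Mod(Abar)
    vals[, , k] <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  }
  map <- list(values = vals, freqs = freqs, fs = model$fs, labels = model$labels)
  class(map) <- "pdc_map"
  map
}

#' Average a PDC map over a frequency band
#'
#' Means `|pi_ij(f)|` (or its square, with `squared = TRUE`) over grid
#' frequencies in `[low_hz, high_hz)` and zeroes the diagonal.
#'
#' @param pdc_map a `pdc_map`
#' @param band band name from [default_bands()], or a numeric `c(low, high)`,
#'   or a one-row data.frame with `name`, `low_hz`, `high_hz`
#' @param squared average squared PDC instead of magnitude PDC
#' @param meta optional metadata list carried on the result
#' @return a `connectivity_matrix`: list with `weights` (R x R, zero
#'   diagonal, entries in `[0, 1]`), `band`, `labels`, `meta`
#' @export
band_average <- function(pdc_map, band, squared = FALSE, meta = list()) {
  if (is.character(band)) {
    bd <- default_bands()
    row <- bd[bd$name == band, ]
    if (nrow(row) != 1) stop("unknown band name: ", band)
    nm <- band; lo <- row$low_hz; hi <- row$high_hz
  } else if (is.numeric(band) && length(band) == 2) {
    nm <- paste0(band[1], "-", band[2], "Hz"); lo <- band[1]; hi <- band[2]
  } else if (is.data.frame(band) && nrow(band) == 1) {
    nm <- band$name; lo <- band$low_hz; hi <- band$high_hz
  } else stop("band must be a name, c(low, high), or a one-row band table")
  sel <- pdc_map$freqs >= lo & pdc_map$freqs < hi
  if (!any(sel)) stop("band [", lo, ", ", hi, ") contains no grid frequencies")
  v <- pdc_map$values[, , sel, drop = FALSE]
  if (squared) v <- v^2
  W <- apply(v, c(1, 2), mean)
  diag(W) <- 0
  dimnames(W) <- list(pdc_map$labels, pdc_map$labels)
  cm <- list(weights = W, band = nm, labels = pdc_map$labels, meta = meta)
  class(cm) <- "connectivity_matrix"
  cm
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix [", x$band, "]: ", nrow(x$weights), " x ",
      ncol(x$weights), ", mean weight ",
      signif(mean(x$weights[row(x$weights) != col(x$weights)]), 3), "\n", sep = "")
  invisible(x)
}

#' Band-averaged PDC connectivity for one subject
#'
#' Composes order selection, the pooled MVAR fit, PDC evaluation and band
#' averaging: one directed connectivity matrix per requested band, all
#' derived from a single broadband model. With `order = "auto"` the order is
#' chosen by BIC over `order_candidates`; to bound the selection cost on
#' long recordings, the criterion is evaluated on the first
#' `order_select_epochs` epochs and the final model is fitted on all epochs.
#'
#' @param source_epochs a `source_epochs` in canonical layout
#' @param bands band table as in [default_bands()]
#' @param order `"auto"` or a fixed integer order
#' @param order_candidates candidate orders for `"auto"`
#' @param order_select_epochs epochs used during order selection
#' @param freqs PDC frequency grid in Hz
#' @param squared use squared PDC in the band averages
#' @return named list of `connectivity_matrix`, one per band, with the chosen
#'   order stored in each matrix's `meta$order`
#' @export
subject_connectivity <- function(source_epochs, bands = default_bands(),
                                 order = "auto", order_candidates = 2:10,
                                 order_select_epochs = 6,
                                 freqs = seq(1, 50, by = 0.5),
                                 squared = FALSE) {
  arr <- as_epoch_array(source_epochs)
  if (identical(order, "auto")) {
    sub <- source_epochs
    n_use <- min(order_select_epochs, dim(arr)[3])
    if (inherits(sub, "source_epochs")) {
      sub$data <- arr[, , seq_len(n_use), drop = FALSE]
    } else sub <- arr[, , seq_len(n_use), drop = FALSE]
    order <- select_order(sub, order_candidates)$order
  }
  model <- fit_mvar(source_epochs, order)
  map <- pdc_spectrum(model, freqs)
  meta <- if (inherits(source_epochs, "source_epochs")) source_epochs$meta else list()
  meta$order <- order
  out <- lapply(seq_len(nrow(bands)), function(b)
    band_average(map, bands[b, ], squared = squared, meta = meta))
  names(out) <- bands$name
  out
}
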