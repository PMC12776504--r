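#' Sensor covariance matrix
#'
#' Sample covariance across time, pooling epochs if a `source_epochs`-style
#' array is given. Warns when there are fewer samples than channels (the
#' covariance is then rank deficient and the beamformer relies on
#' regularization).
#'
#' @param x an `eeg_recording`, a channels x samples matrix, or a
#'   channels x samples x epochs array
#' @return symmetric positive semi-definite channels x channels matrix
#' @export
sensor_covariance <- function(x) {
  if (inherits(x, "eeg_recording")) x <- x$data
  if (length(dim(x)) == 3) x <- matrix(x, nrow = dim(x)[1])
  if (!all(is.finite(x))) stop("non-finite samples in input")
  if (ncol(x) <= nrow(x))
    warning("fewer samples (", ncol(x), ") than channels (", nrow(x),
            "); covariance will be rank deficient")
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / (ncol(x) - 1L)
  (C + t(C)) / 2
}

#' LCMV beamformer spatial filters
#'
#' Linearly constrained minimum-variance filters with diagonal loading: the
#' covariance is regularized as
#' `C_reg = C + fraction * mean(diag(C)) * I`, and for each source column
#' `l_j` of the lead field the filter is
#' `w_j = (l_j' C_reg^-1 l_j)^-1 l_j' C_reg^-1`, which passes the target
#' source with unit gain while minimizing total output variance. The default
#' regularization fraction is 0.05 (the 5% convention).
#'
#' @param leadfield a `leadfield` (full column rank)
#' @param covariance sensors x sensors covariance matrix
#' @param regularization_fraction non-negative diagonal-loading fraction
#' @return a `spatial_filters`: list with `weights` (sources x sensors),
#'   `regularization_fraction`, `covariance_condition` (condition number of
#'   the regularized covariance) and `source_labels`
#' @export
lcmv_filters <- function(leadfield, covariance, regularization_fraction = 0.05) {
  if (regularization_fraction < 0) stop("regularization_fraction must be >= 0")
  G <- leadfield$gain
  if (nrow(covariance) != nrow(G) || ncol(covariance) != nrow(G))
    stop("covariance dimension does not match the lead field")
  C_reg <- covariance + regularization_fraction * mean(diag(covariance)) *
    diag(nrow(covariance))
  ev <- eigen(C_reg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("regularized covariance is singular; increase regularization_fraction")
  Ci <- chol2inv(chol(C_reg))
  CiG <- Ci %*% G                      # sensors x sources
  denom <- colSums(G * CiG)            # l_j' C^-1 l_j
  W <- t(CiG) / denom                  # sources x sensors
  flt <- list(weights = W,
              regularization_fraction = regularization_fraction,
              covariance_condition = max(ev) / min(ev),
              source_labels = leadfield$source_labels)
  class(flt) <- "spatial_filters"
  flt
}

#' Extract virtual-channel source time courses
#'
#' Applies the beamformer weights to sensor data, yielding one reconstructed
#' time course per source region.
#'
#' @param filters a `spatial_filters`
#' @param recording an `eeg_recording` (or channels x samples matrix)
#' @return matrix `sources x samples` with region-label rownames
#' @export
extract_virtual_channels <- function(filters, recording) {
  data <- if (inherits(recording, "eeg_recording")) recording$data else recording
  if (ncol(filters$weights) != nrow(data))
    stop("filter weights expect ", ncol(filters$weights), " channels, got ",
         nrow(data))
  out <- filters$weights %*% data
  rownames(out) <- filters$source_labels
  out
}

#' Reduce a set of constituent signals to one component per region
#'
#' Returns the dominant-component time course of a region's constituent
#' signals: the projection onto the first left singular vector of the
#' signals matrix. The sign is fixed so the component correlates positively
#' with the constituent mean.
#'
#' @param region_signals matrix `signals x samples` (one or more constituent
#'   time courses for a region)
#' @return list with `component` (length-samples vector) and
#'   `variance_fraction` (share of total variance captured)
#' @export
svd_reduce <- function(region_signals) {
  if (is.vector(region_signals)) region_signals <- matrix(region_signals, 1)
  if (all(region_signals == 0)) stop("all-zero region: no component to extract")
  sv <- svd(region_signals, nu = 1, nv = 0)
  comp <- drop(crossprod(sv$u[, 1], region_signals))
  mean_sig <- colMeans(region_signals)
  if (sum(comp * mean_sig) < 0) comp <- -comp
  list(component = comp,
       variance_fraction = sv$d[1]^2 / sum(sv$d^2))
}
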