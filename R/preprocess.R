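#' Default frequency bands
#'
#' The five canonical EEG bands used for band-averaged connectivity. The
#' delta band is bounded below at 1 Hz because the broadband high-pass has
#' already removed slower content.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(1, 4, 8, 13, 30),
             high_hz = c(4, 8, 13, 30, 50))
}

# zero-phase Butterworth band-pass: 4th-order high-pass then 4th-order
# low-pass, each applied forward-backward. Cascading the two half-filters is
# numerically safer than one narrow band-pass near DC.
zero_phase_bandpass <- function(x, low_hz, high_hz, fs, order = 4) {
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}

#' Band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel. The broadband default, 1-50 Hz, matches the analysis band.
#'
#' @param recording an `eeg_recording`
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`
#' @param order Butterworth order per pass (default 4)
#' @return the filtered `eeg_recording`, same dimensions
#' @export
bandpass_filter <- function(recording, low_hz = 1, high_hz = 50, order = 4) {
  fs <- recording$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2 (fs = ", fs, ")")
  recording$data <- t(apply(recording$data, 1, zero_phase_bandpass,
                            low_hz = low_hz, high_hz = high_hz,
                            fs = fs, order = order))
  recording
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at each sample.
#'
#' @param recording an `eeg_recording` with at least two channels
#' @return the re-referenced `eeg_recording`
#' @export
common_average_reference <- function(recording) {
  if (nrow(recording$data) < 2) stop("common average reference needs >= 2 channels")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Segment a source series into fixed-length epochs
#'
#' Cuts consecutive, non-overlapping epochs from the start of the series.
#' The default configuration (4 s at 500 Hz, 29 epochs) produces the
#' canonical `28 x 2000 x 29` array. With `selection = "random"`, the epochs
#' retained are a seeded random subset of all candidate epochs instead of
#' the first `n_epochs`.
#'
#' @param series matrix `regions x samples` (e.g. beamformed virtual channels)
#' @param fs sampling rate in Hz
#' @param epoch_seconds epoch length in seconds (default 4)
#' @param n_epochs number of epochs retained (default 29)
#' @param selection `"first"` (default) or `"random"`
#' @param seed seed used when `selection = "random"`
#' @param meta optional list of subject metadata carried on the result
#' @return a `source_epochs`: list with `data` (regions x samples x epochs
#'   array), `fs`, `region_labels`, `band` (`"broadband"`), `meta`
#' @export
segment_epochs <- function(series, fs = 500, epoch_seconds = 4, n_epochs = 29,
                           selection = c("first", "random"), seed = 1,
                           meta = list()) {
  selection <- match.arg(selection)
  spe <- as.integer(round(epoch_seconds * fs))
  n_avail <- ncol(series) %/% spe
  if (n_avail < n_epochs)
    stop("series supports only ", n_avail, " epochs of ", epoch_seconds,
         " s; ", n_epochs, " requested")
  keep <- if (selection == "first") seq_len(n_epochs) else {
    local_seed(seed); sort(sample.int(n_avail, n_epochs))
  }
  arr <- array(NA_real_, c(nrow(series), spe, n_epochs))
  for (k in seq_along(keep)) {
    off <- (keep[k] - 1L) * spe
    arr[, , k] <- series[, (off + 1L):(off + spe)]
  }
  ep <- list(data = arr, fs = fs, region_labels = rownames(series),
             band = "broadband", meta = meta)
  class(ep) <- "source_epochs"
  ep
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("source_epochs [", x$band, "]: ", d[1], " regions x ", d[2],
      " samples x ", d[3], " epochs @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Flip hemispheres so the affected side is canonical-left
#'
#' For subjects with a right-hemisphere lesion, swaps each region's data with
#' its homotope so that left-indexed labels denote the affected hemisphere in
#' every subject. For left-lesion subjects (or no lesion) this is the
#' identity. Applying the flip twice restores the input.
#'
#' @param epochs a `source_epochs` whose region labels form homotopic pairs
#' @param lesion_side `"left"`, `"right"` or `"none"`
#' @param atlas a `region_atlas`
#' @return the (possibly) flipped `source_epochs`
#' @export
flip_hemispheres <- function(epochs, lesion_side, atlas = region_atlas()) {
  lesion_side <- match.arg(lesion_side, c("left", "right", "none"))
  if (lesion_side != "right") return(epochs)
  idx <- match(epochs$region_labels, atlas$labels)
  if (anyNA(idx)) stop("region label(s) without a homotope: ",
                       paste(epochs$region_labels[is.na(idx)], collapse = ", "))
  perm <- match(atlas$labels[atlas$homotope[idx]], epochs$region_labels)
  if (anyNA(perm)) stop("homotope missing from the epoch array")
  epochs$data <- epochs$data[perm, , , drop = FALSE]
  epochs
}

#' Decompose epochs into frequency bands
#'
#' Zero-phase band-pass filters each region and epoch into each requested
#' band, returning one tagged `source_epochs` per band.
#'
#' @param epochs a `source_epochs`
#' @param bands data.frame with `name`, `low_hz`, `high_hz`
#'   (default [default_bands()])
#' @param order Butterworth order per pass
#' @return named list of `source_epochs`, one per band
#' @export
band_decompose <- function(epochs, bands = default_bands(), order = 4) {
  fs <- epochs$fs
  if (any(bands$high_hz > fs / 2)) stop("band above Nyquist frequency")
  if (any(bands$low_hz >= bands$high_hz) || any(bands$low_hz < 0))
    stop("invalid band edges")
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  d <- dim(epochs$data)
  for (b in seq_len(nrow(bands))) {
    hp <- signal::butter(order, bands$low_hz[b] / (fs / 2), type = "high")
    lp <- signal::butter(order, bands$high_hz[b] / (fs / 2), type = "low")
    arr <- array(NA_real_, d)
    for (e in seq_len(d[3])) {
      seg <- epochs$data[, , e]
      arr[, , e] <- t(apply(seg, 1, function(x)
        signal::filtfilt(lp, signal::filtfilt(hp, x))))
    }
    be <- epochs
    be$data <- arr
    be$band <- bands$name[b]
    out[[b]] <- be
  }
  out
}
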