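#' Write a recording as a delimited matrix with a metadata sidecar
#'
#' The data file is tab-separated, samples x channels, with channel labels
#' as the header; the sidecar (`<basename>_meta.csv`) carries subject id,
#' group, session, lesion side and sampling rate.
#'
#' @param recording an `eeg_recording`
#' @param dir output directory (created if missing)
#' @param basename file stem; defaults to `<subject_id>_<session>`
#' @return invisibly, the path of the data file
#' @export
write_recording <- function(recording, dir, basename = NULL) {
  if (is.null(basename))
    basename <- paste(recording$subject_id, recording$session, sep = "_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, paste0(basename, "_data.tsv"))
  meta_path <- file.path(dir, paste0(basename, "_meta.csv"))
  dt <- data.table::as.data.table(t(recording$data))
  data.table::setnames(dt, recording$channel_labels)
  data.table::fwrite(dt, data_path, sep = "\t")
  data.table::fwrite(data.table::data.table(
    subject_id = recording$subject_id, group = recording$group,
    session = recording$session, lesion_side = recording$lesion_side,
    fs = recording$fs, n_channels = nrow(recording$data)), meta_path)
  invisible(data_path)
}

#' Read a recording written by [write_recording()]
#'
#' @param data_path path of the `*_data.tsv` file; the `*_meta.csv` sidecar
#'   must sit beside it
#' @param fs_override if given and different from the sidecar's sampling
#'   rate, a warning is issued and the override wins (configuration takes
#'   precedence over file metadata)
#' @return an `eeg_recording`
#' @export
read_recording <- function(data_path, fs_override = NULL) {
  if (!file.exists(data_path)) stop("no such data file: ", data_path)
  meta_path <- sub("_data\\.tsv$", "_meta.csv", data_path)
  if (identical(meta_path, data_path) || !file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path)
  meta <- data.table::fread(meta_path)
  dt <- data.table::fread(data_path, sep = "\t")
  data <- t(as.matrix(dt))
  if (nrow(data) != meta$n_channels)
    stop("sidecar declares ", meta$n_channels, " channels but data has ",
         nrow(data))
  fs <- meta$fs
  if (!is.null(fs_override) && fs_override != fs) {
    warning("sidecar sampling rate ", fs, " Hz overridden by configuration (",
            fs_override, " Hz)")
    fs <- fs_override
  }
  if (!all(is.finite(data))) stop("non-finite samples in ", data_path)
  rec <- list(data = unname(data), fs = fs,
              channel_labels = colnames(dt),
              subject_id = meta$subject_id, group = meta$group,
              session = meta$session, lesion_side = meta$lesion_side)
  class(rec) <- "eeg_recording"
  rec
}

#' Write a connectivity matrix as labelled CSV with a JSON sidecar
#'
#' @param connectivity a `connectivity_matrix`
#' @param path output CSV path; the sidecar replaces `.csv` with `.json`
#' @return invisibly, `path`
#' @export
write_connectivity <- function(connectivity, path) {
  dt <- data.table::as.data.table(connectivity$weights, keep.rownames = "region")
  data.table::fwrite(dt, path)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(c(list(band = connectivity$band), connectivity$meta),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path CSV path
#' @return a `connectivity_matrix`
#' @export
read_connectivity <- function(path) {
  dt <- data.table::fread(path)
  labels <- dt$region
  W <- as.matrix(dt[, -1])
  dimnames(W) <- list(labels, labels)
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  cm <- list(weights = W, band = meta$band %||% "unknown", labels = labels,
             meta = meta[setdiff(names(meta), "band")])
  class(cm) <- "connectivity_matrix"
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ground-truth coupling graph as an edge-list CSV
#'
#' @param template a `coupling_graph`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_coupling_graph <- function(template, path) {
  data.table::fwrite(data.table::as.data.table(template$edges), path)
  invisible(path)
}
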