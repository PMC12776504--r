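#' Cortical region atlas (28 regions, 14 homotopic pairs)
#'
#' Builds the region atlas used throughout the pipeline: 14 base regions
#' (cingulate gyrus, insula, inferior parietal lobule, primary motor cortex,
#' middle frontal gyrus, middle temporal gyrus, precuneus, postcentral gyrus,
#' superior parietal lobule, superior temporal gyrus, posterior superior
#' temporal sulcus, ventral premotor cortex, supplementary motor area and
#' dorsal area 6), each present in the left and right hemisphere. Left-hemisphere
#' regions occupy indices 1-14 and right-hemisphere regions 15-28, so that after
#' hemisphere flipping the affected hemisphere is always the left block.
#'
#' @return An object of class `region_atlas`: a list with `labels` (28 region
#'   names, `<base>_L` then `<base>_R`), `base` (the 14 base names),
#'   `hemisphere` (side tag per region, `"L"` or `"R"`), and `homotope`
#'   (integer vector mapping each region index to its mirror-image partner).
#' @examples
#' atlas <- region_atlas()
#' atlas$labels[atlas$homotope[1]]  # homotope of CG_L is CG_R
#' @export
region_atlas <- function() {
  base <- c("CG", "INS", "IPL", "M1", "MFG", "MTG", "Pcun",
            "PoG", "SPL", "STG", "pSTS", "vPM", "SMA", "dorsalA6")
  labels <- c(paste0(base, "_L"), paste0(base, "_R"))
  atlas <- list(
    labels = labels,
    base = base,
    hemisphere = rep(c("L", "R"), each = 14L),
    homotope = c(15:28, 1:14)
  )
  class(atlas) <- "region_atlas"
  atlas
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas: ", length(x$labels), " regions (",
      length(x$base), " homotopic pairs)\n", sep = "")
  invisible(x)
}

#' Index of a region label in the atlas
#' @param atlas a `region_atlas`
#' @param label region label such as `"SMA_L"`
#' @return integer index
#' @keywords internal
atlas_index <- function(atlas, label) {
  idx <- match(label, atlas$labels)
  if (anyNA(idx)) stop("unknown region label(s): ",
                       paste(label[is.na(idx)], collapse = ", "))
  idx
}
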