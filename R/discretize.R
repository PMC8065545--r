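#' Collewet re-segmentation of VOI intensities
#'
#' Single-pass outlier rejection: in-mask voxels whose intensity falls
#' outside mean +/- 3 SD (sample SD) of the in-mask distribution are dropped
#' from the VOI before discretization.
#'
#' @param x numeric vector of in-mask intensities (length >= 2).
#' @return logical vector marking retained voxels; guaranteed nonempty.
#' @export
collewet_resegment <- function(x) {
  if (length(x) < 2) return(rep(TRUE, length(x)))
  mu <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
  keep <- x >= mu - 3 * s & x <= mu + 3 * s
  if (!any(keep))
    stop("internal: Collewet re-segmentation removed every voxel", call. = FALSE)
  keep
}

#' Fixed-bin-number gray-level discretization
#'
#' Maps retained VOI intensities to integer levels 1..n_bins:
#' level(x) = min(n_bins, floor(n_bins (x - min) / (max - min)) + 1), so the
#' minimum maps to level 1 and the maximum exactly to level n_bins. A
#' constant VOI maps entirely to level 1.
#'
#' @param x numeric vector of retained intensities.
#' @param n_bins number of gray levels, default 64.
#' @return integer vector of levels in 1..n_bins.
#' @export
discretize_fbn <- function(x, n_bins = 64L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2, length(x) >= 1)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  pmin(n_bins, as.integer(floor(n_bins * (x - lo) / (hi - lo))) + 1L)
}
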