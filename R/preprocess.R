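#' Pipeline configuration
#'
#' Central container for the analysis constants: the T2w standardization
#' range, the VOI volume inclusion threshold, the number of discretization
#' bins, the redundancy correlation threshold, the stability alpha, the
#' signature size, and the number of undersampling subsets.
#'
#' @param t2w_scale_range target intensity range of T2w standardization.
#' @param voi_min_cc VOI inclusion threshold in cc; lesions must exceed it
#'   strictly.
#' @param n_bins fixed bin number for gray-level discretization.
#' @param r_threshold absolute Pearson correlation above which two features
#'   are considered redundant.
#' @param stability_alpha Friedman-test alpha: features with p strictly above
#'   it are called stable.
#' @param top_k_stable number of top-ranked stable features feeding each
#'   per-modality signature.
#' @param n_subsets number of balanced undersampling repetitions.
#' @param cv_folds stratified cross-validation folds within each subset.
#' @param seed default RNG seed for the stochastic stages.
#' @export
pipeline_config <- function(t2w_scale_range = c(0, 600), voi_min_cc = 0.7,
                            n_bins = 64L, r_threshold = 0.8,
                            stability_alpha = 0.05, top_k_stable = 10L,
                            n_subsets = 10L, cv_folds = 5L, seed = 1L) {
  stopifnot(t2w_scale_range[2] > t2w_scale_range[1], voi_min_cc > 0,
            n_bins >= 2, r_threshold > 0, stability_alpha > 0,
            top_k_stable >= 1, n_subsets >= 1, cv_folds >= 2)
  structure(list(t2w_scale_range = t2w_scale_range, voi_min_cc = voi_min_cc,
                 n_bins = as.integer(n_bins), r_threshold = r_threshold,
                 stability_alpha = stability_alpha,
                 top_k_stable = as.integer(top_k_stable),
                 n_subsets = as.integer(n_subsets),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Compute an ADC map from a two-b-value DWI pair
#'
#' Inverts the monoexponential diffusion model S(b) = S0 exp(-b ADC) from two
#' acquisitions: ADC = ln(S_low / S_high) / (b_high - b_low), in mm^2/s.
#' Voxels where either signal is nonpositive cannot be inverted; they are set
#' to 0 and counted in the `n_nonpositive` attribute, with a warning.
#'
#' @param s_low,s_high `image_volume`s at the low and high b-value, on the
#'   same grid.
#' @param b_values c(low, high) in s/mm^2, b_high > b_low >= 0.
#' @return An `image_volume` holding the ADC map, with attribute
#'   `n_nonpositive`.
#' @export
compute_adc <- function(s_low, s_high, b_values = c(50, 800)) {
  stopifnot(is_image_volume(s_low), is_image_volume(s_high))
  stopifnot_same_grid(s_low, s_high, "DWI volumes")
  if (!(b_values[2] > b_values[1] && b_values[1] >= 0))
    stop("need b_high > b_low >= 0", call. = FALSE)
  lo <- s_low$intensities; hi <- s_high$intensities
  bad <- lo <= 0 | hi <= 0
  adc <- array(0, dim = dim(lo))
  ok <- !bad
  adc[ok] <- log(lo[ok] / hi[ok]) / (b_values[2] - b_values[1])
  if (any(bad))
    warning(sprintf("compute_adc: %d voxel(s) with nonpositive signal set to 0",
                    sum(bad)), call. = FALSE)
  out <- image_volume(adc, s_low$spacing_mm, s_low$origin)
  attr(out, "n_nonpositive") <- sum(bad)
  out
}

#' Standardize T2w intensities by linear scaling and shifting
#'
#' Affine map sending the observed volume minimum and maximum to the ends of
#' the target range (default 0-600). Strictly monotone, so voxel rank order
#' is preserved. The minimum and maximum are taken over the whole volume,
#' since standardization precedes any segmentation-based analysis.
#'
#' @param volume an `image_volume` with at least two distinct intensities.
#' @param range target c(min, max).
#' @return The standardized `image_volume`.
#' @export
standardize_t2w <- function(volume, range = c(0, 600)) {
  stopifnot(is_image_volume(volume))
  x <- volume$intensities
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("constant volume: T2w standardization undefined", call. = FALSE)
  y <- range[1] + (x - lo) * (range[2] - range[1]) / (hi - lo)
  image_volume(y, volume$spacing_mm, volume$origin)
}

#' VOI volume in cubic centimetres
#'
#' @param mask logical 3D array, nonempty.
#' @param spacing_mm voxel spacing (mm).
#' @return Voxel count times voxel volume, converted mm^3 to cc.
#' @export
voi_volume_cc <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty mask has no volume", call. = FALSE)
  sum(mask) * prod(spacing_mm) / 1000
}

#' Apply the VOI volume inclusion filter to a cohort
#'
#' A case is included when its reader-1 ADC-modality mask volume strictly
#' exceeds `min_cc` (the criterion is evaluated on the ADC delineation only,
#' since the ADC map has the coarser resolution). Boundary cases (volume
#' exactly at the threshold) are excluded and flagged in the report.
#'
#' @param cases list of `lesion_case` objects.
#' @param min_cc threshold in cc, default 0.7.
#' @return list with `included`, `excluded` (case lists) and `report`
#'   (data.frame patient_id, volume_cc, included, boundary).
#' @export
filter_cohort_by_volume <- function(cases, min_cc = 0.7) {
  vols <- vapply(cases, function(cs) {
    m <- cs$masks$adc$reader1
    if (is.null(m)) stop(sprintf("case %s lacks an ADC reader-1 mask",
                                 cs$patient_id), call. = FALSE)
    voi_volume_cc(m, cs$volumes$dwi_low$spacing_mm)
  }, numeric(1))
  keep <- vols > min_cc
  report <- data.frame(
    patient_id = vapply(cases, `[[`, character(1), "patient_id"),
    volume_cc = vols, included = keep,
    boundary = abs(vols - min_cc) < 1e-12,
    stringsAsFactors = FALSE)
  list(included = cases[keep], excluded = cases[!keep], report = report)
}
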