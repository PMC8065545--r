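#' Canonical names of the 93 radiomic features
#'
#' The feature set is partitioned into 14 morphological (`shape_`), 18
#' first-order (`fos_`) and 61 textural features (24 `glcm_`, 16 `glrlm_`,
#' 16 `glszm_`, 5 `ngtdm_`).
#'
#' @return Character vector of length 93, with a `classes` attribute giving
#'   the per-family name lists.
#' @export
feature_names <- function() {
  dummy_lev <- array(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L), dim = c(2, 2, 2))
  voi <- list(lev = dummy_lev, n_bins = 64L, n_voxels = 8L)
  fam <- list(
    shape = names(shape_features(array(TRUE, dim = c(2, 2, 2)), c(1, 1, 1))),
    fos = names(first_order_features(c(1, 2), c(1L, 2L))),
    glcm = names(glcm_features(voi)),
    glrlm = names(glrlm_features(voi)),
    glszm = names(glszm_features(voi)),
    ngtdm = names(ngtdm_features(voi)))
  out <- unlist(fam, use.names = FALSE)
  attr(out, "classes") <- fam
  out
}

#' Extract the full 93-feature radiomic vector from one (image, mask) pair
#'
#' Runs the standard chain: isotropic resampling (tri-linear intensities,
#' nearest-neighbour mask), Collewet re-segmentation of the VOI intensities
#' (mean +/- 3 SD), fixed-bin-number discretization to `n_bins` gray levels,
#' then the five feature families. Morphology is computed on the resampled
#' mask (before intensity re-segmentation); intensity and texture features on
#' the re-segmented VOI. Fully deterministic.
#'
#' @param image an `image_volume`.
#' @param mask logical array on the same grid.
#' @param config a [pipeline_config()].
#' @return Named numeric vector of exactly 93 finite values.
#' @export
extract_all <- function(image, mask, config = pipeline_config()) {
  if (!any(mask)) stop("degenerate VOI: empty mask", call. = FALSE)
  rs <- resample_isotropic(image, mask)
  vol <- rs$volume; m <- rs$mask
  x_all <- vol$intensities[m]
  keep <- collewet_resegment(x_all)
  m_seg <- m
  m_seg[m] <- keep
  x <- x_all[keep]
  lev <- discretize_fbn(x, config$n_bins)
  voi <- discretized_voi(lev, m_seg, config$n_bins)
  out <- c(shape_features(m, vol$spacing_mm),
           first_order_features(x, lev, prod(vol$spacing_mm)),
           glcm_features(voi),
           glrlm_features(voi),
           glszm_features(voi),
           ngtdm_features(voi))
  stopifnot(length(out) == 93L, all(is.finite(out)))
  out
}

#' Derive the analysis images of a case
#'
#' Computes the ADC map from the case's DWI pair via the monoexponential
#' model and standardizes the T2w volume to the configured range.
#'
#' @param case a `lesion_case`.
#' @param config a [pipeline_config()].
#' @param b_values c(low, high) b-values in s/mm^2.
#' @return list(t2w = standardized T2w, adc = ADC map), both `image_volume`s.
#' @export
prepare_case_images <- function(case, config = pipeline_config(),
                                b_values = c(50, 800)) {
  adc <- suppressWarnings(
    compute_adc(case$volumes$dwi_low, case$volumes$dwi_high, b_values))
  t2w <- standardize_t2w(case$volumes$t2w, config$t2w_scale_range)
  list(t2w = t2w, adc = adc)
}

#' Extract per-cohort feature tables
#'
#' For every case, modality (T2w, ADC) and requested reader, extracts the 93
#' features and assembles one table per reader with modality-prefixed columns
#' (e.g. `adc_fos_Mean`, the lesion mean ADC).
#'
#' @param cases list of `lesion_case` objects (typically the included cases
#'   after volume filtering).
#' @param config a [pipeline_config()].
#' @param readers character subset of c("reader1", "reader2").
#' @param verbose print progress.
#' @return Named list of data.frames (one per reader), each with a
#'   `patient_id` column plus 186 feature columns.
#' @export
extract_cohort <- function(cases, config = pipeline_config(),
                           readers = c("reader1", "reader2"),
                           verbose = FALSE) {
  tables <- stats::setNames(vector("list", length(readers)), readers)
  for (rd in readers) {
    rows <- vector("list", length(cases))
    for (i in seq_along(cases)) {
      case <- cases[[i]]
      imgs <- prepare_case_images(case, config)
      f_t2w <- extract_all(imgs$t2w, case$masks$t2w[[rd]], config)
      f_adc <- extract_all(imgs$adc, case$masks$adc[[rd]], config)
      rows[[i]] <- c(stats::setNames(f_t2w, paste0("t2w_", names(f_t2w))),
                     stats::setNames(f_adc, paste0("adc_", names(f_adc))))
      if (verbose && i %% 10 == 0)
        message(sprintf("  %s: %d/%d cases", rd, i, length(cases)))
    }
    tab <- as.data.frame(do.call(rbind, rows))
    tab <- cbind(patient_id = vapply(cases, `[[`, character(1), "patient_id"),
                 tab, stringsAsFactors = FALSE)
    tables[[rd]] <- tab
  }
  tables
}
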