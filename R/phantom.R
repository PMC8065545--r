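#' Parameters of the synthetic lesion-phantom cohort
#'
#' The generator stands in for an unavailable patient cohort: it emulates the
#' acquisition geometry (fine in-plane resolution, coarse slice spacing), a
#' two-reader delineation of each lesion, class-dependent intensity and
#' texture structure (high-grade lesions have lower mean ADC and coarser
#' texture), lesions straddling the 0.7 cc inclusion threshold, and imbalanced
#' pathological label frequencies.
#'
#' @param grid_shape integer length-3, voxels per axis of the lesion-centred
#'   subvolume.
#' @param spacing_mm voxel size per axis in mm; default (0.6, 0.6, 3.0)
#'   reflects a typical prostate protocol with 3 mm slices and exercises
#'   anisotropic resampling.
#' @param lesion_radius_range_mm equivalent-sphere radius range (mm) for
#'   lesions intended to pass the 0.7 cc volume filter.
#' @param small_radius_range_mm radius range for deliberately sub-threshold
#'   lesions (below 0.7 cc), which exercise the inclusion filter.
#' @param frac_subthreshold fraction of the cohort generated sub-threshold;
#'   default 40/102 mirrors the reported exclusion rate.
#' @param texture_correlation_length_mm named c(low=, high=): FWHM (mm) of the
#'   Gaussian random field texture per aggressiveness class.
#' @param class_mean_adc named c(low=, high=): mean lesion ADC (mm^2/s).
#' @param class_mean_t2w named c(low=, high=): mean lesion T2w intensity
#'   (arbitrary scanner units).
#' @param adc_texture_sd,t2w_texture_sd standard deviation of the zero-mean
#'   texture field added inside the lesion, in each modality's units.
#' @param background_adc,background_t2w constant background intensities.
#' @param s0 proton-density DWI signal at b = 0 used by the forward
#'   monoexponential model.
#' @param noise_sd_t2w,noise_sd_dwi additive Gaussian measurement noise SD.
#' @param reader_perturbation_mm boundary jitter depth (mm) of the simulated
#'   second reader's masks.
#' @param effect_size multiplier in \[0, 1\] interpolating all class-dependent
#'   parameters between their class midpoint (0, no class signal) and their
#'   stated values (1, full separation).
#' @param label_prevalences list of label-generation probabilities; the
#'   defaults reproduce the reported cohort's marginal frequencies (high GGG
#'   0.71, ECE 0.61, pN>=1 0.25 of assessable, pNx 0.16, PZ 0.69).
#' @param n_patients cohort size before volume filtering; default 102.
#' @param b_values c(low, high) diffusion weightings in s/mm^2.
#' @return A `phantom_params` list, validated.
#' @export
phantom_params <- function(grid_shape = c(48L, 48L, 14L),
                           spacing_mm = c(0.6, 0.6, 3.0),
                           lesion_radius_range_mm = c(5.8, 9.0),
                           small_radius_range_mm = c(3.0, 5.0),
                           frac_subthreshold = 40 / 102,
                           texture_correlation_length_mm = c(low = 1.5, high = 3.0),
                           class_mean_adc = c(low = 1.4e-3, high = 0.9e-3),
                           class_mean_t2w = c(low = 420, high = 300),
                           adc_texture_sd = 1.5e-4,
                           t2w_texture_sd = 45,
                           background_adc = 1.8e-3,
                           background_t2w = 200,
                           s0 = 1200,
                           noise_sd_t2w = 10,
                           noise_sd_dwi = 6,
                           reader_perturbation_mm = 1.2,
                           effect_size = 1,
                           label_prevalences = list(
                             ggg_high = 44 / 62,
                             ece_given_high = 0.70, ece_given_low = 0.40,
                             pn1_given_high = 0.32, pn1_given_low = 0.08,
                             pnx = 10 / 62,
                             zone = c(PZ = 43 / 62, TZ = 16 / 62, both = 3 / 62)),
                           n_patients = 102L,
                           b_values = c(50, 800)) {
  p <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
            lesion_radius_range_mm = lesion_radius_range_mm,
            small_radius_range_mm = small_radius_range_mm,
            frac_subthreshold = frac_subthreshold,
            texture_correlation_length_mm = texture_correlation_length_mm,
            class_mean_adc = class_mean_adc, class_mean_t2w = class_mean_t2w,
            adc_texture_sd = adc_texture_sd, t2w_texture_sd = t2w_texture_sd,
            background_adc = background_adc, background_t2w = background_t2w,
            s0 = s0, noise_sd_t2w = noise_sd_t2w, noise_sd_dwi = noise_sd_dwi,
            reader_perturbation_mm = reader_perturbation_mm,
            effect_size = effect_size, label_prevalences = label_prevalences,
            n_patients = as.integer(n_patients), b_values = b_values)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot(length(p$grid_shape) == 3, all(p$grid_shape >= 4))
  if (any(p$spacing_mm <= 0)) stop("spacings must be > 0", call. = FALSE)
  if (any(p$lesion_radius_range_mm <= 0) || any(p$small_radius_range_mm <= 0))
    stop("lesion radii must be > 0", call. = FALSE)
  pr <- unlist(p$label_prevalences)
  if (any(pr < 0 | pr > 1)) stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (p$frac_subthreshold < 0 || p$frac_subthreshold > 1)
    stop("frac_subthreshold must lie in [0, 1]", call. = FALSE)
  if (p$effect_size < 0 || p$effect_size > 1)
    stop("effect_size must lie in [0, 1]", call. = FALSE)
  if (p$reader_perturbation_mm < 0)
    stop("reader_perturbation_mm must be >= 0", call. = FALSE)
  invisible(TRUE)
}

# Interpolate a named c(low=, high=) pair toward its midpoint by effect size.
class_value <- function(pair, class_label, effect_size) {
  mid <- mean(pair)
  mid + effect_size * (pair[[class_label]] - mid)
}

# Solid ellipsoid mask from semi-axes (mm), axis-aligned up to an in-plane
# rotation, on a voxel-centre lattice.
ellipsoid_mask <- function(grid_shape, spacing_mm, center_mm, semi_axes_mm,
                           theta = 0) {
  cx <- (seq_len(grid_shape[1]) - 1) * spacing_mm[1]
  cy <- (seq_len(grid_shape[2]) - 1) * spacing_mm[2]
  cz <- (seq_len(grid_shape[3]) - 1) * spacing_mm[3]
  dx <- outer(cx - center_mm[1], cy - center_mm[2], function(x, y)
    cos(theta) * x + sin(theta) * y)
  dy <- outer(cx - center_mm[1], cy - center_mm[2], function(x, y)
    -sin(theta) * x + cos(theta) * y)
  q2d <- (dx / semi_axes_mm[1])^2 + (dy / semi_axes_mm[2])^2
  m <- array(FALSE, dim = grid_shape)
  for (k in seq_len(grid_shape[3])) {
    qz <- ((cz[k] - center_mm[3]) / semi_axes_mm[3])^2
    m[, , k] <- q2d + qz <= 1
  }
  m
}

# Zero-mean, unit-SD Gaussian random field: white noise smoothed with a
# Gaussian kernel whose FWHM (mm) is the texture correlation length.
gaussian_random_field <- function(grid_shape, spacing_mm, corr_length_mm) {
  w <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  sigma_vox <- (corr_length_mm / 2.3548) / spacing_mm
  f <- smooth_gaussian_3d(w, sigma_vox)
  s <- stats::sd(as.numeric(f))
  if (s > 0) f <- f / s
  f - mean(f)
}

#' Generate one synthetic lesion phantom
#'
#' Builds a single patient's volumes and masks: a T2w volume and a DWI pair
#' (b-low, b-high) generated so that the exact monoexponential relation
#' S(b) = S0 exp(-b ADC) holds voxel-wise before noise, with lesion texture
#' drawn from a Gaussian random field at the class's correlation length.
#'
#' @param params a [phantom_params()] object.
#' @param class_label "high" or "low" aggressiveness class.
#' @param seed integer RNG seed; identical (params, class, seed) give a
#'   byte-identical phantom.
#' @param small generate a deliberately sub-threshold (< 0.7 cc) lesion.
#' @param patient_id identifier string.
#' @return A `lesion_case` list with elements `volumes` (t2w, dwi_low,
#'   dwi_high), `adc_true` (the generating ADC field, for validation),
#'   `masks` (per modality, per reader) and `labels` (filled by
#'   [generate_cohort()], NULL here).
#' @export
generate_phantom <- function(params, class_label = c("high", "low"), seed,
                             small = FALSE, patient_id = "P001") {
  class_label <- match.arg(class_label)
  validate_phantom_params(params)
  gs <- params$grid_shape; sp <- params$spacing_mm
  fov <- (gs - 1) * sp
  with_seed(seed, {
    rr <- if (small) params$small_radius_range_mm else params$lesion_radius_range_mm
    r_eq <- stats::runif(1, rr[1], rr[2])
    # anisotropy around the equivalent radius, volume-preserving
    f1 <- stats::runif(1, 0.8, 1.3); f2 <- stats::runif(1, 0.8, 1.3)
    semi <- r_eq * c(f1, f2, 1 / (f1 * f2))
    if (any(2 * semi > fov))
      stop("lesion larger than grid: increase grid_shape", call. = FALSE)
    center <- fov / 2 + stats::runif(3, -1, 1) * pmin(2, (fov - 2 * semi) / 4)
    theta <- stats::runif(1, 0, pi)
    mask <- ellipsoid_mask(gs, sp, center, semi, theta)
    if (!any(mask)) stop("degenerate lesion: empty mask", call. = FALSE)

    es <- params$effect_size
    corr_len <- class_value(params$texture_correlation_length_mm, class_label, es)
    mu_adc <- class_value(params$class_mean_adc, class_label, es)
    mu_t2w <- class_value(params$class_mean_t2w, class_label, es)

    tex_t2w <- gaussian_random_field(gs, sp, corr_len)
    tex_adc <- gaussian_random_field(gs, sp, corr_len)

    t2w <- array(params$background_t2w, dim = gs)
    t2w[mask] <- mu_t2w + params$t2w_texture_sd * tex_t2w[mask]
    t2w <- t2w + stats::rnorm(prod(gs), 0, params$noise_sd_t2w)

    adc <- array(params$background_adc, dim = gs)
    adc[mask] <- mu_adc + params$adc_texture_sd * tex_adc[mask]
    adc <- pmax(adc, 1e-5)
    s_low <- params$s0 * exp(-params$b_values[1] * adc)
    s_high <- params$s0 * exp(-params$b_values[2] * adc)
    s_low <- s_low + stats::rnorm(prod(gs), 0, params$noise_sd_dwi)
    s_high <- s_high + stats::rnorm(prod(gs), 0, params$noise_sd_dwi)

    # both readers delineate the same true boundary with independent errors
    pm <- params$reader_perturbation_mm
    masks <- list(
      t2w = list(reader1 = perturb_mask(mask, sp, pm,
                                        seed = derive_seed(seed, 101)),
                 reader2 = perturb_mask(mask, sp, pm,
                                        seed = derive_seed(seed, 102))),
      adc = list(reader1 = perturb_mask(mask, sp, pm,
                                        seed = derive_seed(seed, 201)),
                 reader2 = perturb_mask(mask, sp, pm,
                                        seed = derive_seed(seed, 202)))
    )
    structure(list(
      patient_id = patient_id,
      volumes = list(t2w = image_volume(t2w, sp),
                     dwi_low = image_volume(array(s_low, gs), sp),
                     dwi_high = image_volume(array(s_high, gs), sp)),
      adc_true = image_volume(adc, sp),
      lesion_mask = mask,
      masks = masks,
      labels = NULL,
      zone = NA_character_
    ), class = "lesion_case")
  })
}

#' Simulate a reader's delineation of a lesion boundary
#'
#' Perturbs a binary mask by coherent random boundary dilation/erosion of
#' physical depth at most `magnitude_mm`: the output always contains the
#' erosion of the input by `magnitude_mm` and is contained in its dilation,
#' with the in-between shell resolved by a smooth random field. The shell
#' voxels are selected volume-matched (exactly as many as the input owns in
#' the shell), so a perturbed delineation never biases the VOI volume. Draws
#' are retried until the Dice overlap with the input is at least `min_dice`.
#'
#' @param mask logical 3D array, nonempty.
#' @param spacing_mm voxel spacing (mm).
#' @param magnitude_mm maximal boundary displacement depth (mm); 0 returns the
#'   input unchanged.
#' @param seed RNG seed.
#' @param min_dice minimal acceptable Dice overlap with the input.
#' @return A logical mask of the same shape.
#' @export
perturb_mask <- function(mask, spacing_mm, magnitude_mm, seed = 1,
                         min_dice = 0.6) {
  if (magnitude_mm < 0) stop("magnitude_mm must be >= 0", call. = FALSE)
  if (!any(mask)) stop("cannot perturb an empty mask", call. = FALSE)
  if (magnitude_mm == 0) return(mask)
  se <- struct_el_offsets(magnitude_mm, spacing_mm)
  lo <- binary_erode(mask, se)
  hi <- binary_dilate(mask, se)
  band <- hi & !lo
  if (!any(band)) return(mask)
  n_target <- sum(band & mask)   # volume-matched shell occupancy
  if (n_target == 0) return(lo | (band & mask))
  with_seed(seed, {
    for (attempt in 1:20) {
      g <- smooth_gaussian_3d(array(stats::rnorm(length(mask)), dim = dim(mask)),
                              c(2, 2, 0.7))
      gb <- g[band]
      sel <- array(FALSE, dim = dim(mask))
      sel[band][order(gb, decreasing = TRUE)[seq_len(n_target)]] <- TRUE
      out <- lo | sel
      if (any(out) && dice_coefficient(mask, out) >= min_dice) return(out)
    }
    mask  # all draws rejected; fall back to the original delineation
  })
}

#' Draw a clinical label table
#'
#' Labels are generated class-first: the aggressiveness class (high/low GGG)
#' is Bernoulli with the cohort prevalence, and ECE and pN are drawn
#' conditionally on class so that their marginal frequencies match the stated
#' prevalences while remaining associated with the class (as the downstream
#' association analysis assumes). pNx status and zone are independent.
#'
#' @param n number of patients.
#' @param prevalences list as in [phantom_params()]'s `label_prevalences`.
#' @param seed RNG seed.
#' @return data.frame with columns patient_id, ggg_high, ece, pn
#'   (pN0/pN1/pNx), zone (PZ/TZ/both), true_class.
#' @export
generate_labels <- function(n, prevalences, seed = 1) {
  pv <- prevalences
  with_seed(seed, {
    ggg_high <- stats::runif(n) < pv$ggg_high
    p_ece <- ifelse(ggg_high, pv$ece_given_high, pv$ece_given_low)
    ece <- stats::runif(n) < p_ece
    p_pn1 <- ifelse(ggg_high, pv$pn1_given_high, pv$pn1_given_low)
    pn <- ifelse(stats::runif(n) < p_pn1, "pN1", "pN0")
    pn[stats::runif(n) < pv$pnx] <- "pNx"
    zone <- sample(names(pv$zone), n, replace = TRUE, prob = pv$zone)
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      ggg_high = ggg_high, ece = ece, pn = pn, zone = zone,
      true_class = ifelse(ggg_high, "high", "low"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Draws a label table, then one lesion phantom per patient whose image
#' structure follows the patient's aggressiveness class; a fixed fraction of
#' lesions is generated below the 0.7 cc inclusion threshold to exercise the
#' volume filter.
#'
#' @param params a [phantom_params()] object.
#' @param seed master RNG seed; all per-patient seeds derive from it.
#' @return list with `cases` (list of `lesion_case`, labels attached),
#'   `labels` (the table, with a `subthreshold` column), and `params`.
#' @export
generate_cohort <- function(params, seed = 1) {
  validate_phantom_params(params)
  n <- params$n_patients
  if (n < 4) stop("n_patients must be >= 4", call. = FALSE)
  labels <- generate_labels(n, params$label_prevalences,
                            seed = derive_seed(seed, 1))
  n_small <- round(params$frac_subthreshold * n)
  small_idx <- with_seed(derive_seed(seed, 2), sample.int(n, n_small))
  labels$subthreshold <- seq_len(n) %in% small_idx
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- generate_phantom(
      params,
      class_label = labels$true_class[i],
      seed = derive_seed(seed, 1000 + i),
      small = labels$subthreshold[i],
      patient_id = labels$patient_id[i])
    cases[[i]]$labels <- list(ggg_high = labels$ggg_high[i],
                              ece = labels$ece[i], pn = labels$pn[i])
    cases[[i]]$zone <- labels$zone[i]
  }
  list(cases = cases, labels = labels, params = params)
}

#' Write / read a cohort as NIfTI volumes plus a CSV label table
#'
#' One file per (patient, volume) and per (patient, modality, reader) mask,
#' plus `labels.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort$cases) {
    id <- case$patient_id
    for (v in names(case$volumes))
      write_volume(case$volumes[[v]],
                   file.path(dir, sprintf("%s_%s.nii.gz", id, v)))
    for (mod in names(case$masks))
      for (rd in names(case$masks[[mod]]))
        write_volume(case$masks[[mod]][[rd]],
                     file.path(dir, sprintf("%s_mask_%s_%s.nii.gz", id, mod, rd)))
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param spacing_mm spacing applied to mask files on read.
#' @export
read_cohort <- function(dir, spacing_mm = NULL) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$patient_id[i]
    vols <- list(
      t2w = read_volume(file.path(dir, sprintf("%s_t2w.nii.gz", id))),
      dwi_low = read_volume(file.path(dir, sprintf("%s_dwi_low.nii.gz", id))),
      dwi_high = read_volume(file.path(dir, sprintf("%s_dwi_high.nii.gz", id))))
    masks <- lapply(c(t2w = "t2w", adc = "adc"), function(mod)
      lapply(c(reader1 = "reader1", reader2 = "reader2"), function(rd)
        read_mask(file.path(dir, sprintf("%s_mask_%s_%s.nii.gz", id, mod, rd)))))
    structure(list(patient_id = id, volumes = vols, adc_true = NULL,
                   masks = masks,
                   labels = list(ggg_high = labels$ggg_high[i],
                                 ece = labels$ece[i], pn = labels$pn[i]),
                   zone = labels$zone[i]),
              class = "lesion_case")
  })
  list(cases = cases, labels = labels, params = NULL)
}
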