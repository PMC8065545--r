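#' First-order statistical features of the VOI intensity distribution
#'
#' The 18 histogram/intensity descriptors: energy, total energy, entropy,
#' minimum, 10th percentile, 90th percentile, maximum, mean, median,
#' interquartile range, range, mean absolute deviation, robust MAD (within
#' the 10-90 percentile band), RMS, skewness, kurtosis, variance and
#' uniformity. Entropy (bits) and uniformity are computed on the fixed-bin
#' discretized levels; all moments are population moments; skewness and
#' kurtosis of a constant VOI are defined as 0.
#'
#' @param x numeric vector of retained in-mask intensities.
#' @param levels integer vector of discretized gray levels for the same
#'   voxels (see [discretize_fbn()]).
#' @param voxel_volume_mm3 voxel volume, used by total energy.
#' @return Named numeric vector of 18 features, prefix `fos_`.
#' @export
first_order_features <- function(x, levels, voxel_volume_mm3 = 1) {
  n <- length(x)
  stopifnot(n >= 1, length(levels) == n)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  inb <- x >= q[1] & x <= q[4]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(fos_Energy = sum(x^2),
    fos_TotalEnergy = voxel_volume_mm3 * sum(x^2),
    fos_Entropy = -sum(p * log2(p)),
    fos_Minimum = min(x),
    fos_10Percentile = q[1],
    fos_90Percentile = q[4],
    fos_Maximum = max(x),
    fos_Mean = mu,
    fos_Median = stats::median(x),
    fos_InterquartileRange = q[3] - q[2],
    fos_Range = max(x) - min(x),
    fos_MeanAbsoluteDeviation = mean(abs(x - mu)),
    fos_RobustMeanAbsoluteDeviation =
      if (any(inb)) mean(abs(x[inb] - mean(x[inb]))) else 0,
    fos_RootMeanSquared = sqrt(mean(x^2)),
    fos_Skewness = skew,
    fos_Kurtosis = kurt,
    fos_Variance = m2,
    fos_Uniformity = sum(p^2))
}
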