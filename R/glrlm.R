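# Gray level run length matrix features.

# Run-length matrix (levels x run length) for one direction: maximal runs of
# equal level along lattice lines in direction `off`, in-mask voxels only.
glrlm_matrix <- function(lev, off, n_levels) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  v <- lev[!is.na(lev)]
  ax0 <- which(off != 0)[1]
  t <- idx[, ax0] * off[ax0]          # line parameter (unit steps)
  key <- idx - outer(t, off)          # line identifier
  ord <- order(key[, 1], key[, 2], key[, 3], t)
  k1 <- key[ord, 1]; k2 <- key[ord, 2]; k3 <- key[ord, 3]
  tt <- t[ord]; vv <- v[ord]
  n <- length(vv)
  newrun <- c(TRUE, k1[-1] != k1[-n] | k2[-1] != k2[-n] | k3[-1] != k3[-n] |
                tt[-1] != tt[-n] + 1 | vv[-1] != vv[-n])
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  runlev <- vv[newrun]
  lmax <- max(runlen)
  R <- matrix(0, n_levels, lmax)
  cnt <- tabulate((runlev - 1L) * lmax + runlen, nbins = n_levels * lmax)
  matrix(cnt, n_levels, lmax, byrow = TRUE)
}

glrlm_features_one <- function(R, n_voxels) {
  nr <- sum(R)
  i <- row(R); j <- col(R)
  p <- R / nr
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(glrlm_ShortRunEmphasis = sum(R / j^2) / nr,
    glrlm_LongRunEmphasis = sum(R * j^2) / nr,
    glrlm_GrayLevelNonUniformity = sum(ri^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    glrlm_RunLengthNonUniformity = sum(rj^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    glrlm_RunPercentage = nr / n_voxels,
    glrlm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    glrlm_RunVariance = sum(p * (j - mu_j)^2),
    glrlm_RunEntropy = entropy_bits(p),
    glrlm_LowGrayLevelRunEmphasis = sum(R / i^2) / nr,
    glrlm_HighGrayLevelRunEmphasis = sum(R * i^2) / nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * j^2)) / nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(R * i^2 / j^2) / nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(R * j^2 / i^2) / nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(R * i^2 * j^2) / nr)
}

#' Gray level run length matrix features
#'
#' Maximal runs of equal gray level along each of the 13 unique 3D lattice
#' directions, restricted to in-mask voxels (a gap in the mask breaks a run);
#' the 16 features are averaged over directions.
#'
#' @param voi a [discretized_voi()].
#' @return Named numeric vector of 16 features, prefix `glrlm_`.
#' @export
glrlm_features <- function(voi) {
  lev <- crop_to_mask(voi$lev)
  n_levels <- max(lev, na.rm = TRUE)
  n_voxels <- sum(!is.na(lev))
  dirs <- unique_directions_3d()
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- glrlm_matrix(lev, dirs[r, ], n_levels)
    f <- glrlm_features_one(R, n_voxels)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}
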