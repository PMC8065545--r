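# Isotropic resampling of (volume, mask) pairs prior to feature extraction.

# Sparse-in-spirit 1D linear interpolation matrix mapping n_in samples at
# `sp_in` spacing onto n_out samples at `sp_out`, voxel-centre aligned.
interp_matrix_1d <- function(n_in, sp_in, n_out, sp_out) {
  pos <- (seq_len(n_out) - 1) * sp_out / sp_in       # in input index units
  pos <- pmin(pmax(pos, 0), n_in - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  if (n_in == 1L) return(matrix(1, n_out, 1))
  w <- pos - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0 + 1)] <- 1 - w
  W[cbind(seq_len(n_out), i0 + 2)] <- W[cbind(seq_len(n_out), i0 + 2)] + w
  W
}

apply_axis <- function(a, W, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- W %*% m
  d2 <- d; d2[axis] <- nrow(W)
  aperm(array(out, dim = d2[perm]), order(perm))
}

#' Resample a volume and mask to isotropic voxel spacing
#'
#' The target spacing is the smallest in-plane spacing, applied on all axes
#' (an upsampling scheme along the coarse slice axis). Intensities are
#' tri-linearly interpolated; the mask is resampled by nearest neighbour on
#' the same voxel-centre grid. Already-isotropic input is returned unchanged.
#'
#' @param volume an `image_volume`.
#' @param mask logical array on the same grid.
#' @return list(volume, mask) at isotropic spacing.
#' @export
resample_isotropic <- function(volume, mask) {
  stopifnot(is_image_volume(volume))
  if (!identical(dim(volume$intensities), dim(mask)))
    stop("mask grid does not match volume grid", call. = FALSE)
  sp <- volume$spacing_mm
  target <- min(sp[1:2])
  if (max(abs(sp - target)) < 1e-9)
    return(list(volume = volume, mask = mask))
  d <- dim(volume$intensities)
  n_out <- pmax(1L, as.integer(round(d * sp / target)))
  a <- volume$intensities
  for (ax in 1:3) {
    if (abs(sp[ax] - target) < 1e-12 && n_out[ax] == d[ax]) next
    a <- apply_axis(a, interp_matrix_1d(d[ax], sp[ax], n_out[ax], target), ax)
  }
  # nearest-neighbour indices per axis for the mask
  nn <- lapply(1:3, function(ax) {
    pos <- (seq_len(n_out[ax]) - 1) * target / sp[ax]
    pmin(pmax(round(pos), 0), d[ax] - 1) + 1L
  })
  m_out <- mask[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
  dim(m_out) <- n_out
  if (!any(m_out))
    stop("VOI empty after resampling", call. = FALSE)
  list(volume = image_volume(a, rep(target, 3), volume$origin), mask = m_out)
}
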