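# Shared machinery for the gray-level texture matrices.
#
# A discretized VOI is represented as an integer 3D array of levels in
# 1..n_bins with NA outside the (re-segmented) mask; all matrices count only
# in-mask voxels/pairs.

#' Build a discretized VOI array
#'
#' @param levels integer levels of the retained in-mask voxels.
#' @param mask logical array; `sum(mask)` must equal `length(levels)`.
#' @param n_bins number of gray levels.
#' @return list with `lev` (integer array, NA outside mask), `n_bins`,
#'   `n_voxels`.
#' @export
discretized_voi <- function(levels, mask, n_bins = 64L) {
  stopifnot(sum(mask) == length(levels))
  lev <- array(NA_integer_, dim = dim(mask))
  lev[mask] <- as.integer(levels)
  list(lev = lev, n_bins = as.integer(n_bins), n_voxels = length(levels))
}

# Crop an NA-padded level array to the mask bounding box (plus nothing).
crop_to_mask <- function(lev) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  rng <- lapply(1:3, function(k) min(idx[, k]):max(idx[, k]))
  out <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  dim(out) <- vapply(rng, length, 1L)
  out
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one per
# +/- pair; the first nonzero component is positive).
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  keep <- apply(g, 1, function(v) {
    nz <- which(v != 0)
    length(nz) > 0 && v[nz[1]] > 0
  })
  unname(g[keep, , drop = FALSE])
}

# NA-filled shift of a level array.
shift_lev <- function(lev, off) {
  d <- dim(lev)
  out <- array(NA_integer_, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o) }
    else        { dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- lev[src[[1]], src[[2]], src[[3]]]
  out
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}
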