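# Internal array and RNG helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shift a 3D array by an integer offset, filling vacated voxels with `fill`.
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o) }
    else        { dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array with per-axis sigma in voxels.
# Edges handled by reflection. sigma[k] <= 0 skips that axis.
smooth_gaussian_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s <= 0) next
    k <- gaussian_kernel_1d(s)
    r <- (length(k) - 1L) / 2L
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), nrow = d[ax])
    n <- nrow(m)
    ridx <- c(pmin(n, r:1), 1:n, pmax(1L, n - (1:r) + 1L))  # reflect-pad
    mp <- m[ridx, , drop = FALSE]
    f <- stats::filter(mp, k, sides = 2)
    m <- matrix(f[(r + 1L):(r + n), ], nrow = n)
    a <- aperm(array(m, dim = d[perm]), order(perm))
  }
  a
}

# Integer offsets whose physical length is <= radius_mm (excluding the origin);
# the discrete ellipsoidal structuring element for mm-scale morphology.
struct_el_offsets <- function(radius_mm, spacing_mm) {
  rv <- floor(radius_mm / spacing_mm)
  if (all(rv < 1)) return(matrix(integer(0), ncol = 3))
  g <- as.matrix(expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2], z = -rv[3]:rv[3]))
  phys2 <- (g[, 1] * spacing_mm[1])^2 + (g[, 2] * spacing_mm[2])^2 +
    (g[, 3] * spacing_mm[3])^2
  g <- g[phys2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- mask
  if (nrow(offsets) == 0) return(out)
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_array(mask, offsets[i, ], fill = FALSE)
  out
}

binary_erode <- function(mask, offsets) {
  out <- mask
  if (nrow(offsets) == 0) return(out)
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_array(mask, offsets[i, ], fill = FALSE)
  out
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Sample skewness (g1, population-moment form); 0 for constant input.
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0 || n < 3) return(0)
  mean((x - m)^3) / s2^1.5
}

# Derive a stream of child seeds from one user seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483647
}
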