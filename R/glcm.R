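# Gray level co-occurrence matrix features.

# Symmetrized, normalized GLCM for one direction; NULL when the direction
# yields no valid in-mask pair.
glcm_matrix <- function(lev, off, n_levels) {
  b <- shift_lev(lev, -off)   # neighbour at +off of each voxel
  ok <- !is.na(lev) & !is.na(b)
  if (!any(ok)) return(NULL)
  a <- lev[ok]; bb <- b[ok]
  idx <- (a - 1L) * n_levels + bb
  cnt <- tabulate(idx, nbins = n_levels * n_levels)
  M <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

glcm_features_one <- function(P) {
  K <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)                       # symmetric: px == py
  mu <- sum(seq_len(K) * px)
  sig2 <- sum((seq_len(K) - mu)^2 * px)
  contrast <- sum(P * (i - j)^2)
  # difference distribution p_{|i-j|}(k), k = 0..K-1
  dk <- 0:(K - 1)
  pd <- vapply(dk, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(dk * pd)
  # sum distribution p_{i+j}(k), k = 2..2K
  sk <- 2:(2 * K)
  ps <- vapply(sk, function(k) sum(P[(i + j) == k]), numeric(1))
  hxy <- entropy_bits(P)
  hx <- entropy_bits(px)
  PxPy <- outer(px, px)
  nz <- P > 0
  hxy1 <- -sum(P[nz & PxPy > 0] * log2(PxPy[nz & PxPy > 0]))
  hxy2 <- entropy_bits(PxPy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(P * i * j) - mu^2) / sig2 else 1
  # Maximal correlation coefficient on occupied levels
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Po <- P[occ, occ, drop = FALSE]
    pxo <- px[occ]
    # Q[a,b] = sum_k P[a,k] P[b,k] / (px[a] px[k]), using symmetry of P
    Q <- sweep(Po, 1, pxo, "/") %*% sweep(Po, 1, pxo, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  iv_mask <- i != j
  c(glcm_Autocorrelation = sum(P * i * j),
    glcm_JointAverage = mu,
    glcm_ClusterProminence = sum(P * (i + j - 2 * mu)^4),
    glcm_ClusterShade = sum(P * (i + j - 2 * mu)^3),
    glcm_ClusterTendency = sum(P * (i + j - 2 * mu)^2),
    glcm_Contrast = contrast,
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = entropy_bits(pd),
    glcm_DifferenceVariance = sum(pd * (dk - da)^2),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_Idmn = sum(P / (1 + ((i - j) / K)^2)),
    glcm_Idn = sum(P / (1 + abs(i - j) / K)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[iv_mask] / (i[iv_mask] - j[iv_mask])^2),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(sk * ps),
    glcm_SumEntropy = entropy_bits(ps),
    glcm_SumSquares = sig2)
}

#' Gray level co-occurrence matrix features
#'
#' One GLCM per each of the 13 unique 3D directions at Chebyshev distance 1,
#' counting in-mask voxel pairs only, symmetrized and normalized; the 24
#' feature values are averaged over directions. Directions with no valid
#' pair are skipped (with a warning if that leaves none, in which case
#' defined fallbacks are returned: contrast 0, correlation 1, etc.).
#'
#' @param voi a [discretized_voi()].
#' @return Named numeric vector of 24 features, prefix `glcm_`.
#' @export
glcm_features <- function(voi) {
  lev <- crop_to_mask(voi$lev)
  n_levels <- max(lev, na.rm = TRUE)
  dirs <- unique_directions_3d()
  acc <- NULL; nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    P <- glcm_matrix(lev, dirs[r, ], n_levels)
    if (is.null(P)) next
    f <- glcm_features_one(P)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) {
    warning("GLCM: no valid voxel pair in any direction; using fallbacks",
            call. = FALSE)
    return(glcm_features_one(matrix(1, 1, 1)))
  }
  acc / nd
}
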