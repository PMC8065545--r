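# Gray level size zone matrix features.

# Zones: 26-connected components of equal gray level within the mask.
# Returns a data.frame (level, size), one row per zone.
glszm_zones <- function(lev) {
  d <- dim(lev)
  inmask <- which(!is.na(lev))
  n <- length(inmask)
  vid <- array(NA_integer_, dim = d)
  vid[inmask] <- seq_len(n)
  dirs <- unique_directions_3d()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    b <- shift_lev(lev, -dirs[r, ])
    bid <- shift_lev(vid, -dirs[r, ])
    ok <- !is.na(lev) & !is.na(b) & lev == b
    if (!any(ok)) next
    from <- c(from, vid[ok]); to <- c(to, bid[ok])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  comp <- igraph::components(g)
  data.frame(level = as.integer(tapply(lev[inmask], comp$membership, `[`, 1)),
             size = as.integer(comp$csize))
}

glszm_features_one <- function(Z, n_voxels) {
  nz <- sum(Z)
  i <- row(Z); j <- col(Z)
  p <- Z / nz
  zi <- rowSums(Z); zj <- colSums(Z)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(glszm_SmallAreaEmphasis = sum(Z / j^2) / nz,
    glszm_LargeAreaEmphasis = sum(Z * j^2) / nz,
    glszm_GrayLevelNonUniformity = sum(zi^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(zi^2) / nz^2,
    glszm_SizeZoneNonUniformity = sum(zj^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(zj^2) / nz^2,
    glszm_ZonePercentage = nz / n_voxels,
    glszm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    glszm_ZoneVariance = sum(p * (j - mu_j)^2),
    glszm_ZoneEntropy = entropy_bits(p),
    glszm_LowGrayLevelZoneEmphasis = sum(Z / i^2) / nz,
    glszm_HighGrayLevelZoneEmphasis = sum(Z * i^2) / nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(Z / (i^2 * j^2)) / nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(Z * i^2 / j^2) / nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(Z * j^2 / i^2) / nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(Z * i^2 * j^2) / nz)
}

#' Gray level size zone matrix features
#'
#' Zones are 26-connected components of equal gray level within the mask;
#' the matrix is direction-free. 16 features, prefix `glszm_`.
#'
#' @param voi a [discretized_voi()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(voi) {
  lev <- crop_to_mask(voi$lev)
  zones <- glszm_zones(lev)
  n_levels <- max(lev, na.rm = TRUE)
  smax <- max(zones$size)
  Z <- matrix(0, n_levels, smax)
  cnt <- tabulate((zones$level - 1L) * smax + zones$size,
                  nbins = n_levels * smax)
  Z <- matrix(cnt, n_levels, smax, byrow = TRUE)
  glszm_features_one(Z, sum(!is.na(lev)))
}
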