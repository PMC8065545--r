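# Neighborhood gray tone difference matrix features.

# Per occupied level i: n_i (count of in-mask voxels of level i having at
# least one in-mask 26-neighbour) and s_i (sum over those voxels of
# |i - mean of its in-mask 26-neighbours|).
ngtdm_table <- function(lev) {
  d <- dim(lev)
  dirs <- unique_directions_3d()
  nsum <- array(0, dim = d)
  ncnt <- array(0, dim = d)
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1, -1)) {
      b <- shift_lev(lev, sgn * dirs[r, ])
      ok <- !is.na(b)
      nsum[ok] <- nsum[ok] + b[ok]
      ncnt <- ncnt + ok
    }
  }
  inm <- !is.na(lev) & ncnt > 0
  v <- lev[inm]
  diffs <- abs(v - nsum[inm] / ncnt[inm])
  levels <- sort(unique(v))
  data.frame(level = levels,
             n_i = as.numeric(tabulate(factor(v, levels = levels))),
             s_i = as.numeric(tapply(diffs, factor(v, levels = levels), sum)))
}

#' Neighborhood gray tone difference matrix features
#'
#' The 5 descriptors (coarseness, contrast, busyness, complexity, strength)
#' from per-level sums of absolute deviation between a voxel's level and the
#' mean level of its in-mask 26-neighbourhood. Division-by-zero fallbacks:
#' coarseness capped at 1e6 for a perfectly uniform VOI; contrast 0 with a
#' single occupied level; busyness and strength 0 when their denominators
#' vanish.
#'
#' @param voi a [discretized_voi()].
#' @return Named numeric vector of 5 features, prefix `ngtdm_`.
#' @export
ngtdm_features <- function(voi) {
  lev <- crop_to_mask(voi$lev)
  tab <- ngtdm_table(lev)
  nvc <- sum(tab$n_i)
  p <- tab$n_i / nvc
  s <- tab$s_i
  lv <- tab$level
  ngp <- nrow(tab)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (ngp > 1) {
    pij <- outer(p, p)
    dij2 <- outer(lv, lv, "-")^2
    contrast <- sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s) / nvc
  } else contrast <- 0
  busy_den <- sum(abs(outer(lv * p, lv * p, "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  if (ngp > 1) {
    psum <- outer(p, p, "+")
    num <- outer(p * s, p * s, "+")
    complexity <- sum(abs(outer(lv, lv, "-")) * num / psum) / nvc
    strength_num <- sum(outer(p, p, "+") * outer(lv, lv, "-")^2)
    strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  } else { complexity <- 0; strength <- 0 }
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}
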