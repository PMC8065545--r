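# Morphological (shape) features from the binary VOI mask.
#
# Surface area and mesh volume come from a triangulated iso-surface of the
# mask indicator, extracted by marching tetrahedra on the Kuhn 6-tetrahedra
# decomposition of each grid cube. The indicator is lightly Gaussian-smoothed
# before iso-surfacing (0.5 level) to suppress voxelization bias in the area
# estimate; masks too small to survive smoothing fall back to the raw binary
# field.

kuhn_tetrahedra <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    v <- matrix(0, 4, 3)
    v[2, p[1]] <- 1
    v[3, p[1:2]] <- 1
    v[4, ] <- 1
    v
  })
}

# Iso-surface (level) of scalar field f; returns total triangle area and the
# enclosed volume via the divergence theorem, in the units of `spacing`.
mesh_surface <- function(f, spacing, level = 0.5) {
  d <- dim(f)
  nc <- d - 1L
  if (any(nc < 1L)) return(list(area = 0, volume = 0, n_triangles = 0L))
  # corner values of every cube, as 8 vectors over cubes
  corner <- function(o) {
    f[(1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]),
      (1 + o[3]):(nc[3] + o[3])]
  }
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cv <- lapply(seq_len(8), function(i) as.numeric(corner(offs[i, ])))
  vmin <- Reduce(pmin, cv); vmax <- Reduce(pmax, cv)
  cand <- which(vmin < level & vmax >= level)
  if (length(cand) == 0) return(list(area = 0, volume = 0, n_triangles = 0L))
  base <- arrayInd(cand, nc) - 1L   # cube origin in voxel units
  cvc <- vapply(cv, `[`, numeric(length(cand)), cand)  # ncand x 8

  corner_id <- function(o) 1L + o[1] + 2L * o[2] + 4L * o[3]
  area <- 0; volume <- 0; ntri <- 0L
  sp <- spacing

  emit <- function(P1, P2, P3, inside_c, outside_c) {
    # orient triangles so normals point from inside to outside, then
    # accumulate area and signed volume
    e1 <- P2 - P1; e2 <- P3 - P1
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    ref <- outside_c - inside_c
    flip <- nx * ref[, 1] + ny * ref[, 2] + nz * ref[, 3] < 0
    if (any(flip)) {
      tmp <- P2[flip, , drop = FALSE]
      P2[flip, ] <- P3[flip, , drop = FALSE]
      P3[flip, ] <- tmp
      nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]; nz[flip] <- -nz[flip]
    }
    area <<- area + sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
    # signed volume of tetrahedra (origin, P1, P2, P3), outward orientation
    volume <<- volume + sum(
      P1[, 1] * (P2[, 2] * P3[, 3] - P2[, 3] * P3[, 2]) +
      P1[, 2] * (P2[, 3] * P3[, 1] - P2[, 1] * P3[, 3]) +
      P1[, 3] * (P2[, 1] * P3[, 2] - P2[, 2] * P3[, 1])) / 6
    ntri <<- ntri + nrow(P1)
  }

  for (tet in kuhn_tetrahedra()) {
    ids <- apply(tet, 1, corner_id)
    V <- cvc[, ids, drop = FALSE]                 # ncand x 4 corner values
    inside <- V >= level
    pat <- inside %*% c(1L, 2L, 4L, 8L)
    # physical corner coordinates: (base + tet corner) * spacing
    coords <- lapply(1:4, function(k)
      sweep(base, 2, tet[k, ], "+") %*% diag(sp))
    interp <- function(rows, a, b) {
      t <- (level - V[rows, a]) / (V[rows, b] - V[rows, a])
      coords[[a]][rows, , drop = FALSE] * (1 - t) +
        coords[[b]][rows, , drop = FALSE] * t
    }
    centroid <- function(rows, ks) {
      out <- 0
      for (k in ks) out <- out + coords[[k]][rows, , drop = FALSE]
      out / length(ks)
    }
    for (p in 1:14) {
      rows <- which(pat == p)
      if (length(rows) == 0) next
      ins <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0)
      outs <- setdiff(1:4, ins)
      ci <- centroid(rows, ins); co <- centroid(rows, outs)
      if (length(ins) == 1) {
        a <- ins
        emit(interp(rows, a, outs[1]), interp(rows, a, outs[2]),
             interp(rows, a, outs[3]), ci, co)
      } else if (length(ins) == 3) {
        a <- outs
        emit(interp(rows, ins[1], a), interp(rows, ins[2], a),
             interp(rows, ins[3], a), ci, co)
      } else {
        a <- ins[1]; b <- ins[2]; cc <- outs[1]; dd <- outs[2]
        p_ac <- interp(rows, a, cc); p_ad <- interp(rows, a, dd)
        p_bd <- interp(rows, b, dd); p_bc <- interp(rows, b, cc)
        emit(p_ac, p_ad, p_bd, ci, co)
        emit(p_ac, p_bd, p_bc, ci, co)
      }
    }
  }
  list(area = area, volume = abs(volume), n_triangles = ntri)
}

mask_surface_mesh <- function(mask, spacing_mm, smooth_sigma = 0.7) {
  d <- dim(mask)
  pad <- max(2L, ceiling(3 * smooth_sigma) + 1L)  # keep the surface closed
  padded <- array(0, dim = d + 2L * pad)
  padded[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- as.numeric(mask)
  f <- smooth_gaussian_3d(padded, rep(smooth_sigma, 3))
  if (max(f) <= 0.5) f <- padded   # tiny mask: smoothing washed it out
  mesh_surface(f, spacing_mm, level = 0.5)
}

boundary_voxels <- function(mask) {
  inner <- mask
  for (ax in 1:3) {
    o <- c(0L, 0L, 0L)
    o[ax] <- 1L
    inner <- inner & shift_array(mask, o, FALSE) & shift_array(mask, -o, FALSE)
  }
  mask & !inner
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(pts^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Morphological features of a binary VOI
#'
#' Computes the 14 shape descriptors used by the pipeline: mesh volume, voxel
#' volume, surface area, surface-to-volume ratio, sphericity, maximum 3D
#' diameter, three maximum 2D diameters (axial/coronal/sagittal planes),
#' the three principal axis lengths, elongation and flatness. Sphericity is
#' (36 pi V^2)^(1/3) / A with mesh-based V and A; axis lengths are
#' 4 sqrt(lambda) for the eigenvalues of the physical voxel-coordinate
#' covariance, with elongation sqrt(l2/l1) and flatness sqrt(l3/l1)
#' (l1 >= l2 >= l3). A degenerate (isotropically point-like) mask has
#' elongation and flatness 1 by convention.
#'
#' @param mask logical 3D array, nonempty.
#' @param spacing_mm voxel spacing (mm).
#' @return Named numeric vector of 14 features, prefix `shape_`.
#' @export
shape_features <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  # every shape descriptor is translation-invariant: crop to the bounding box
  bb <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(k) min(bb[, k]):max(bb[, k]))
  mask <- mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  dim(mask) <- vapply(rng, length, 1L)
  mesh <- mask_surface_mesh(mask, spacing_mm)
  A <- mesh$area
  V_mesh <- mesh$volume
  V_vox <- sum(mask) * prod(spacing_mm)
  if (V_mesh <= 0) V_mesh <- V_vox   # degenerate sub-voxel mesh
  if (A <= 0) A <- 2 * (prod(spacing_mm[c(1, 2)]) + prod(spacing_mm[c(1, 3)]) +
                          prod(spacing_mm[c(2, 3)]))  # single-voxel cube

  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing_mm, "*")
  n <- nrow(pts)
  if (n >= 2) {
    cv <- stats::cov(pts)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  if (ev[1] <= 0) {
    elongation <- 1; flatness <- 1
  } else {
    elongation <- sqrt(ev[2] / ev[1])
    flatness <- sqrt(ev[3] / ev[1])
  }

  bnd <- boundary_voxels(mask)
  bidx <- which(bnd, arr.ind = TRUE)
  bpts <- sweep(bidx - 1, 2, spacing_mm, "*")
  max3d <- max_pairwise_distance(bpts)
  max2d <- function(plane_axes, slice_axis) {
    best <- 0
    for (s in unique(bidx[, slice_axis])) {
      rows <- bidx[, slice_axis] == s
      best <- max(best,
                  max_pairwise_distance(bpts[rows, plane_axes, drop = FALSE]))
    }
    best
  }

  sph <- (36 * pi * V_mesh^2)^(1 / 3) / A
  c(shape_MeshVolume = V_mesh,
    shape_VoxelVolume = V_vox,
    shape_SurfaceArea = A,
    shape_SurfaceVolumeRatio = A / V_mesh,
    shape_Sphericity = sph,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = max2d(c(1, 2), 3),
    shape_Maximum2DDiameterColumn = max2d(c(1, 3), 2),
    shape_Maximum2DDiameterRow = max2d(c(2, 3), 1),
    shape_MajorAxisLength = 4 * sqrt(ev[1]),
    shape_MinorAxisLength = 4 * sqrt(ev[2]),
    shape_LeastAxisLength = 4 * sqrt(ev[3]),
    shape_Elongation = elongation,
    shape_Flatness = flatness)
}
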