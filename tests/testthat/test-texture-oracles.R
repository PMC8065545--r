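# Texture matrices against independent brute-force enumeration, plus the
# hand-derived worked examples for each family.

dirs13 <- radpipe:::unique_directions_3d()

test_that("there are exactly 13 unique 3D directions at Chebyshev distance 1", {
  expect_equal(nrow(dirs13), 13)
  # no two directions are negatives of each other
  keys <- apply(dirs13, 1, paste, collapse = ",")
  neg <- apply(-dirs13, 1, paste, collapse = ",")
  expect_length(intersect(keys, neg), 0)
})

test_that("GLCM matches pair enumeration on random masked grids", {
  for (s in 1:12) {
    lev <- random_voi(dim3 = c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1)),
                      n_levels = sample(2:4, 1), p_mask = 0.7, seed = s)
    K <- max(lev, na.rm = TRUE)
    for (r in sample(13, 4)) {
      got <- radpipe:::glcm_matrix(lev, dirs13[r, ], K)
      want <- oracle_glcm_matrix(lev, dirs13[r, ], K)
      if (is.null(want)) expect_null(got)
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("GLCM features match independent formulas on enumerated matrices", {
  for (s in 1:8) {
    lev <- random_voi(dim3 = c(4, 5, 4), n_levels = 4, p_mask = 0.8, seed = 100 + s)
    K <- max(lev, na.rm = TRUE)
    P <- oracle_glcm_matrix(lev, dirs13[1, ], K)
    got <- radpipe:::glcm_features_one(P)
    want <- oracle_glcm_features(P)
    for (f in names(want))
      expect_equal(unname(got[paste0("glcm_", f)]), unname(want[f]),
                   tolerance = 1e-10, label = f)
  }
})

test_that("the 1D-strip GLCM worked example holds", {
  # strip [1,2,1,2]: one direction gives symmetric counts {(1,2):3,(2,1):3}
  lev <- array(NA_integer_, dim = c(4, 1, 1))
  lev[, 1, 1] <- c(1L, 2L, 1L, 2L)
  P <- radpipe:::glcm_matrix(lev, c(1, 0, 0), 2)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-15)
  f <- radpipe:::glcm_features_one(P)
  expect_equal(unname(f["glcm_InverseVariance"]), 1.0)
})

test_that("a symmetric-marginal GLCM has zero cluster shade", {
  P <- matrix(c(0.2, 0.1, 0.1, 0.1, 0.0, 0.1, 0.1, 0.1, 0.2), 3, 3)
  expect_equal(unname(radpipe:::glcm_features_one(P)["glcm_ClusterShade"]), 0,
               tolerance = 1e-14)
})

test_that("constant VOI gives the documented GLCM fallbacks", {
  lev <- array(1L, dim = c(3, 3, 3))
  f <- glcm_features(voi_from_lev(lev))
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_ClusterShade"]), 0)
  expect_equal(unname(f["glcm_Correlation"]), 1)
})

test_that("GLRLM matches the naive run scanner on random masked grids", {
  for (s in 1:12) {
    lev <- random_voi(dim3 = c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1)),
                      n_levels = sample(2:4, 1), p_mask = 0.75, seed = 20 + s)
    K <- max(lev, na.rm = TRUE)
    for (r in sample(13, 4)) {
      got <- radpipe:::glrlm_matrix(lev, dirs13[r, ], K)
      want <- oracle_glrlm_matrix(lev, dirs13[r, ], K)
      expect_equal(got, want, tolerance = 0)
    }
  }
})

test_that("GLRLM features agree with independent formulas and the strip example", {
  lev <- array(NA_integer_, dim = c(3, 1, 1))
  lev[, 1, 1] <- c(1L, 1L, 2L)
  R <- radpipe:::glrlm_matrix(lev, c(1, 0, 0), 2)
  f <- radpipe:::glrlm_features_one(R, 3)
  expect_equal(unname(f["glrlm_ShortRunHighGrayLevelEmphasis"]), 2.125)
  # constant strip of length L: one run among L voxels
  levc <- array(1L, dim = c(7, 1, 1))
  Rc <- radpipe:::glrlm_matrix(levc, c(1, 0, 0), 1)
  fc <- radpipe:::glrlm_features_one(Rc, 7)
  expect_equal(unname(fc["glrlm_RunPercentage"]), 1 / 7)
  for (s in 1:6) {
    lev <- random_voi(c(5, 5, 5), 3, 0.8, seed = 40 + s)
    K <- max(lev, na.rm = TRUE)
    R <- oracle_glrlm_matrix(lev, dirs13[5, ], K)
    got <- radpipe:::glrlm_features_one(R, sum(!is.na(lev)))
    want <- oracle_glrlm_features(R, sum(!is.na(lev)))
    expect_equal(unname(got["glrlm_ShortRunEmphasis"]), unname(want["SRE"]),
                 tolerance = 1e-12)
    expect_equal(unname(got["glrlm_LongRunLowGrayLevelEmphasis"]),
                 unname(want["LRLGLE"]), tolerance = 1e-12)
    expect_equal(unname(got["glrlm_GrayLevelNonUniformity"]),
                 unname(want["GLN"]), tolerance = 1e-12)
  }
})

test_that("GLSZM zones match recursive flood fill on random masked grids", {
  for (s in 1:12) {
    lev <- random_voi(dim3 = c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1)),
                      n_levels = sample(2:4, 1), p_mask = 0.7, seed = 60 + s)
    got <- radpipe:::glszm_zones(lev)
    want <- oracle_glszm_zones(lev)
    key <- function(z) sort(paste(z$level, z$size, sep = ":"))
    expect_equal(key(got), key(want))
  }
})

test_that("GLSZM worked examples and independent formulas hold", {
  # constant VOI of n voxels: single zone; SAHGLE = 1/n^2, LAHGLE = n^2
  lev <- array(1L, dim = c(2, 3, 1))
  f <- glszm_features(voi_from_lev(lev))
  expect_equal(unname(f["glszm_SmallAreaHighGrayLevelEmphasis"]), 1 / 36)
  expect_equal(unname(f["glszm_LargeAreaHighGrayLevelEmphasis"]), 36)
  # two disjoint level-2 zones of sizes 1 and 3
  lev2 <- array(NA_integer_, dim = c(7, 1, 1))
  lev2[c(1, 3, 4, 5), 1, 1] <- 2L
  f2 <- glszm_features(voi_from_lev(lev2))
  expect_equal(unname(f2["glszm_SmallAreaHighGrayLevelEmphasis"]),
               (4 / 1 + 4 / 9) / 2, tolerance = 1e-12)
  for (s in 1:6) {
    lev <- random_voi(c(5, 4, 5), 3, 0.7, seed = 80 + s)
    zones <- oracle_glszm_zones(lev)
    got <- glszm_features(voi_from_lev(lev))
    want <- oracle_glszm_features(zones, sum(!is.na(lev)))
    for (pair in list(c("glszm_SmallAreaEmphasis", "SAE"),
                      c("glszm_LargeAreaEmphasis", "LAE"),
                      c("glszm_SmallAreaHighGrayLevelEmphasis", "SAHGLE"),
                      c("glszm_LargeAreaHighGrayLevelEmphasis", "LAHGLE"),
                      c("glszm_ZonePercentage", "ZonePercentage")))
      expect_equal(unname(got[pair[1]]), unname(want[pair[2]]),
                   tolerance = 1e-10, label = pair[1])
  }
})

test_that("NGTDM table matches the per-voxel neighbourhood loop", {
  for (s in 1:12) {
    lev <- random_voi(dim3 = c(4, 4, 4), n_levels = sample(2:4, 1),
                      p_mask = 0.75, seed = 120 + s)
    got <- radpipe:::ngtdm_table(lev)
    want <- oracle_ngtdm_table(lev)
    expect_equal(got$level, want$level)
    expect_equal(got$n_i, want$n_i, tolerance = 1e-12)
    expect_equal(got$s_i, want$s_i, tolerance = 1e-10)
  }
})

test_that("NGTDM worked examples hold", {
  # 3x3x1 plane with a level-2 centre among level-1 neighbours: s_2 = 1
  lev <- array(1L, dim = c(3, 3, 1))
  lev[2, 2, 1] <- 2L
  tab <- radpipe:::ngtdm_table(lev)
  expect_equal(tab$s_i[tab$level == 2], 1)
  # constant VOI: all s_i zero, contrast and busyness fall back to 0
  f <- ngtdm_features(voi_from_lev(array(3L, dim = c(3, 3, 2))))
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
  expect_equal(unname(f["ngtdm_Busyness"]), 0)
})
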