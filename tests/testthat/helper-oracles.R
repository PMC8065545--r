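# Independent brute-force oracles for the texture matrices and the
# statistical tests, plus small fixture builders. Everything here is written
# as plainly as possible (explicit loops, no shared code with the package
# implementation) so it can serve as a reference enumeration.

# ---- fixtures ---------------------------------------------------------------

random_voi <- function(dim3 = c(5, 5, 5), n_levels = 4, p_mask = 0.7,
                       seed = 1) {
  set.seed(seed)
  mask <- array(runif(prod(dim3)) < p_mask, dim = dim3)
  if (!any(mask)) mask[1] <- TRUE
  lev <- array(NA_integer_, dim = dim3)
  lev[mask] <- sample.int(n_levels, sum(mask), replace = TRUE)
  lev
}

voi_from_lev <- function(lev, n_bins = 64L) {
  list(lev = lev, n_bins = as.integer(n_bins), n_voxels = sum(!is.na(lev)))
}

# Solid digitized ball of radius r voxels in an n^3 grid.
digitized_ball <- function(r, n = 2 * r + 5) {
  cx <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  array((g$i - cx)^2 + (g$j - cx)^2 + (g$k - cx)^2 <= r^2, dim = c(n, n, n))
}

# Axis-aligned solid ellipsoid with semi-axes (mm) on an isotropic grid.
digitized_ellipsoid <- function(semi_mm, spacing = 1) {
  n <- ceiling(2 * semi_mm / spacing) + 5
  ctr <- (n + 1) / 2
  g <- expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3])
  q <- ((g$i - ctr[1]) * spacing / semi_mm[1])^2 +
       ((g$j - ctr[2]) * spacing / semi_mm[2])^2 +
       ((g$k - ctr[3]) * spacing / semi_mm[3])^2
  array(q <= 1, dim = n)
}

all_directions_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

# ---- GLCM oracle: enumerate every ordered voxel pair ------------------------

oracle_glcm_matrix <- function(lev, off, n_levels) {
  d <- dim(lev)
  M <- matrix(0, n_levels, n_levels)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    for (sgn in c(1, -1)) {
      ii <- i + sgn * off[1]; jj <- j + sgn * off[2]; kk <- k + sgn * off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      b <- lev[ii, jj, kk]
      if (!is.na(b)) M[a, b] <- M[a, b] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

# Independent formulas for a structurally diverse GLCM feature subset.
oracle_glcm_features <- function(P) {
  K <- nrow(P)
  out <- c(Contrast = 0, InverseVariance = 0, ClusterShade = 0,
           Autocorrelation = 0, JointEntropy = 0, MaximumProbability = max(P),
           JointEnergy = 0, Id = 0, SumSquares = 0, Correlation = 0)
  mu <- 0
  for (i in 1:K) for (j in 1:K) mu <- mu + i * P[i, j]
  sig2 <- 0
  for (i in 1:K) for (j in 1:K) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  cor_num <- 0
  for (i in 1:K) for (j in 1:K) {
    p <- P[i, j]
    out["Contrast"] <- out["Contrast"] + p * (i - j)^2
    if (i != j) out["InverseVariance"] <- out["InverseVariance"] + p / (i - j)^2
    out["ClusterShade"] <- out["ClusterShade"] + p * (i + j - 2 * mu)^3
    out["Autocorrelation"] <- out["Autocorrelation"] + p * i * j
    if (p > 0) out["JointEntropy"] <- out["JointEntropy"] - p * log2(p)
    out["JointEnergy"] <- out["JointEnergy"] + p^2
    out["Id"] <- out["Id"] + p / (1 + abs(i - j))
    out["SumSquares"] <- out["SumSquares"] + p * (i - mu)^2
    cor_num <- cor_num + p * i * j
  }
  out["Correlation"] <- if (sig2 > 0) (cor_num - mu^2) / sig2 else 1
  out
}

# ---- GLRLM oracle: naive run scanner ----------------------------------------

oracle_glrlm_matrix <- function(lev, off, n_levels) {
  d <- dim(lev)
  runs <- list()
  visited <- array(FALSE, dim = d)   # voxels already assigned for this dir
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    p <- c(i, j, k)
    if (is.na(lev[i, j, k]) || visited[i, j, k]) next
    prev <- p - off
    # start of a run only if the predecessor is outside/masked/different
    if (inb(prev) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == lev[i, j, k]) next
    len <- 0
    q <- p
    while (inb(q) && !is.na(lev[q[1], q[2], q[3]]) &&
           lev[q[1], q[2], q[3]] == lev[i, j, k]) {
      visited[q[1], q[2], q[3]] <- TRUE
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(lev[i, j, k], len)
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, n_levels, lmax)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_glrlm_features <- function(R, n_voxels) {
  nr <- sum(R)
  out <- c(SRE = 0, LRE = 0, SRHGLE = 0, LRLGLE = 0, HGLRE = 0,
           RunPercentage = nr / n_voxels, GLN = 0, RLN = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    out["SRE"] <- out["SRE"] + r / j^2
    out["LRE"] <- out["LRE"] + r * j^2
    out["SRHGLE"] <- out["SRHGLE"] + r * i^2 / j^2
    out["LRLGLE"] <- out["LRLGLE"] + r * j^2 / i^2
    out["HGLRE"] <- out["HGLRE"] + r * i^2
  }
  for (i in seq_len(nrow(R))) out["GLN"] <- out["GLN"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) out["RLN"] <- out["RLN"] + sum(R[, j])^2
  out[c("SRE", "LRE", "SRHGLE", "LRLGLE", "HGLRE", "GLN", "RLN")] <-
    out[c("SRE", "LRE", "SRHGLE", "LRLGLE", "HGLRE", "GLN", "RLN")] / nr
  out
}

# ---- GLSZM oracle: recursive flood fill -------------------------------------

oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  labeled <- array(FALSE, dim = d)
  dirs <- all_directions_26()
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k]) || labeled[i, j, k]) next
    val <- lev[i, j, k]
    stack <- list(c(i, j, k))
    labeled[i, j, k] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(dirs))) {
        q <- p + dirs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (labeled[q[1], q[2], q[3]]) next
        if (is.na(lev[q[1], q[2], q[3]]) || lev[q[1], q[2], q[3]] != val) next
        labeled[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  df <- do.call(rbind, zones)
  data.frame(level = df[, 1], size = df[, 2])
}

oracle_glszm_features <- function(zones, n_voxels) {
  nz <- nrow(zones)
  out <- c(SAE = 0, LAE = 0, SAHGLE = 0, LAHGLE = 0, LGLZE = 0,
           ZonePercentage = nz / n_voxels)
  for (z in seq_len(nz)) {
    i <- zones$level[z]; s <- zones$size[z]
    out["SAE"] <- out["SAE"] + 1 / s^2
    out["LAE"] <- out["LAE"] + s^2
    out["SAHGLE"] <- out["SAHGLE"] + i^2 / s^2
    out["LAHGLE"] <- out["LAHGLE"] + i^2 * s^2
    out["LGLZE"] <- out["LGLZE"] + 1 / i^2
  }
  out[c("SAE", "LAE", "SAHGLE", "LAHGLE", "LGLZE")] <-
    out[c("SAE", "LAE", "SAHGLE", "LAHGLE", "LGLZE")] / nz
  out
}

# ---- NGTDM oracle: per-voxel neighbourhood loop -----------------------------

oracle_ngtdm_table <- function(lev) {
  d <- dim(lev)
  dirs <- all_directions_26()
  levels_present <- sort(unique(lev[!is.na(lev)]))
  n_i <- stats::setNames(numeric(length(levels_present)), levels_present)
  s_i <- n_i
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    v <- lev[i, j, k]
    if (is.na(v)) next
    nb <- c()
    for (r in seq_len(nrow(dirs))) {
      q <- c(i, j, k) + dirs[r, ]
      if (any(q < 1) || any(q > d)) next
      w <- lev[q[1], q[2], q[3]]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (length(nb) == 0) next
    key <- as.character(v)
    n_i[key] <- n_i[key] + 1
    s_i[key] <- s_i[key] + abs(v - mean(nb))
  }
  keep <- n_i > 0
  data.frame(level = levels_present[keep], n_i = unname(n_i[keep]),
             s_i = unname(s_i[keep]))
}

# ---- statistical oracles ----------------------------------------------------

# Exact permutation Friedman test for k = 2: enumerate all 2^n within-subject
# swaps; p = fraction of permutations with statistic >= observed.
oracle_friedman_perm_k2 <- function(m) {
  n <- nrow(m)
  stat <- function(mm) {
    r <- t(apply(mm, 1, rank))
    Rj <- colSums(r)
    S <- sum((Rj - n * 3 / 2)^2)
    den <- sum(r^2) - n * 2 * 9 / 4
    if (den <= 0) 0 else S / den
  }
  q_obs <- stat(m)
  count <- 0
  for (b in 0:(2^n - 1)) {
    mm <- m
    for (s in 1:n) if (bitwAnd(b, bitwShiftL(1, s - 1)) > 0)
      mm[s, ] <- mm[s, 2:1]
    if (stat(mm) >= q_obs - 1e-12) count <- count + 1
  }
  count / 2^n
}
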