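# Friedman stability ranking, CoV and redundancy reduction.

test_that("Friedman statistic matches the closed form for strict discordance", {
  # reader 2 strictly above reader 1 for all 8 subjects: R = (8, 16), Q = 8
  m <- cbind(1:8, 1:8 + 0.5)
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 8)
  expect_equal(ft$p_value, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(ft$p_value, 0.00468, tolerance = 1e-3)
})

test_that("fully tied readings give Q = 0, p = 1", {
  m <- cbind(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5))
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
})

test_that("friedman_test agrees with base R on untied data", {
  set.seed(5)
  for (k in 2:4) {
    m <- matrix(rnorm(9 * k), 9, k)
    ours <- friedman_test(m)
    base <- friedman.test(m)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square p agrees with the exact permutation oracle where it matters", {
  # the exact k = 2 permutation distribution is discrete (granularity 2^-n),
  # so pointwise agreement across the whole range is impossible; what the
  # stability decision needs is agreement in the rejection region and a
  # concordant ordering
  set.seed(8)
  p_chi <- p_perm <- numeric(50)
  for (s in 1:50) {
    n <- sample(5:8, 1)
    m <- matrix(rnorm(2 * n), n, 2)
    if (s %% 3 == 0) m[, 2] <- m[, 1] + abs(rnorm(n))   # directional shifts
    p_chi[s] <- friedman_test(m)$p_value
    p_perm[s] <- oracle_friedman_perm_k2(m)
  }
  # decisions at alpha = 0.05 agree except inside the discreteness window
  # just above the threshold (the exact p takes values j/2^n)
  disagree <- (p_chi > 0.05) != (p_perm > 0.05)
  expect_true(all(pmax(p_chi, p_perm)[disagree] <= 0.1))
  # in the rejection tail the approximation is sharp
  tail_idx <- p_perm <= 0.1
  expect_true(any(tail_idx))
  expect_true(all(abs(p_chi[tail_idx] - p_perm[tail_idx]) < 0.05))
  # orderings agree
  expect_gt(cor(p_chi, p_perm, method = "spearman"), 0.9)
})

test_that("stability_rank flags copies stable and shifted features unstable", {
  set.seed(12)
  n <- 12
  r1 <- data.frame(patient_id = sprintf("P%02d", 1:n),
                   f_copy = rnorm(n), f_shift = rnorm(n), f_noise = rnorm(n))
  r2 <- r1
  r2$f_shift <- r1$f_shift + 2          # consistent reader-2 bias
  r2$f_noise <- r1$f_noise + rnorm(n, 0, 1e-3) * sample(c(-1, 1), n, TRUE)
  rep_ <- stability_rank(list(reader1 = r1, reader2 = r2))
  expect_true(rep_$stable[rep_$feature == "f_copy"])
  expect_equal(rep_$p_value[rep_$feature == "f_copy"], 1)
  expect_false(rep_$stable[rep_$feature == "f_shift"])
  expect_lt(rep_$p_value[rep_$feature == "f_shift"], 0.05)
  expect_setequal(rep_$rank, 1:3)
  # column order does not affect any p-value
  rep_sh <- stability_rank(list(reader1 = r1[, c(1, 4, 2, 3)],
                                reader2 = r2[, c(1, 4, 2, 3)]))
  expect_equal(
    rep_sh$p_value[match(rep_$feature, rep_sh$feature)], rep_$p_value)
})

test_that("directionally shifted features are consistently unstable (n >= 10)", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 10
    r1 <- data.frame(patient_id = sprintf("P%02d", 1:n), f = rnorm(n))
    r2 <- r1; r2$f <- r1$f + runif(n, 0.1, 0.5)
    rep_ <- stability_rank(list(r1 = r1, r2 = r2))
    expect_false(rep_$stable[1])
    # an exact copy stays stable when appended agreement rows arrive
    r1b <- rbind(r1, data.frame(patient_id = "P99", f = 0.5))
    r2b <- rbind(r2, data.frame(patient_id = "P99", f = 0.5))
    r2b$f[1:n] <- r1b$f[1:n]
    rep_b <- stability_rank(list(r1 = r1b, r2 = r2b))
    expect_true(rep_b$stable[1])
  }
})

test_that("stability_rank requires aligned patients", {
  r1 <- data.frame(patient_id = c("A", "B"), f = c(1, 2))
  r2 <- data.frame(patient_id = c("B", "A"), f = c(1, 2))
  expect_error(stability_rank(list(r1, r2)), "patient mismatch")
})

test_that("coefficient of variation is sd/|mean| and scale invariant", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  x <- rexp(20)
  expect_equal(coefficient_of_variation(3.7 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
  expect_warning(v <- coefficient_of_variation(c(-1, 1)), "Inf")
  expect_identical(v, Inf)
})

test_that("redundancy reduction clusters correlated features by max CoV", {
  set.seed(33)
  n <- 40
  f1 <- rexp(n) + 1                      # CoV around 0.4-0.5
  tab <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    f1 = f1,
                    f2 = 2 * f1,                 # r = 1 with f1, same CoV
                    f3 = f1 + 10,                # r = 1, much smaller CoV
                    g1 = rnorm(n, 50, 5),
                    g2 = rnorm(n, 50, 5))        # independent
  rr <- redundancy_reduce(tab, c("f1", "f2", "f3", "g1", "g2"), 0.8)
  cl_sizes <- sort(vapply(rr$clusters, length, 1L))
  expect_equal(cl_sizes, c(1L, 1L, 3L))
  # representative of the correlated cluster is the highest-CoV member
  big <- rr$clusters[[which(vapply(rr$clusters, length, 1L) == 3)]]
  expect_setequal(big, c("f1", "f2", "f3"))
  rep_big <- intersect(rr$representatives, big)
  expect_true(rr$cov[rep_big] >= max(rr$cov[big]) - 1e-12)
  expect_false("f3" == rep_big)
  # independent noise features are retained as their own representatives
  expect_true(all(c("g1", "g2") %in% rr$representatives))
})

test_that("every pruned feature correlates above threshold with its cluster", {
  set.seed(44)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 8), n))
  names(X) <- paste0("v", 1:8)
  X$v2 <- X$v1 * 0.95 + rnorm(n, 0, 0.1)
  X$v5 <- -X$v4 + rnorm(n, 0, 0.05)      # anti-correlated duplicate
  X <- cbind(patient_id = sprintf("P%02d", 1:n), X)
  rr <- redundancy_reduce(X, paste0("v", 1:8), 0.8)
  pruned <- setdiff(paste0("v", 1:8), rr$representatives)
  for (f in pruned) {
    cl <- rr$clusters[[which(vapply(rr$clusters, function(c) f %in% c, TRUE))]]
    expect_gt(max(abs(rr$cor_matrix[f, setdiff(cl, f)])), 0.8)
  }
})

test_that("constant features get zero correlation and never block others", {
  tab <- data.frame(patient_id = c("A", "B", "C"),
                    c1 = c(5, 5, 5), f1 = c(1, 2, 3))
  expect_warning(rr <- redundancy_reduce(tab, c("c1", "f1"), 0.8), "constant")
  expect_setequal(rr$representatives, c("c1", "f1"))
  expect_equal(unname(rr$cov["c1"]), 0)
})
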