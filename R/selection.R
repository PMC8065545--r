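# Inter-reader stability ranking and redundancy reduction.

#' Friedman rank test for repeated measurements
#'
#' Within-subject mid-ranks across k conditions; the tie-corrected statistic
#' Q = (k-1) sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)
#' is referred to a chi-square distribution with k-1 degrees of freedom.
#' With every subject fully tied the statistic is 0/0; this is interpreted as
#' no evidence of a condition effect (Q = 0, p = 1). With k = 2 conditions
#' the test reduces to a sign test on the paired differences.
#'
#' @param readings n x k numeric matrix: one row per subject, one column per
#'   condition (here: reader).
#' @return list(statistic, p_value, df).
#' @export
friedman_test <- function(readings) {
  readings <- as.matrix(readings)
  n <- nrow(readings); k <- ncol(readings)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  r <- t(apply(readings, 1, rank))
  Rj <- colSums(r)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0)
    return(list(statistic = 0, p_value = 1, df = k - 1))
  Q <- (k - 1) * S / denom
  list(statistic = Q, p_value = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
       df = k - 1)
}

#' Rank features by inter-reader stability
#'
#' For each feature, applies the Friedman test across readers (subjects =
#' patients); a feature is called stable when its p-value strictly exceeds
#' `alpha`. The stability rank orders features by descending p (most stable
#' first), ties broken by the feature's position in the table.
#'
#' @param tables named list of per-reader feature data.frames, identical
#'   `patient_id` columns and feature columns.
#' @param alpha stability threshold on the Friedman p-value.
#' @return data.frame (feature, statistic, p_value, stable, rank), one row
#'   per feature, ordered by rank.
#' @export
stability_rank <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 2)
  ids <- tables[[1]]$patient_id
  for (t in tables)
    if (!identical(t$patient_id, ids))
      stop("patient mismatch between reader tables", call. = FALSE)
  feats <- setdiff(colnames(tables[[1]]), "patient_id")
  res <- lapply(feats, function(f) {
    m <- vapply(tables, function(t) t[[f]], numeric(length(ids)))
    ft <- friedman_test(m)
    data.frame(feature = f, statistic = ft$statistic, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$stable <- out$p_value > alpha
  ord <- order(-out$p_value, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean; scale-free
#' dispersion used to pick cluster representatives. A zero mean yields +Inf
#' (with a warning): such a feature only wins representative selection if
#' every competitor is also degenerate.
#'
#' @param values numeric vector.
#' @return Nonnegative scalar (possibly Inf).
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 1)
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  if (m == 0) {
    if (s == 0) return(0)
    warning("zero-mean feature: CoV undefined, returning Inf", call. = FALSE)
    return(Inf)
  }
  s / abs(m)
}

#' Correlation-based redundancy reduction
#'
#' Computes the Pearson correlation of candidate features across patients,
#' links every pair with |r| > `r_threshold`, and reduces each connected
#' component of that graph to a single representative: the member with the
#' highest coefficient of variation (ties broken by candidate order).
#' Constant features correlate with nothing (their correlations are set to 0,
#' with a warning) and have CoV 0.
#'
#' @param feature_table data.frame with a `patient_id` column (ignored) and
#'   feature columns; >= 2 rows.
#' @param candidates character vector of feature columns to consider.
#' @param r_threshold redundancy threshold on |r|, default 0.8.
#' @return list(clusters, representatives, cor_matrix, cov): `clusters` is a
#'   list of feature-name vectors partitioning the candidates,
#'   `representatives` the selected feature per cluster (same order).
#' @export
redundancy_reduce <- function(feature_table, candidates, r_threshold = 0.8) {
  stopifnot(all(candidates %in% colnames(feature_table)))
  X <- as.matrix(feature_table[, candidates, drop = FALSE])
  if (nrow(X) < 2) stop("need >= 2 patients", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("%d constant feature(s): correlations set to 0",
                    sum(sds == 0)), call. = FALSE)
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  covs <- vapply(candidates, function(f)
    suppressWarnings(coefficient_of_variation(X[, f])), numeric(1))
  adj <- abs(C) > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(candidates, comp)
  names(clusters) <- NULL
  representatives <- vapply(clusters, function(cl) {
    cl[which.max(covs[cl])]   # which.max takes the first on ties
  }, character(1))
  list(clusters = clusters, representatives = representatives,
       cor_matrix = C, cov = covs)
}
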