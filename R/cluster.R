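# Unsupervised radiomic phenotype clustering and clinical association.

#' Log2-transform features with extreme values
#'
#' A column is considered extreme when its absolute sample skewness exceeds
#' `skew_threshold` and all values are nonnegative; zeros are then replaced
#' by the column's smallest positive value before taking log2. Columns with
#' negative values are never transformed (a warning is raised if they are
#' extreme). The returned `applied` flag records the decision so the
#' transform is never applied twice.
#'
#' @param column numeric vector.
#' @param skew_threshold absolute skewness above which the transform is
#'   applied; default 2.
#' @return list(values, applied).
#' @export
log2_extreme_transform <- function(column, skew_threshold = 2) {
  sk <- sample_skewness(column)
  extreme <- is.finite(sk) && abs(sk) > skew_threshold
  if (!extreme) return(list(values = column, applied = FALSE))
  if (any(column < 0)) {
    warning("extreme-valued column with negatives: not log2-transformed",
            call. = FALSE)
    return(list(values = column, applied = FALSE))
  }
  pos <- column[column > 0]
  if (length(pos) == 0) return(list(values = column, applied = FALSE))
  x <- column
  x[x == 0] <- min(pos)
  list(values = log2(x), applied = TRUE)
}

#' Standardize feature columns to zero mean and unit SD
#'
#' Per column: subtract the mean, divide by the sample SD. Constant columns
#' cannot be standardized and are dropped with a warning.
#'
#' @param table data.frame of numeric feature columns (a `patient_id` column,
#'   if present, is carried through untouched).
#' @return data.frame of the same shape minus any dropped columns.
#' @export
zscore_columns <- function(table) {
  id <- NULL
  if ("patient_id" %in% colnames(table)) {
    id <- table$patient_id
    table <- table[, setdiff(colnames(table), "patient_id"), drop = FALSE]
  }
  sds <- vapply(table, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant column(s) before standardization",
                    sum(sds == 0)), call. = FALSE)
    table <- table[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- as.data.frame(scale(as.matrix(table)))
  if (!is.null(id)) out <- cbind(patient_id = id, out,
                                 stringsAsFactors = FALSE)
  out
}

#' Two-group unsupervised hierarchical clustering of patients
#'
#' Log2-transforms extreme-valued features, standardizes columns, then
#' agglomerates patients with Euclidean distance and complete linkage and
#' cuts the dendrogram at k = 2. Group labels are normalized so that group 1
#' contains the first patient.
#'
#' @param table data.frame: `patient_id` plus feature columns; >= 4 patients.
#' @param preprocess apply the log2/z-score preprocessing (default TRUE; set
#'   FALSE if the table is already standardized).
#' @param method agglomeration method passed to [stats::hclust()]; complete
#'   linkage by default (the heatmap-tool convention). With heavy-tailed
#'   radiomic features complete linkage can cut off small outlier groups;
#'   "ward.D2" is the common alternative.
#' @return list(groups: named integer vector in \{1, 2\}; hclust: the tree;
#'   log2_applied: named logical per feature).
#' @export
hierarchical_two_groups <- function(table, preprocess = TRUE,
                                    method = "complete") {
  stopifnot("patient_id" %in% colnames(table))
  if (nrow(table) < 4) stop("need >= 4 patients to cluster", call. = FALSE)
  ids <- table$patient_id
  feats <- setdiff(colnames(table), "patient_id")
  if (length(feats) < 1) stop("need >= 1 feature", call. = FALSE)
  X <- table[, feats, drop = FALSE]
  log2_applied <- stats::setNames(rep(FALSE, length(feats)), feats)
  if (preprocess) {
    for (f in feats) {
      tr <- log2_extreme_transform(X[[f]])
      X[[f]] <- tr$values
      log2_applied[f] <- tr$applied
    }
    X <- zscore_columns(X)
  }
  hc <- stats::hclust(stats::dist(as.matrix(X), method = "euclidean"),
                      method = method)
  grp <- stats::cutree(hc, k = 2)
  if (grp[1] != 1L) grp <- 3L - grp
  list(groups = stats::setNames(as.integer(grp), ids), hclust = hc,
       log2_applied = log2_applied)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the observed table's
#' probability (with 1e-7 relative slack against ties in floating point).
#' A table with a zero margin carries no information: p = 1.
#'
#' @param m 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Association of radiomic groups with pathological endpoints
#'
#' Builds three 2x2 contingency tables — group x GGG (high/low), group x ECE
#' (yes/no), and group x pN (pN0 / pN1, pNx patients excluded from this table
#' only) — and tests each with the Fisher exact test.
#'
#' @param groups named integer vector (patient -> 1 or 2), as returned by
#'   [hierarchical_two_groups()].
#' @param labels data.frame with patient_id, ggg_high, ece, pn.
#' @return Named numeric vector of p-values for c(ggg, ece, pn); an endpoint
#'   with a single observed level is NA with a warning.
#' @export
associate <- function(groups, labels) {
  lab <- labels[match(names(groups), labels$patient_id), , drop = FALSE]
  if (any(is.na(lab$patient_id)))
    stop("labels missing for some clustered patients", call. = FALSE)
  test_one <- function(flag, keep = rep(TRUE, length(flag)), name) {
    g <- groups[keep]; f <- flag[keep]
    if (length(unique(f)) < 2 || length(unique(g)) < 2) {
      warning(sprintf("endpoint %s has a single observed level: skipped", name),
              call. = FALSE)
      return(NA_real_)
    }
    m <- table(factor(g, levels = c(1, 2)), factor(f, levels = c(FALSE, TRUE)))
    fisher_exact_2x2(unclass(m))
  }
  c(ggg = test_one(lab$ggg_high, name = "GGG"),
    ece = test_one(lab$ece, name = "ECE"),
    pn = test_one(lab$pn == "pN1", keep = lab$pn != "pNx", name = "pN"))
}
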