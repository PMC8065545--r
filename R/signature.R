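# Radiomic signature assembly and class-imbalance-aware SVM evaluation.

#' Assemble a top-stable non-redundant signature
#'
#' For each requested modality, takes the `top_k` most stable features (by
#' stability rank) and reduces them among themselves to non-redundant
#' representatives (correlation clusters at `r_threshold`, highest-CoV
#' representative); the signature is the union over modalities.
#' `include_adc_mean` appends the lesion mean ADC (`adc_fos_Mean`) when it is
#' not already present.
#'
#' @param stability named list (per modality) of [stability_rank()] tables
#'   over modality-prefixed feature names.
#' @param feature_table reader-consensus feature data.frame used for the
#'   redundancy correlations.
#' @param modality_set character subset of names(stability).
#' @param top_k signature depth per modality, default 10.
#' @param r_threshold redundancy threshold on |r|, default 0.8.
#' @param include_adc_mean append `adc_fos_Mean`.
#' @return Character vector of feature column names.
#' @export
build_signature <- function(stability, feature_table,
                            modality_set = c("t2w", "adc"), top_k = 10L,
                            r_threshold = 0.8, include_adc_mean = FALSE) {
  feats <- character(0)
  for (mod in modality_set) {
    st <- stability[[mod]]
    top <- st$feature[st$stable][seq_len(min(top_k, sum(st$stable)))]
    top <- top[!is.na(top)]
    if (length(top) == 0) next
    rr <- suppressWarnings(redundancy_reduce(feature_table, top, r_threshold))
    feats <- c(feats, rr$representatives)
  }
  if (include_adc_mean) feats <- union(feats, "adc_fos_Mean")
  if (length(feats) == 0)
    stop("empty signature: no stable non-redundant feature", call. = FALSE)
  unique(feats)
}

#' The five signature specifications
#'
#' @inheritParams build_signature
#' @return Named list of feature-name vectors: S_TOP-T2w, S_TOP-ADC, S_TOP,
#'   S_ADCmean, S_TOP+ADCmean.
#' @export
signature_specs <- function(stability, feature_table, top_k = 10L,
                            r_threshold = 0.8) {
  list(
    "S_TOP-T2w" = build_signature(stability, feature_table, "t2w", top_k,
                                  r_threshold),
    "S_TOP-ADC" = build_signature(stability, feature_table, "adc", top_k,
                                  r_threshold),
    "S_TOP" = build_signature(stability, feature_table, c("t2w", "adc"),
                              top_k, r_threshold),
    "S_ADCmean" = "adc_fos_Mean",
    "S_TOP+ADCmean" = build_signature(stability, feature_table,
                                      c("t2w", "adc"), top_k, r_threshold,
                                      include_adc_mean = TRUE))
}

#' Balanced undersampling subsets
#'
#' Each subset keeps every minority-class sample and an equal-size uniform
#' draw (without replacement, independently per subset) from the majority
#' class. Deterministic given the seed.
#'
#' @param labels logical or two-level vector.
#' @param n_subsets number of subsets, default 10.
#' @param seed RNG seed.
#' @return List of `n_subsets` integer index vectors.
#' @export
undersample_subsets <- function(labels, n_subsets = 10L, seed = 1) {
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 classes", call. = FALSE)
  tab <- table(f)
  if (any(tab == 0)) stop("a class is empty", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  idx_min <- which(f == minority)
  idx_maj <- which(f != minority)
  with_seed(seed, lapply(seq_len(n_subsets), function(s) {
    sort(c(idx_min, sample(idx_maj, length(idx_min))))
  }))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin across folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Empirical ROC curve and AUC
#'
#' Thresholds the scores at every distinct value (higher score = positive
#' call) and integrates the curve by the trapezoidal rule.
#'
#' @param scores numeric decision scores.
#' @param labels logical (TRUE = positive class).
#' @return list(fpr, tpr, auc).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ord <- order(scores, decreasing = TRUE)
  y <- as.logical(labels)[ord]
  s <- scores[ord]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("need both classes for a ROC", call. = FALSE)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # keep one point per threshold
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate a signature with an RBF SVM under balanced undersampling
#'
#' Within each balanced subset, runs stratified k-fold cross-validation: on
#' each training split the features are z-scored (test folds use the training
#' mean/SD) and a radial-kernel SVM (cost 1, gamma = 1/n_features on the
#' standardized scale) is fitted; fold predictions are pooled into one
#' confusion matrix per subset. Summaries are the mean, SD, min and max of
#' accuracy, sensitivity and specificity over the subsets; the ROC pools
#' decision scores across all subsets.
#'
#' @param feature_table data.frame with `patient_id` and feature columns.
#' @param labels logical vector (TRUE = positive class), aligned with rows.
#' @param features character vector of signature feature columns.
#' @param subsets list of row-index vectors from [undersample_subsets()].
#' @param cv_folds folds per subset, default 5.
#' @param seed RNG seed for fold assignment.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses 1/n_features.
#' @return list(per_subset: data.frame of accuracy/sensitivity/specificity;
#'   summary: data.frame of mean/sd/min/max per metric; roc; auc; features).
#' @export
eval_signature <- function(feature_table, labels, features, subsets,
                           cv_folds = 5L, seed = 1, cost = 1, gamma = NULL) {
  stopifnot(all(features %in% colnames(feature_table)))
  X_all <- as.matrix(feature_table[, features, drop = FALSE])
  y_all <- as.logical(labels)
  if (is.null(gamma)) gamma <- 1 / length(features)
  per <- data.frame(subset = seq_along(subsets), accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  pool_scores <- numeric(0); pool_y <- logical(0)
  with_seed(seed, {
    for (s in seq_along(subsets)) {
      idx <- subsets[[s]]
      X <- X_all[idx, , drop = FALSE]; y <- y_all[idx]
      if (min(table(y)) < 2)
        stop("need >= 2 samples per class in every subset", call. = FALSE)
      k <- min(cv_folds, min(table(y)))
      fold <- stratified_folds(y, k)
      pred <- logical(length(y)); score <- numeric(length(y))
      for (fd in seq_len(k)) {
        tr <- fold != fd; te <- !tr
        mu <- colMeans(X[tr, , drop = FALSE])
        sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sd_[sd_ == 0] <- 1
        Ztr <- scale(X[tr, , drop = FALSE], mu, sd_)
        Zte <- scale(X[te, , drop = FALSE], mu, sd_)
        fit <- e1071::svm(Ztr, factor(y[tr], levels = c(FALSE, TRUE)),
                          kernel = "radial", cost = cost, gamma = gamma,
                          scale = FALSE)
        pr <- stats::predict(fit, Zte, decision.values = TRUE)
        dv <- drop(attr(pr, "decision.values"))
        # orient decision values so larger = positive class
        if (colnames(attr(pr, "decision.values"))[1] == "FALSE/TRUE")
          dv <- -dv
        pred[te] <- pr == "TRUE"
        score[te] <- dv
      }
      tp <- sum(pred & y); tn <- sum(!pred & !y)
      fp <- sum(pred & !y); fn <- sum(!pred & y)
      per$accuracy[s] <- (tp + tn) / length(y)
      per$sensitivity[s] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      per$specificity[s] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      pool_scores <- c(pool_scores, score); pool_y <- c(pool_y, y)
    }
  })
  summ <- do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity"),
    function(mt) data.frame(metric = mt, mean = mean(per[[mt]]),
                            sd = stats::sd(per[[mt]]), min = min(per[[mt]]),
                            max = max(per[[mt]]))))
  roc <- roc_curve(pool_scores, pool_y)
  list(per_subset = per, summary = summ, roc = roc, auc = roc$auc,
       features = features)
}

#' Evaluate all signatures against all endpoints
#'
#' Runs the five signature specifications against the three endpoints (high
#' vs low GGG, ECE presence, pN0 vs pN1 with pNx excluded) on the full
#' cohort, then repeats on the PZ-lesion subset. Endpoints with fewer than 4
#' minority samples are skipped with a warning. TZ-only lesions are never
#' analysed separately.
#'
#' @param feature_table reader-consensus feature data.frame.
#' @param labels label data.frame (patient_id, ggg_high, ece, pn, zone).
#' @param specs named list of signatures from [signature_specs()].
#' @param config a [pipeline_config()].
#' @return Long data.frame: signature, endpoint, cohort (full/PZ), metric,
#'   mean, sd, min, max, auc, n, n_pos.
#' @export
run_all_signatures <- function(feature_table, labels, specs,
                               config = pipeline_config()) {
  lab <- labels[match(feature_table$patient_id, labels$patient_id), ]
  endpoints <- list(
    ggg = list(y = lab$ggg_high, keep = rep(TRUE, nrow(lab))),
    ece = list(y = lab$ece, keep = rep(TRUE, nrow(lab))),
    pn = list(y = lab$pn == "pN1", keep = lab$pn != "pNx"))
  cohorts <- list(full = rep(TRUE, nrow(lab)), PZ = lab$zone == "PZ")
  out <- list()
  for (co in names(cohorts)) {
    for (ep in names(endpoints)) {
      keep <- endpoints[[ep]]$keep & cohorts[[co]]
      y <- endpoints[[ep]]$y[keep]
      if (min(table(factor(y, levels = c(FALSE, TRUE)))) < 4) {
        warning(sprintf("endpoint %s (%s): < 4 minority samples, skipped",
                        ep, co), call. = FALSE)
        next
      }
      tab <- feature_table[keep, , drop = FALSE]
      subsets <- undersample_subsets(y, config$n_subsets,
                                     seed = derive_seed(config$seed,
                                                        match(ep, names(endpoints)) * 10 +
                                                          match(co, names(cohorts))))
      for (sg in names(specs)) {
        ev <- eval_signature(tab, y, specs[[sg]], subsets, config$cv_folds,
                             seed = derive_seed(config$seed, 777))
        s <- ev$summary
        s$signature <- sg; s$endpoint <- ep; s$cohort <- co
        s$auc <- ev$auc; s$n <- sum(keep); s$n_pos <- sum(y)
        out[[length(out) + 1]] <- s
      }
    }
  }
  do.call(rbind, out)
}
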