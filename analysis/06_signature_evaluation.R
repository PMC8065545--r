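#!/usr/bin/env Rscript
# Stage 6 -- radiomic signature evaluation.
#
# Builds the five signatures (per-modality and joint top-10-stable
# non-redundant sets, lesion mean ADC alone, and the joint set plus mean
# ADC) and evaluates each against the three endpoints with a radial-kernel
# SVM under 10-fold balanced undersampling, on the full cohort and on the
# PZ-lesion subset. Writes the performance table and pooled ROC curves.

source("analysis/_common.R")

tab1 <- read_features("reader1")
labels <- read_labels()
labels <- labels[labels$patient_id %in% tab1$patient_id, ]

stab <- lapply(c(t2w = "t2w", adc = "adc"), function(mod)
  utils::read.csv(file.path(RESULTS, sprintf("stability_%s.csv", mod)),
                  stringsAsFactors = FALSE))
specs <- signature_specs(stab, tab1, CONFIG$top_k_stable, CONFIG$r_threshold)
for (nm in names(specs))
  message(nm, ": ", paste(specs[[nm]], collapse = ", "))

res <- suppressWarnings(run_all_signatures(tab1, labels, specs, CONFIG))
utils::write.csv(res, file.path(RESULTS, "signature_performance.csv"),
                 row.names = FALSE)

acc <- res[res$metric == "accuracy" & res$cohort == "full", ]
message("\nMean accuracy over 10 balanced subsets (full cohort):")
for (ep in unique(acc$endpoint)) {
  rows <- acc[acc$endpoint == ep, ]
  message(sprintf("  %-4s  %s", ep,
                  paste(sprintf("%s %.2f", rows$signature, rows$mean),
                        collapse = "  ")))
}

# pooled ROC curves per endpoint for the joint signature
png(file.path(RESULTS, "roc_signatures.png"), width = 900, height = 900,
    res = 120)
plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
     ylab = "True positive rate", main = "S_TOP+ADCmean, pooled ROC")
abline(0, 1, lty = 3, col = "grey")
cols <- c(ggg = "firebrick", ece = "steelblue", pn = "darkgreen")
for (ep in c("ggg", "ece", "pn")) {
  keep <- if (ep == "pn") labels$pn != "pNx" else rep(TRUE, nrow(labels))
  y <- switch(ep, ggg = labels$ggg_high, ece = labels$ece,
              pn = labels$pn == "pN1")[keep]
  if (min(table(y)) < 4) next
  sub <- undersample_subsets(y, CONFIG$n_subsets,
                             seed = radpipe:::derive_seed(SEED, 55))
  ev <- eval_signature(tab1[keep, ], y, specs[["S_TOP+ADCmean"]], sub,
                       CONFIG$cv_folds, seed = radpipe:::derive_seed(SEED, 56))
  lines(ev$roc$fpr, ev$roc$tpr, col = cols[ep], lwd = 2)
  utils::write.csv(data.frame(endpoint = ep, fpr = ev$roc$fpr,
                              tpr = ev$roc$tpr),
                   file.path(RESULTS, sprintf("roc_points_%s.csv", ep)),
                   row.names = FALSE)
  message(sprintf("  AUC (%s, S_TOP+ADCmean): %.3f", ep, ev$auc))
}
legend("bottomright", names(cols), col = cols, lwd = 2, bty = "n")
dev.off()
message("Performance table and ROC outputs written under ", RESULTS)
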