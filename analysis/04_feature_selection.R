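#!/usr/bin/env Rscript
# Stage 4 -- inter-reader stability ranking and redundancy reduction.
#
# Per modality: Friedman test across the two readers' feature values ranks
# the 93 features by stability (p > 0.05 = stable); clusters of highly
# correlated stable features (|r| > 0.8) collapse to their highest-CoV
# representative. Writes the stability and redundancy reports.

source("analysis/_common.R")

tabs <- list(reader1 = read_features("reader1"),
             reader2 = read_features("reader2"))

for (mod in c("t2w", "adc")) {
  cols <- grep(paste0("^", mod, "_"), colnames(tabs$reader1), value = TRUE)
  sub <- lapply(tabs, function(t) t[, c("patient_id", cols)])
  stab <- stability_rank(sub, alpha = CONFIG$stability_alpha)
  utils::write.csv(stab, file.path(RESULTS, sprintf("stability_%s.csv", mod)),
                   row.names = FALSE)
  red <- suppressWarnings(
    redundancy_reduce(tabs$reader1, stab$feature[stab$stable],
                      CONFIG$r_threshold))
  cl_id <- rep(seq_along(red$clusters), lengths(red$clusters))
  red_tab <- data.frame(feature = unlist(red$clusters), cluster_id = cl_id,
                        is_representative = unlist(red$clusters) %in%
                          red$representatives,
                        cov = red$cov[unlist(red$clusters)])
  utils::write.csv(red_tab,
                   file.path(RESULTS, sprintf("redundancy_%s.csv", mod)),
                   row.names = FALSE)
  message(sprintf("%s: %d/93 stable, %d non-redundant representatives",
                  toupper(mod), sum(stab$stable),
                  length(red$representatives)))
}
message("Stability and redundancy reports written under ", RESULTS)
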