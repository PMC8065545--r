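#!/usr/bin/env Rscript
# Stage 5 -- unsupervised radiomic phenotypes and clinical association.
#
# Clusters patients (Euclidean distance, complete linkage, two groups) on the
# non-redundant stable features of each modality and of both jointly, and
# tests the association of the two radiomic groups with GGG, ECE and pN by
# Fisher's exact test. Writes assignments, association p-values and a
# heatmap per feature set.

source("analysis/_common.R")

tab1 <- read_features("reader1")
labels <- read_labels()
labels <- labels[labels$patient_id %in% tab1$patient_id, ]

reps <- lapply(c(t2w = "t2w", adc = "adc"), function(mod) {
  red <- utils::read.csv(file.path(RESULTS,
                                   sprintf("redundancy_%s.csv", mod)))
  red$feature[red$is_representative]
})
sets <- list(t2w = reps$t2w, adc = reps$adc, joint = c(reps$t2w, reps$adc))

assoc <- list()
for (nm in names(sets)) {
  cl <- hierarchical_two_groups(tab1[, c("patient_id", sets[[nm]])])
  p <- suppressWarnings(associate(cl$groups, labels))
  assoc[[nm]] <- as.list(p)
  utils::write.csv(data.frame(patient_id = names(cl$groups),
                              group = unname(cl$groups)),
                   file.path(RESULTS, sprintf("clusters_%s.csv", nm)),
                   row.names = FALSE)
  message(sprintf("%s pattern: groups %d/%d; p(GGG)=%.3f p(ECE)=%.3f p(pN)=%.3f",
                  nm, sum(cl$groups == 1), sum(cl$groups == 2),
                  p["ggg"], p["ece"], p["pn"]))

  # annotated heatmap of the standardized features (columns = patients)
  X <- tab1[, sets[[nm]], drop = FALSE]
  for (f in colnames(X)) X[[f]] <- log2_extreme_transform(X[[f]])$values
  X <- suppressWarnings(zscore_columns(X))
  rownames(X) <- tab1$patient_id
  ann <- data.frame(GGG = ifelse(labels$ggg_high, "high", "low"),
                    ECE = ifelse(labels$ece, "yes", "no"),
                    pN = labels$pn, row.names = tab1$patient_id)
  png(file.path(RESULTS, sprintf("heatmap_%s.png", nm)),
      width = 1400, height = 900, res = 120)
  pheatmap::pheatmap(t(as.matrix(X)), annotation_col = ann,
                     clustering_method = "complete", show_colnames = FALSE,
                     main = sprintf("Radiomic pattern (%s)", nm))
  dev.off()
}
jsonlite::write_json(assoc, file.path(RESULTS, "association.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Association p-values written to ",
        file.path(RESULTS, "association.json"))
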