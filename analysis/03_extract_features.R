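#!/usr/bin/env Rscript
# Stage 3 -- radiomic feature extraction.
#
# For every included patient, modality (standardized T2w, computed ADC map)
# and reader, extracts the 93 features after isotropic resampling, Collewet
# re-segmentation and 64-bin discretization. Writes one feature table per
# reader (rows = patients, columns = modality-prefixed features).

source("analysis/_common.R")

cohort <- read_cohort(COHORT_DIR)
keep <- utils::read.csv(file.path(RESULTS, "volume_filter.csv"))
included <- cohort$cases[match(keep$patient_id[keep$included],
                               vapply(cohort$cases, `[[`, character(1),
                                      "patient_id"))]
message("Extracting 93 features x 2 modalities x 2 readers for ",
        length(included), " patients")
t0 <- Sys.time()
tabs <- extract_cohort(included, CONFIG, verbose = TRUE)
message(sprintf("  done in %.1f min",
                as.numeric(difftime(Sys.time(), t0, units = "mins"))))
for (rd in names(tabs))
  utils::write.csv(tabs[[rd]],
                   file.path(RESULTS, sprintf("features_%s.csv", rd)),
                   row.names = FALSE)
message("Feature tables written under ", RESULTS)
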