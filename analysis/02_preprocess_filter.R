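#!/usr/bin/env Rscript
# Stage 2 -- preprocessing and the VOI inclusion filter.
#
# Validates the cohort directory, then applies the volumetric criterion:
# only lesions whose ADC-delineated VOI strictly exceeds 0.7 cc enter the
# analysis. Writes the exclusion report.

source("analysis/_common.R")

issues <- validate_inputs(COHORT_DIR)
if (nrow(issues) > 0) {
  print(issues)
  stop("cohort directory is not well-formed")
}
message("Input validation: clean")

cohort <- read_cohort(COHORT_DIR)
filt <- filter_cohort_by_volume(cohort$cases, CONFIG$voi_min_cc)
utils::write.csv(filt$report, file.path(RESULTS, "volume_filter.csv"),
                 row.names = FALSE)
message(sprintf("VOI filter (> %.1f cc on ADC): %d included, %d excluded",
                CONFIG$voi_min_cc, sum(filt$report$included),
                sum(!filt$report$included)))
message("Report written to ", file.path(RESULTS, "volume_filter.csv"))
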