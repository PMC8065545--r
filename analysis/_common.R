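# Shared settings for the numbered analysis scripts. Every script can be
# rerun on its own; stages communicate through files under results/.

library(radpipe)

SEED <- as.integer(Sys.getenv("RADPIPE_SEED", "42"))
RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
CONFIG <- pipeline_config(seed = SEED)
PARAMS <- phantom_params()     # the study conditions: 102 lesions, 40 < 0.7 cc

dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

read_features <- function(reader) {
  utils::read.csv(file.path(RESULTS, sprintf("features_%s.csv", reader)),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

read_labels <- function() {
  utils::read.csv(file.path(COHORT_DIR, "labels.csv"),
                  stringsAsFactors = FALSE)
}
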