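# End-to-end orchestration: synthetic cohort (or a cohort directory) through
# preprocessing, extraction, selection, clustering and signature evaluation.

#' Run the full radiomic pipeline
#'
#' Executes, in order: cohort generation (or loading), the VOI volume filter,
#' per-reader feature extraction, inter-reader stability ranking per modality,
#' redundancy reduction among the stable features, two-group hierarchical
#' clustering with Fisher association per modality and jointly, and the five
#' signature evaluations. All randomness derives from one seed; a rerun with
#' the same configuration is bit-identical in every tabular output.
#'
#' @param config a [pipeline_config()].
#' @param params a [phantom_params()] for synthetic input, or NULL when
#'   `input_dir` is given.
#' @param input_dir directory of a written cohort (see [write_cohort()]);
#'   overrides `params`.
#' @param seed master seed; defaults to `config$seed`.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print stage progress.
#' @return A run manifest: list with counts, stage outputs (tables) and the
#'   configuration snapshot.
#' @export
run_pipeline <- function(config = pipeline_config(), params = phantom_params(),
                         input_dir = NULL, seed = NULL, out_dir = NULL,
                         verbose = TRUE) {
  seed <- if (is.null(seed)) config$seed else seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("Stage 1: cohort")
  cohort <- if (is.null(input_dir)) generate_cohort(params, seed = seed)
            else read_cohort(input_dir)

  say("Stage 2: VOI volume filter (> %.2f cc on the ADC mask)", config$voi_min_cc)
  filt <- filter_cohort_by_volume(cohort$cases, config$voi_min_cc)
  say("  included %d / excluded %d of %d cases",
      length(filt$included), length(filt$excluded), length(cohort$cases))
  labels <- cohort$labels[cohort$labels$patient_id %in%
                            vapply(filt$included, `[[`, character(1),
                                   "patient_id"), , drop = FALSE]

  say("Stage 3: feature extraction (93 features x 2 modalities x 2 readers)")
  tables <- extract_cohort(filt$included, config, verbose = verbose)

  say("Stage 4: stability ranking and redundancy reduction")
  modalities <- c("t2w", "adc")
  stab <- list(); red <- list()
  for (mod in modalities) {
    cols <- grep(paste0("^", mod, "_"), colnames(tables$reader1), value = TRUE)
    sub <- lapply(tables, function(t) t[, c("patient_id", cols)])
    stab[[mod]] <- stability_rank(sub, alpha = config$stability_alpha)
    stable_feats <- stab[[mod]]$feature[stab[[mod]]$stable]
    red[[mod]] <- redundancy_reduce(tables$reader1, stable_feats,
                                    config$r_threshold)
  }

  say("Stage 5: unsupervised clustering and clinical association")
  assoc <- list(); groups <- list()
  sets <- list(t2w = red$t2w$representatives, adc = red$adc$representatives,
               joint = c(red$t2w$representatives, red$adc$representatives))
  for (nm in names(sets)) {
    tab <- tables$reader1[, c("patient_id", sets[[nm]]), drop = FALSE]
    cl <- hierarchical_two_groups(tab)
    groups[[nm]] <- cl$groups
    assoc[[nm]] <- suppressWarnings(associate(cl$groups, labels))
  }

  say("Stage 6: signature evaluation")
  specs <- signature_specs(stab, tables$reader1, config$top_k_stable,
                           config$r_threshold)
  results <- withCallingHandlers(
    run_all_signatures(tables$reader1, labels, specs, config),
    warning = function(w) { say("  note: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })

  manifest <- list(
    config = unclass(config),
    seed = seed,
    counts = list(
      n_input = length(cohort$cases),
      n_included = length(filt$included),
      n_excluded = length(filt$excluded),
      n_features = 93L,
      n_stable = vapply(stab, function(s) sum(s$stable), integer(1)),
      n_nonredundant = vapply(red, function(r) length(r$representatives),
                              integer(1))),
    volume_report = filt$report,
    stability = stab,
    redundancy = red,
    cluster_groups = groups,
    association = assoc,
    signatures = specs,
    performance = results,
    feature_tables = tables,
    labels = labels)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(filt$report, file.path(out_dir, "volume_filter.csv"),
                     row.names = FALSE)
    for (rd in names(tables))
      utils::write.csv(tables[[rd]],
                       file.path(out_dir, sprintf("features_%s.csv", rd)),
                       row.names = FALSE)
    for (mod in modalities)
      utils::write.csv(stab[[mod]],
                       file.path(out_dir, sprintf("stability_%s.csv", mod)),
                       row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "signature_performance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = manifest$counts, association = assoc,
           signatures = specs, seed = seed),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(manifest)
}

#' Validate a cohort directory
#'
#' Checks, without throwing: the label table schema, the presence of every
#' expected volume and mask file, grid/spacing agreement between each mask
#' and its volume, and mask nonemptiness.
#'
#' @param dir cohort directory (see [write_cohort()]).
#' @return data.frame of issues (patient_id, file, issue); zero rows when the
#'   directory is well-formed.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(pid, file, issue)
    issues[[length(issues) + 1]] <<- data.frame(
      patient_id = pid, file = file, issue = issue, stringsAsFactors = FALSE)
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    add(NA, "labels.csv", "missing label table")
    return(do.call(rbind, issues))
  }
  labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  for (col in c("patient_id", "ggg_high", "ece", "pn", "zone"))
    if (!col %in% colnames(labels))
      add(NA, "labels.csv", sprintf("missing column '%s'", col))
  if (!"patient_id" %in% colnames(labels))
    return(do.call(rbind, issues))
  for (id in labels$patient_id) {
    vols <- list()
    for (v in c("t2w", "dwi_low", "dwi_high")) {
      f <- sprintf("%s_%s.nii.gz", id, v)
      if (!file.exists(file.path(dir, f))) { add(id, f, "missing volume"); next }
      vols[[v]] <- tryCatch(read_volume(file.path(dir, f)),
                            error = function(e) { add(id, f, "unreadable"); NULL })
    }
    for (mod in c("t2w", "adc")) for (rd in c("reader1", "reader2")) {
      f <- sprintf("%s_mask_%s_%s.nii.gz", id, mod, rd)
      if (!file.exists(file.path(dir, f))) { add(id, f, "missing mask"); next }
      m <- tryCatch(read_mask(file.path(dir, f)),
                    error = function(e) { add(id, f, "unreadable"); NULL })
      if (is.null(m)) next
      ref <- if (mod == "t2w") vols$t2w else vols$dwi_low
      if (!is.null(ref) && !identical(dim(m), dim(ref$intensities)))
        add(id, f, sprintf("grid mismatch: mask %s vs volume %s",
                           paste(dim(m), collapse = "x"),
                           paste(dim(ref$intensities), collapse = "x")))
      if (!any(m)) add(id, f, "empty mask")
    }
  }
  if (length(issues) == 0)
    data.frame(patient_id = character(0), file = character(0),
               issue = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, issues)
}
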