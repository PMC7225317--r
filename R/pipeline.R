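#' Pipeline configuration
#'
#' Collects every rule constant of the analysis under its published default
#' (arousal drop 15 ms within 5–45 s, PTT valid range 150–500 ms, 50 ms
#' artifact spikes, >4% dips lasting >5 s and <180 s, 4 h oximetry / 3 h
#' PTT inclusion, 0.90 sensitivity/specificity targets) together with the
#' simulation configuration, seed and bootstrap size.
#'
#' @param cohort A [cohort_config()] describing the simulated cohort.
#' @param seed Seed for the train/test split and bootstrap.
#' @param n_boot Bootstrap replicates.
#' @param target_hz Resampling rate of the raw PTT channel, Hz.
#' @param ptt2_window PTT2 moving-average window, samples.
#' @param arousal_drop_ms Minimum PTT2 drop for an arousal, ms.
#' @param arousal_window_s Arousal duration gate, seconds (increasing).
#' @param ptt_valid_range_ms Valid PTT range, ms (increasing).
#' @param spike_ms PTT artifact spike threshold, ms.
#' @param dip_pct Desaturation threshold below baseline, percentage points.
#' @param desat_duration_s Dip duration gates, seconds (increasing).
#' @param min_oximetry_hours,min_ptt_hours Inclusion thresholds, hours.
#' @param target_sens,target_spec ROC threshold targets.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            seed = 1, n_boot = 2000,
                            target_hz = 5, ptt2_window = 17,
                            arousal_drop_ms = 15, arousal_window_s = c(5, 45),
                            ptt_valid_range_ms = c(150, 500),
                            spike_ms = 50, dip_pct = 4,
                            desat_duration_s = c(5, 180),
                            min_oximetry_hours = 4, min_ptt_hours = 3,
                            target_sens = 0.9, target_spec = 0.9) {
  cfg <- structure(
    list(cohort = cohort, seed = as.integer(seed), n_boot = n_boot,
         target_hz = target_hz, ptt2_window = ptt2_window,
         arousal_drop_ms = arousal_drop_ms,
         arousal_window_s = arousal_window_s,
         ptt_valid_range_ms = ptt_valid_range_ms,
         spike_ms = spike_ms, dip_pct = dip_pct,
         desat_duration_s = desat_duration_s,
         min_oximetry_hours = min_oximetry_hours,
         min_ptt_hours = min_ptt_hours,
         target_sens = target_sens, target_spec = target_spec),
    class = "pipeline_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Range-checks every field and reports all violations at once.
#'
#' @param config A `pipeline_config` (or a bare list with its fields).
#' @return The checked configuration, invisibly classed `pipeline_config`.
#' @export
validate_config <- function(config) {
  known <- c("cohort", "seed", "n_boot", "target_hz", "ptt2_window",
             "arousal_drop_ms", "arousal_window_s", "ptt_valid_range_ms",
             "spike_ms", "dip_pct", "desat_duration_s",
             "min_oximetry_hours", "min_ptt_hours",
             "target_sens", "target_spec")
  problems <- character()
  extra <- setdiff(names(config), known)
  if (length(extra))
    problems <- c(problems, paste0("unknown fields: ",
                                   paste(extra, collapse = ", ")))
  missing <- setdiff(known, names(config))
  if (length(missing))
    problems <- c(problems, paste0("missing fields: ",
                                   paste(missing, collapse = ", ")))
  chk <- function(cond, msg) if (isTRUE(cond)) character() else msg
  if (!length(missing)) {
    problems <- c(
      problems,
      chk(inherits(config$cohort, "cohort_config"),
          "`cohort` must be a cohort_config"),
      chk(config$n_boot >= 100, "`n_boot` must be >= 100"),
      chk(config$target_hz > 0, "`target_hz` must be positive"),
      chk(config$ptt2_window >= 3 && config$ptt2_window %% 2 == 1,
          "`ptt2_window` must be an odd number >= 3"),
      chk(config$arousal_drop_ms > 0, "`arousal_drop_ms` must be positive"),
      chk(length(config$arousal_window_s) == 2 &&
            config$arousal_window_s[1] > 0 &&
            config$arousal_window_s[1] < config$arousal_window_s[2],
          "`arousal_window_s` must be an increasing positive pair"),
      chk(length(config$ptt_valid_range_ms) == 2 &&
            config$ptt_valid_range_ms[1] > 0 &&
            config$ptt_valid_range_ms[1] < config$ptt_valid_range_ms[2],
          "`ptt_valid_range_ms` must be an increasing positive pair"),
      chk(config$spike_ms > 0, "`spike_ms` must be positive"),
      chk(config$dip_pct > 0, "`dip_pct` must be positive"),
      chk(length(config$desat_duration_s) == 2 &&
            config$desat_duration_s[1] > 0 &&
            config$desat_duration_s[1] < config$desat_duration_s[2],
          "`desat_duration_s` must be an increasing positive pair"),
      chk(config$min_oximetry_hours > 0,
          "`min_oximetry_hours` must be positive"),
      chk(config$min_ptt_hours > 0, "`min_ptt_hours` must be positive"),
      chk(config$target_sens > 0 && config$target_sens <= 1,
          "`target_sens` must lie in (0, 1]"),
      chk(config$target_spec > 0 && config$target_spec <= 1,
          "`target_spec` must lie in (0, 1]"))
  }
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(config) <- "pipeline_config"
  invisible(config)
}

# feature extraction + classification for one simulated child
process_child <- function(child, config) {
  ptt <- ptt_features_for_record(
    child$beats, target_hz = config$target_hz,
    drop_ms = config$arousal_drop_ms, window_s = config$arousal_window_s,
    valid_range_ms = config$ptt_valid_range_ms, spike_ms = config$spike_ms,
    ptt2_window = config$ptt2_window, min_ptt_hours = config$min_ptt_hours)
  ox <- oximetry_summary(child$spo2, min_hours = config$min_oximetry_hours,
                         drop_pct = config$dip_pct,
                         min_s = config$desat_duration_s[1],
                         max_s = config$desat_duration_s[2])
  rec <- study_record(child$child_id, ox, child$video, ptt)
  apply_exclusions(rec, min_oximetry_hours = config$min_oximetry_hours,
                   min_ptt_hours = config$min_ptt_hours)
}

# flatten study records into the cohort-level table
records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    child_id = r$child_id,
    study_category = r$study_category,
    oximetry_category = r$oximetry$category,
    mean_spo2_pct = r$oximetry$mean_spo2_pct,
    min_spo2_pct = r$oximetry$min_spo2_pct,
    baseline_spo2_pct = r$oximetry$baseline_spo2_pct,
    dip_index_per_hour = r$oximetry$dip_index_per_hour,
    oximetry_hours = r$oximetry$artifact_free_hours,
    ptt_arousal_index = if (is.null(r$ptt)) NA_real_ else r$ptt$ptt_arousal_index,
    respiratory_swing_ms = if (is.null(r$ptt)) NA_real_ else r$ptt$respiratory_swing_ms,
    ptt_hours = if (is.null(r$ptt)) NA_real_ else r$ptt$artifact_free_hours,
    included_oximetry = r$included_oximetry,
    included_ptt = r$included_ptt,
    in_roc_set = r$in_roc_set,
    stringsAsFactors = FALSE)))
}

# train/test threshold analysis of one PTT index over the ROC set
index_diagnostics <- function(tab, index, config) {
  keep <- tab$in_roc_set & is.finite(tab[[index]])
  lv <- labeled_values(tab[[index]][keep],
                       tab$study_category[keep] %in% c("uars", "osa"))
  sp <- split_train_test(lv, seed = config$seed)
  roc_train <- roc_curve(sp$train_data)
  sel <- select_thresholds(roc_train, target_sens = config$target_sens,
                           target_spec = config$target_spec)
  thr <- sel$max_sum$threshold
  list(index = index, n = length(lv$values),
       roc_train = roc_train, thresholds = sel,
       train = evaluate_threshold(sp$train_data, thr),
       test = evaluate_threshold(sp$test_data, thr),
       test_ci = bootstrap_ci(sp$test_data, thr, n_boot = config$n_boot,
                              seed = config$seed))
}

#' Run the full simulated pipeline
#'
#' simulate -> extract features -> classify -> apply exclusions ->
#' train/test ROC analysis of both PTT indices. The report embeds the
#' configuration and seed needed to regenerate it exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress.
#' @return A list of class `pipeline_report` with `records` (cohort table),
#'   `truth`, `diagnostics` (per PTT index) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d children (%.1f h each)",
      config$cohort$n_children, config$cohort$study_hours)
  cohort <- generate_cohort(config$cohort)
  say("extracting features")
  records <- lapply(cohort$children, process_child, config = config)
  tab <- records_table(records)
  for (r in records) {
    if (!r$included_oximetry)
      say("WARN %s excluded: <%g h artifact-free oximetry",
          r$child_id, config$min_oximetry_hours)
    else if (!r$included_ptt)
      say("WARN %s excluded from PTT analysis: <%g h artifact-free PTT",
          r$child_id, config$min_ptt_hours)
  }
  say("threshold analysis")
  diagnostics <- list(
    respiratory_swing_ms = index_diagnostics(tab, "respiratory_swing_ms", config),
    ptt_arousal_index = index_diagnostics(tab, "ptt_arousal_index", config))
  structure(
    list(records = tab, truth = cohort$truth, diagnostics = diagnostics,
         manifest = list(seed = config$seed, config = config,
                         package_version =
                           as.character(utils::packageVersion("pttsdb")),
                         generated = "deterministic given config")),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d children, %d in PTT threshold set\n",
              nrow(x$records), sum(x$records$in_roc_set)))
  sw <- x$diagnostics$respiratory_swing_ms
  cat(sprintf("  swing max-sum threshold %.2f ms: test sens %.2f spec %.2f\n",
              sw$thresholds$max_sum$threshold,
              sw$test$sensitivity, sw$test$specificity))
  ai <- x$diagnostics$ptt_arousal_index
  cat(sprintf("  PTT-AI max-sum threshold %.2f /h: test sens %.2f spec %.2f\n",
              ai$thresholds$max_sum$threshold,
              ai$test$sensitivity, ai$test$specificity))
  invisible(x)
}
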