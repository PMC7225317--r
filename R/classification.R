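#' Video and sound annotations for a sleep study
#'
#' Human-scored observations consumed by the classifier: whether snoring was
#' heard, and the witnessed obstructive episodes (pauses in snoring with
#' continued respiratory effort), each flagged as arousal-linked when
#' followed by movement and a pulse-rate rise.
#'
#' @param snoring_present Logical flag.
#' @param episodes An [event_list()] with a logical `arousal_linked` column,
#'   or `NULL` for none.
#' @param study_span_s Optional two-element study span used to validate that
#'   episodes lie within the recording.
#' @return A list of class `video_annotations`.
#' @export
video_annotations <- function(snoring_present, episodes = NULL,
                              study_span_s = NULL) {
  if (is.null(episodes))
    episodes <- event_list(type = "obstructive", arousal_linked = logical())
  if (is.null(episodes$arousal_linked))
    stop("`episodes` must carry an `arousal_linked` column")
  if (!is.null(study_span_s) && nrow(episodes) > 0L &&
      (any(episodes$start_s < study_span_s[1]) ||
       any(episodes$end_s > study_span_s[2])))
    stop("obstructive episodes must lie within the study span")
  structure(list(snoring_present = isTRUE(snoring_present),
                 episodes = episodes),
            class = "video_annotations")
}

#' Classify a sleep study from oximetry category and video annotations
#'
#' Five-category classification:
#' \itemize{
#'   \item \strong{osa} — abnormal oximetry with at least
#'     `osa_min_episodes` arousal-linked obstructive episodes;
#'   \item \strong{abnormal_other} — abnormal oximetry with no video
#'     evidence of obstruction;
#'   \item \strong{uars} — normal/inconclusive oximetry with at least
#'     `uars_min_episodes` arousal-linked obstructive episodes;
#'   \item \strong{primary_snoring} — normal/inconclusive oximetry with
#'     snoring (or any witnessed episode) but fewer arousal-linked episodes
#'     than the UARS rule requires;
#'   \item \strong{normal} — normal/inconclusive oximetry, no snoring and
#'     no obstructive episodes.
#' }
#' The function is total: every combination of inputs maps to exactly one
#' category.
#'
#' @param oximetry_category Output of [categorize_oximetry()].
#' @param video A [video_annotations()].
#' @param uars_min_episodes Arousal-linked episodes required for UARS.
#' @param osa_min_episodes Arousal-linked episodes required for OSA (the
#'   abnormal-oximetry arm).
#' @return One of `"normal"`, `"primary_snoring"`, `"uars"`, `"osa"`,
#'   `"abnormal_other"`.
#' @export
classify_study <- function(oximetry_category, video,
                           uars_min_episodes = 3, osa_min_episodes = 1) {
  stopifnot(inherits(video, "video_annotations"))
  oximetry_category <- match.arg(
    oximetry_category,
    c("normal", "inconclusive", "abnormal_low_risk", "abnormal_high_risk"))
  abnormal <- oximetry_category %in% c("abnormal_low_risk", "abnormal_high_risk")
  n_ep <- nrow(video$episodes)
  n_ar <- sum(video$episodes$arousal_linked)
  if (abnormal) {
    if (n_ar >= osa_min_episodes) return("osa")
    return("abnormal_other")
  }
  if (n_ar >= uars_min_episodes) return("uars")
  if (video$snoring_present || n_ep > 0L) return("primary_snoring")
  "normal"
}

#' Assemble a per-child study record
#'
#' @param child_id Identifier.
#' @param oximetry An `oximetry_feature_set` from [oximetry_summary()].
#' @param video A [video_annotations()].
#' @param ptt A `ptt_feature_set` from [ptt_features_for_record()], or
#'   `NULL` when no PTT channel was recorded.
#' @return A list of class `study_record` (before exclusion flags are set,
#'   see [apply_exclusions()]).
#' @export
study_record <- function(child_id, oximetry, video, ptt = NULL) {
  stopifnot(inherits(oximetry, "oximetry_feature_set"),
            inherits(video, "video_annotations"))
  structure(list(child_id = child_id, oximetry = oximetry, video = video,
                 ptt = ptt, study_category = NA_character_,
                 included_oximetry = NA, included_ptt = NA, in_roc_set = NA),
            class = "study_record")
}

#' Apply cohort exclusion rules and assign the study category
#'
#' A child is included in the oximetry analysis with at least
#' `min_oximetry_hours` artifact-free oximetry hours; the study category is
#' assigned only for included studies. The child enters the PTT analysis
#' with at least `min_ptt_hours` artifact-free PTT hours, and children
#' categorised "abnormal other" (whose findings are unrelated to
#' obstruction) are additionally excluded from the PTT threshold analysis.
#'
#' @param record A [study_record()].
#' @param min_oximetry_hours,min_ptt_hours Inclusion thresholds in hours.
#' @return The record with `study_category`, `included_oximetry`,
#'   `included_ptt` and `in_roc_set` set.
#' @export
apply_exclusions <- function(record, min_oximetry_hours = 4, min_ptt_hours = 3) {
  stopifnot(inherits(record, "study_record"))
  record$included_oximetry <-
    record$oximetry$artifact_free_hours >= min_oximetry_hours
  record$study_category <- if (record$included_oximetry)
    classify_study(record$oximetry$category, record$video)
  else NA_character_
  record$included_ptt <- record$included_oximetry &&
    !is.null(record$ptt) && record$ptt$artifact_free_hours >= min_ptt_hours
  record$in_roc_set <- isTRUE(record$included_ptt) &&
    !is.na(record$study_category) && record$study_category != "abnormal_other"
  record
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s: %s (oximetry %s)%s\n",
              x$child_id,
              if (is.na(x$study_category)) "excluded" else x$study_category,
              x$oximetry$category,
              if (isTRUE(x$in_roc_set)) "" else " [not in PTT threshold set]"))
  invisible(x)
}
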