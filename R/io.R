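#' Read and write per-beat PTT series as CSV
#'
#' CSV dialect: header `beat_time_s,ptt_ms,valid`, UTF-8, '.' decimal.
#'
#' @param path File path.
#' @return [read_beat_csv()] returns a [beat_ptt_series()].
#' @export
read_beat_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("beat_time_s", "ptt_ms")
  if (!all(need %in% names(d)))
    stop("beat CSV must have columns beat_time_s, ptt_ms[, valid]")
  beat_ptt_series(d$beat_time_s, d$ptt_ms,
                  valid = if ("valid" %in% names(d)) as.logical(d$valid))
}

#' @rdname read_beat_csv
#' @param series A [beat_ptt_series()].
#' @export
write_beat_csv <- function(series, path) {
  stopifnot(inherits(series, "beat_ptt_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read an SpO2 trace from CSV
#'
#' Expects columns `time_s, spo2_pct` on a regular grid; small gaps are
#' tolerated and returned as masked (NA) samples.
#'
#' @param path File path.
#' @return A [uniform_series()].
#' @export
read_spo2_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "spo2_pct") %in% names(d)))
    stop("SpO2 CSV must have columns time_s, spo2_pct")
  d <- d[order(d$time_s), ]
  steps <- diff(d$time_s)
  step <- stats::median(steps)
  if (step <= 0) stop("time_s must be increasing")
  grid <- seq(d$time_s[1], d$time_s[nrow(d)], by = step)
  idx <- round((d$time_s - d$time_s[1]) / step) + 1L
  vals <- rep(NA_real_, length(grid))
  vals[idx[idx >= 1 & idx <= length(grid)]] <- d$spo2_pct
  uniform_series(vals, step_s = step, start_s = d$time_s[1])
}

#' @rdname read_spo2_csv
#' @param spo2 A [uniform_series()].
#' @export
write_spo2_csv <- function(spo2, path) {
  stopifnot(inherits(spo2, "uniform_series"))
  utils::write.csv(data.frame(time_s = series_times(spo2),
                              spo2_pct = spo2$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write video/sound annotations as JSON
#'
#' Format: `{"snoring": bool, "episodes": [{"start_s", "end_s",
#' "arousal_linked"}]}`.
#'
#' @param path File path.
#' @return [read_annotations_json()] returns a [video_annotations()].
#' @export
read_annotations_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- if (!is.null(j$episodes) && length(j$episodes) &&
            NROW(j$episodes) > 0)
    event_list(j$episodes$start_s, j$episodes$end_s, type = "obstructive",
               arousal_linked = as.logical(j$episodes$arousal_linked))
  else NULL
  video_annotations(isTRUE(j$snoring), ep)
}

#' @rdname read_annotations_json
#' @param video A [video_annotations()].
#' @export
write_annotations_json <- function(video, path) {
  stopifnot(inherits(video, "video_annotations"))
  ep <- video$episodes
  jsonlite::write_json(
    list(snoring = video$snoring_present,
         episodes = data.frame(start_s = ep$start_s, end_s = ep$end_s,
                               arousal_linked = ep$arousal_linked)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export per-record features as a metric,value CSV
#'
#' @param features A `ptt_feature_set` or `oximetry_feature_set`.
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  keep <- vapply(features, function(x)
    is.numeric(x) && length(x) == 1, logical(1))
  d <- data.frame(metric = names(features)[keep],
                  value = unlist(features[keep], use.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export an event list as JSON (half-open intervals)
#'
#' @param events An [event_list()].
#' @param path File path.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(as.data.frame(events), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
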