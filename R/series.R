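#' Regularly sampled signal with an artifact mask
#'
#' The uniform-series container holds every regularly sampled channel in the
#' pipeline: the resampled raw PTT channel, the smoothed PTT2 channel, the
#' 1 Hz interpolated swing channel and the SpO2 trace. Masked samples
#' (`mask = TRUE`) are treated as artifact and excluded from all downstream
#' statistics.
#'
#' @param values Numeric vector of samples.
#' @param step_s Sampling step in seconds (> 0).
#' @param start_s Time of the first sample, seconds from recording start.
#' @param mask Logical vector the same length as `values`; `TRUE` marks a
#'   sample as artifact. Non-finite values are always masked.
#'
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, step_s, start_s = 0, mask = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(step_s) || length(step_s) != 1L || !is.finite(step_s) || step_s <= 0)
    stop("`step_s` must be a single positive number")
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  mask <- as.logical(mask)
  if (length(mask) != length(values))
    stop("`mask` and `values` must have equal length")
  mask <- mask | !is.finite(values)
  structure(
    list(values = values, step_s = as.numeric(step_s),
         start_s = as.numeric(start_s), mask = mask),
    class = "uniform_series"
  )
}

#' Sample times of a uniform series
#' @param x A [uniform_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$start_s + (seq_along(x$values) - 1L) * x$step_s
}

#' Total unmasked duration of a uniform series, in hours
#'
#' One sample accounts for one sampling step of recording time; this is the
#' denominator used for per-hour indices (PTT arousal index, oximetry dip
#' index).
#'
#' @param x A [uniform_series()].
#' @return Hours of artifact-free signal.
#' @export
artifact_free_hours <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  sum(!x$mask) * x$step_s / 3600
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %.4g Hz, start %.3f s, %d masked\n",
              length(x$values), 1 / x$step_s, x$start_s, sum(x$mask)))
  invisible(x)
}

#' Per-beat pulse transit time series
#'
#' One row per detected heart beat: the time of the R-wave midpoint and the
#' pulse transit time to the following plethysmograph upstroke, in
#' milliseconds. Beats for which no pulse arrival could be matched are kept
#' with `valid = FALSE` and `ptt_ms = NA`.
#'
#' @param beat_time_s Strictly increasing beat times (R-wave midpoints), s.
#' @param ptt_ms Per-beat PTT in milliseconds; positive where `valid`.
#' @param valid Logical; defaults to beats with finite positive PTT.
#'
#' @return An object of class `beat_ptt_series` (also a data.frame).
#' @export
beat_ptt_series <- function(beat_time_s, ptt_ms, valid = NULL) {
  beat_time_s <- as.numeric(beat_time_s)
  ptt_ms <- as.numeric(ptt_ms)
  if (length(beat_time_s) != length(ptt_ms))
    stop("`beat_time_s` and `ptt_ms` must have equal length")
  if (length(beat_time_s) > 1L && any(diff(beat_time_s) <= 0))
    stop("`beat_time_s` must be strictly increasing")
  if (is.null(valid)) valid <- is.finite(ptt_ms) & ptt_ms > 0
  valid <- as.logical(valid) & is.finite(ptt_ms) & ptt_ms > 0
  if (length(valid) != length(beat_time_s))
    stop("`valid` must match the number of beats")
  out <- data.frame(beat_time_s = beat_time_s, ptt_ms = ptt_ms, valid = valid)
  class(out) <- c("beat_ptt_series", "data.frame")
  out
}

#' Typed event list with half-open intervals
#'
#' Events (arousals, desaturations, artifact spans, obstructive episodes)
#' are intervals `[start_s, end_s)` in seconds from recording start.
#'
#' @param start_s,end_s Interval bounds, `start_s < end_s`.
#' @param type Event type label, recycled.
#' @param ... Further per-event columns (e.g. `arousal_linked`).
#' @return An object of class `event_list` (also a data.frame), ordered by
#'   start time.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       type = character(), ...) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s))
    stop("`start_s` and `end_s` must have equal length")
  if (any(end_s <= start_s))
    stop("events must satisfy start_s < end_s (half-open intervals)")
  if (length(type) == 0L && length(start_s) > 0L) type <- "event"
  out <- data.frame(start_s = start_s, end_s = end_s,
                    type = rep_len(as.character(type), length(start_s)),
                    ...)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_list", "data.frame")
  out
}

#' Merge overlapping or touching events
#' @param events An [event_list()].
#' @return An [event_list()] with overlapping spans coalesced.
#' @export
merge_events <- function(events) {
  if (nrow(events) <= 1L) return(events)
  ev <- events[order(events$start_s), , drop = FALSE]
  start <- ev$start_s[1]; end <- ev$end_s[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$start_s[i] <= end) {
      end <- max(end, ev$end_s[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- ev$start_s[i]; end <- ev$end_s[i]
    }
  }
  out_s <- c(out_s, start); out_e <- c(out_e, end)
  event_list(out_s, out_e, type = ev$type[1])
}

#' Mask the samples of a uniform series that fall inside events
#' @param x A [uniform_series()].
#' @param events An [event_list()] of spans to exclude.
#' @return `x` with the mask extended over the event intervals.
#' @export
mask_events <- function(x, events) {
  stopifnot(inherits(x, "uniform_series"))
  if (is.null(events) || nrow(events) == 0L) return(x)
  tt <- series_times(x)
  for (i in seq_len(nrow(events)))
    x$mask <- x$mask | (tt >= events$start_s[i] & tt < events$end_s[i])
  x
}

# TRUE for times falling inside any half-open event interval
times_in_events <- function(times, events) {
  if (is.null(events) || nrow(events) == 0L) return(rep(FALSE, length(times)))
  hit <- rep(FALSE, length(times))
  for (i in seq_len(nrow(events)))
    hit <- hit | (times >= events$start_s[i] & times < events$end_s[i])
  hit
}

# restore the RNG state after running seeded code
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
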