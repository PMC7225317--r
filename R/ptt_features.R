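#' Smooth the raw PTT channel into PTT2
#'
#' Centred moving average of `window` samples (17 points at 5 Hz, a ~3.2 s
#' span) computed over unmasked samples only. An output sample is masked if
#' more than half of its window is masked, or if the window is truncated at
#' a series edge (no partial-window output).
#'
#' @param raw A [uniform_series()] of raw PTT in ms.
#' @param window Number of samples in the averaging window (odd).
#' @return A [uniform_series()], the PTT2 channel.
#' @export
smooth_ptt2 <- function(raw, window = 17) {
  stopifnot(inherits(raw, "uniform_series"))
  n <- length(raw$values)
  if (n < window) stop(sprintf("series shorter than the %d-sample window", window))
  if (window %% 2 == 0) stop("`window` must be odd")
  ok <- !raw$mask
  v0 <- ifelse(ok, raw$values, 0)
  ssum <- stats::filter(v0, rep(1, window), sides = 2)
  cnt <- stats::filter(as.numeric(ok), rep(1, window), sides = 2)
  vals <- as.numeric(ssum / cnt)
  mask <- is.na(cnt) | cnt < window / 2          # >50% masked, or edge
  vals[mask | cnt == 0] <- NA_real_
  uniform_series(vals, step_s = raw$step_s, start_s = raw$start_s, mask = mask)
}

#' Detect artifact spans in the raw PTT channel
#'
#' Flags rapid spikes — excursions of more than `spike_ms` within any
#' horizon up to `horizon_s` — and samples outside the physiologically
#' valid PTT range. Because the beat series is linearly resampled, a
#' one-beat spike is spread over several grid samples, so the excursion is
#' tested at all lags up to the horizon rather than only between adjacent
#' samples. Each flagged span is dilated by `pad_s` on both sides (spikes
#' corrupt the smoothed channel beyond their own samples) and overlapping
#' spans are merged.
#'
#' @param raw A [uniform_series()] of raw PTT in ms.
#' @param spike_ms Spike threshold in ms.
#' @param valid_range_ms Two-element valid PTT range in ms.
#' @param pad_s Dilation of each artifact span, seconds per side.
#' @param horizon_s Longest horizon over which the spike excursion is
#'   evaluated, seconds.
#' @return An [event_list()] of artifact spans.
#' @export
detect_ptt_artifact <- function(raw, spike_ms = 50, valid_range_ms = c(150, 500),
                                pad_s = 2, horizon_s = 1) {
  stopifnot(inherits(raw, "uniform_series"))
  v <- raw$values
  n <- length(v)
  step <- raw$step_s
  bad <- !is.finite(v) | v < valid_range_ms[1] | v > valid_range_ms[2]
  max_lag <- max(1L, floor(horizon_s / step))
  for (k in seq_len(max_lag)) {
    if (n <= k) break
    d <- abs(v[(1 + k):n] - v[1:(n - k)])
    hit <- which(is.finite(d) & d > spike_ms)
    if (length(hit)) {
      for (h in hit) bad[h:(h + k)] <- TRUE
    }
  }
  if (!any(bad)) return(event_list(type = "artifact"))
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  tt <- series_times(raw)
  ev <- event_list(pmax(tt[1], tt[starts] - pad_s),
                   tt[ends] + step + pad_s, type = "artifact")
  merge_events(ev)
}

#' Detect PTT arousals on the smoothed PTT2 channel
#'
#' A PTT arousal is a drop of at least `drop_ms` from a local maximum to a
#' following local minimum of PTT2, lasting between `window_s[1]` and
#' `window_s[2]` seconds, with both endpoints unmasked and inside the valid
#' PTT range. Because the smoothing filter broadens any drop by its own
#' span, the measured max-to-min duration is reduced by `smoothing_span_s`
#' before the duration gate is applied, so the gate acts on the duration of
#' the underlying drop. Candidate maxima are scanned left to right (earliest
#' qualifying maximum wins, paired with the deepest qualifying minimum);
#' after an event is accepted, scanning resumes at its minimum, so events
#' never overlap.
#'
#' @param ptt2 A [uniform_series()], the smoothed, masked PTT2 channel.
#' @param drop_ms Minimum drop in ms.
#' @param window_s Two-element duration gate in seconds.
#' @param valid_range_ms Valid PTT2 range in ms.
#' @param smoothing_span_s Temporal span of the smoothing filter,
#'   `(window - 1) * step`; defaults to the 17-point/5 Hz value.
#' @param shoulder_tolerance_ms How far below the event maximum the PTT2
#'   may sit while still counting as the pre-drop shoulder (absorbs
#'   breath-cycle ripple when timing the start of the fall).
#' @param shoulder_step_ms Backward step gain below which the pre-drop
#'   shoulder walk stops (distinguishes the flat baseline from the fall).
#' @return An [event_list()] of arousals `[t_max, t_min)` with a `drop_ms`
#'   column.
#' @export
detect_arousals <- function(ptt2, drop_ms = 15, window_s = c(5, 45),
                            valid_range_ms = c(150, 500),
                            smoothing_span_s = 16 * ptt2$step_s,
                            shoulder_tolerance_ms = 5,
                            shoulder_step_ms = 2) {
  stopifnot(inherits(ptt2, "uniform_series"))
  # coarse turning points with reversal threshold = the drop criterion:
  # breath-cycle ripple (well below drop_ms on PTT2) never reverses that
  # far, so every qualifying descent yields exactly one max -> min pair,
  # measured across the whole fall
  big <- turning_points(ptt2, prominence_ms = drop_ms)
  ev_s <- ev_e <- ev_d <- numeric(0)
  if (nrow(big) >= 2L) {
    # fine-scale turning points time the pre-drop shoulder: the fall
    # starts at the last small-scale maximum still within
    # `shoulder_tolerance_ms` of the event maximum
    fine <- turning_points(ptt2, prominence_ms = 1)
    fmax <- fine[fine$type == "max", , drop = FALSE]
    for (k in seq_len(nrow(big) - 1L)) {
      if (big$type[k] != "max" || big$type[k + 1L] != "min" ||
          big$segment[k] != big$segment[k + 1L]) next
      v_max <- big$value[k]; v_min <- big$value[k + 1L]
      t_min <- big$time_s[k + 1L]
      d <- v_max - v_min
      if (d < drop_ms) next
      if (v_max < valid_range_ms[1] || v_max > valid_range_ms[2] ||
          v_min < valid_range_ms[1] || v_min > valid_range_ms[2]) next
      prev_end <- if (k > 1L && big$segment[k - 1L] == big$segment[k])
        big$time_s[k - 1L] else -Inf
      cand <- which(fmax$time_s >= max(big$time_s[k], prev_end) &
                      fmax$time_s < t_min &
                      fmax$segment == big$segment[k])
      # walk backward from the trough over fine-scale maxima: climb until
      # within the shoulder tolerance of the event maximum, then stop at
      # the first near-flat step (the baseline plateau before the fall)
      t_start <- big$time_s[k]
      if (length(cand)) {
        vals <- fmax$value[cand]; tms <- fmax$time_s[cand]
        j <- length(cand)
        while (j >= 1L) {
          if (vals[j] >= v_max - shoulder_tolerance_ms &&
              (j == 1L || vals[j - 1L] - vals[j] < shoulder_step_ms)) break
          j <- j - 1L
        }
        if (j >= 1L) t_start <- tms[j]
      }
      dur <- t_min - t_start - smoothing_span_s
      if (dur >= window_s[1] && dur <= window_s[2]) {
        ev_s <- c(ev_s, t_start)
        ev_e <- c(ev_e, t_min)
        ev_d <- c(ev_d, d)
      }
    }
  }
  event_list(ev_s, ev_e, type = "arousal", drop_ms = ev_d)
}

#' PTT arousal index
#'
#' Arousals per hour of artifact-free PTT recording.
#'
#' @param events An [event_list()] of arousals.
#' @param hours Artifact-free PTT hours (> 0).
#' @return Events per hour.
#' @export
arousal_index <- function(events, hours) {
  if (!is.numeric(hours) || length(hours) != 1L || !is.finite(hours) || hours <= 0)
    stop("`hours` must be a positive number of artifact-free hours")
  nrow(events) / hours
}

#' Respiratory swing of the PTT signal
#'
#' The PTT channel oscillates with the breath cycle (inspiratory effort
#' lowers intrathoracic pressure and stretches PTT). The swing statistic is
#' computed on a derived channel: the valid beats are linearly interpolated
#' to a 1 s grid, a centred 3-sample moving average is applied (shrinking
#' to the available samples at the edges), alternating troughs and peaks
#' are extracted outside artifact spans, and the mean rise from each
#' inspiratory trough to the following expiratory peak is returned, in ms.
#'
#' @param raw_beats A [beat_ptt_series()].
#' @param artifact_spans Optional [event_list()] of artifact spans to
#'   exclude.
#' @param prominence_ms Minimum trough-to-peak reversal retained (suppresses
#'   numerical jitter).
#' @param min_minutes Minimum artifact-free duration required, minutes.
#' @return The mean trough-to-peak rise in ms.
#' @export
respiratory_swing <- function(raw_beats, artifact_spans = NULL,
                              prominence_ms = 1, min_minutes = 10) {
  stopifnot(inherits(raw_beats, "beat_ptt_series"))
  v <- raw_beats$valid
  if (sum(v) < 2L) stop("need at least 2 valid beats")
  bt <- raw_beats$beat_time_s
  grid <- seq(ceiling(bt[v][1]), floor(bt[v][sum(v)]), by = 1)
  if (length(grid) < 3L) stop("series too short for the swing channel")
  y <- stats::approx(bt[v], raw_beats$ptt_ms[v], xout = grid)$y
  # centred 3-sample mean, shrinking at the edges
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[1] <- mean(y[1:2]); ys[length(y)] <- mean(y[(length(y) - 1):length(y)])
  j <- findInterval(grid, bt)
  j <- pmin(pmax(j, 1L), length(bt) - 1L)
  bad <- !v[j] | !v[j + 1L]
  chan <- uniform_series(ys, step_s = 1, start_s = grid[1], mask = bad)
  if (!is.null(artifact_spans)) chan <- mask_events(chan, artifact_spans)
  if (artifact_free_hours(chan) * 60 < min_minutes)
    stop(sprintf("need at least %g min of artifact-free data for the respiratory swing",
                 min_minutes))
  tp <- turning_points(chan, prominence_ms = prominence_ms)
  if (nrow(tp) < 2L)
    stop("no trough-to-peak pairs: the swing channel has no qualifying oscillation")
  rises <- numeric(0)
  for (k in seq_len(nrow(tp) - 1L)) {
    if (tp$type[k] == "min" && tp$type[k + 1L] == "max" &&
        tp$segment[k] == tp$segment[k + 1L])
      rises <- c(rises, tp$value[k + 1L] - tp$value[k])
  }
  if (!length(rises))
    stop("no trough-to-peak pairs: the swing channel has no qualifying oscillation")
  mean(rises)
}

#' Full PTT feature set for one record
#'
#' Composition of the PTT pipeline: resample the beat series, detect
#' artifact spans, mask them, smooth into PTT2, detect arousals, and compute
#' the arousal index (per artifact-free hour) and the respiratory swing
#' (excluding artifact spans). Records whose swing channel carries no
#' qualifying oscillation (e.g. a flat test record) report a swing of 0.
#'
#' @param raw_beats A [beat_ptt_series()].
#' @param target_hz Resampling rate for the raw PTT channel.
#' @param drop_ms,window_s,valid_range_ms Arousal rule constants.
#' @param spike_ms,pad_s Artifact rule constants.
#' @param ptt2_window PTT2 averaging window, samples.
#' @param min_ptt_hours Inclusion threshold on artifact-free PTT hours.
#' @return A list of class `ptt_feature_set`: `ptt_arousal_count`,
#'   `ptt_arousal_index`, `respiratory_swing_ms`, `artifact_free_hours`,
#'   `arousal_events`, `artifact_spans`, `included_ptt`.
#' @export
ptt_features_for_record <- function(raw_beats, target_hz = 5,
                                    drop_ms = 15, window_s = c(5, 45),
                                    valid_range_ms = c(150, 500),
                                    spike_ms = 50, pad_s = 2,
                                    ptt2_window = 17, min_ptt_hours = 3) {
  raw <- resample_ptt(raw_beats, target_hz = target_hz)
  spans <- detect_ptt_artifact(raw, spike_ms = spike_ms,
                               valid_range_ms = valid_range_ms, pad_s = pad_s)
  raw <- mask_events(raw, spans)
  hours <- artifact_free_hours(raw)
  ptt2 <- smooth_ptt2(raw, window = ptt2_window)
  ar <- detect_arousals(ptt2, drop_ms = drop_ms, window_s = window_s,
                        valid_range_ms = valid_range_ms,
                        smoothing_span_s = (ptt2_window - 1) / target_hz)
  idx <- if (hours > 0) arousal_index(ar, hours) else NA_real_
  swing <- tryCatch(
    respiratory_swing(raw_beats, artifact_spans = spans),
    error = function(e) {
      if (grepl("no trough-to-peak pairs", conditionMessage(e))) 0 else stop(e)
    }
  )
  structure(
    list(ptt_arousal_count = nrow(ar),
         ptt_arousal_index = idx,
         respiratory_swing_ms = swing,
         artifact_free_hours = hours,
         arousal_events = ar,
         artifact_spans = spans,
         included_ptt = hours >= min_ptt_hours),
    class = "ptt_feature_set"
  )
}

#' @export
print.ptt_feature_set <- function(x, ...) {
  cat(sprintf(
    "<ptt_feature_set> PTT-AI %.2f/h (%d arousals), swing %.2f ms, %.2f artifact-free h%s\n",
    x$ptt_arousal_index, x$ptt_arousal_count, x$respiratory_swing_ms,
    x$artifact_free_hours,
    if (x$included_ptt) "" else " [excluded: <3 h]"))
  invisible(x)
}
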