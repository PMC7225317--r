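#' Configuration for the synthetic sleep-study cohort
#'
#' Defines the generative conditions for a cohort of children referred for
#' multi-channel sleep studies. Each child is assigned one of four
#' diagnostic categories; the category controls the respiratory modulation
#' of the PTT signal (inspiratory effort), the subcortical arousal rate and
#' the oxygen desaturation profile, so that downstream detectors can be
#' validated against planted ground truth.
#'
#' Category proportions default to the mix observed in secondary-care
#' referral cohorts (roughly 65% normal/primary snoring vs 35% UARS/OSA,
#' with OSA the smaller part of the obstructed group). The respiratory
#' swing separation (12 vs 22 ms peak-to-trough) and arousal rates (8 vs
#' 25 per hour) reproduce the qualitative group separation reported for
#' these indices. Breath periods are drawn from 4.3–4.7 s, inside the
#' physiological range for sleeping children and chosen where the swing
#' measurement chain (1 Hz interpolation + 3-sample mean) has a flat
#' frequency response; see the methods vignette.
#'
#' @param n_children Number of children.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param category_probs Named probabilities for
#'   `normal`, `primary_snoring`, `uars`, `osa`; must sum to 1.
#' @param study_hours Recording duration per child, hours.
#' @param ptt_baseline_ms Mean/sd of the per-child PTT baseline; the mean
#'   must lie in the 150–500 ms valid range.
#' @param swing_params Per-category `c(mean, sd)` of the planted
#'   peak-to-trough respiratory swing, ms.
#' @param arousal_rate_per_h Per-category PTT arousal rates, events/hour.
#' @param desat_rate_per_h Per-category desaturation rates, events/hour.
#' @param desat_depth_pct Per-category `c(min, max)` of the uniform dip
#'   depth below baseline, percentage points.
#' @param artifact_spike_rate_per_h Rate of planted high-amplitude PTT
#'   artifact spikes, events/hour.
#' @param spike_ms Amplitude of planted artifact spikes, ms.
#' @param breath_period_s Range of the per-child breath period, seconds.
#' @param heart_rate_bpm Mean/sd of the per-child heart rate.
#' @param ptt_noise_ms Beat-to-beat PTT measurement noise sd, ms.
#' @param spo2_baseline_pct Mean/sd of the per-child baseline saturation.
#' @param spo2_noise_pct SpO2 sample noise sd, percentage points.
#' @param spo2_dropout_rate_per_h Rate of planted SpO2 dropouts.
#' @param fidelity `"beats"` (beat-series children, fast, default) or
#'   `"waveform"` (also synthesises ECG/plethysmograph waveforms).
#' @param sampling_hz Waveform sampling rate (waveform fidelity only).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_children = 368,
    seed = 1,
    category_probs = c(normal = 0.25, primary_snoring = 0.40,
                       uars = 0.22, osa = 0.13),
    study_hours = 8,
    ptt_baseline_ms = c(mean = 300, sd = 30),
    swing_params = list(normal = c(mean = 12, sd = 3),
                        primary_snoring = c(mean = 12, sd = 3),
                        uars = c(mean = 22, sd = 4),
                        osa = c(mean = 22, sd = 4)),
    arousal_rate_per_h = c(normal = 8, primary_snoring = 8,
                           uars = 25, osa = 25),
    desat_rate_per_h = c(normal = 0.5, primary_snoring = 0.5,
                         uars = 1.5, osa = 6),
    desat_depth_pct = list(normal = c(4.5, 5.2),
                           primary_snoring = c(4.5, 5.2),
                           uars = c(4.5, 5.2),
                           osa = c(8, 13)),
    artifact_spike_rate_per_h = 5,
    spike_ms = 120,
    breath_period_s = c(4.3, 4.7),
    heart_rate_bpm = c(mean = 90, sd = 8),
    ptt_noise_ms = 1,
    spo2_baseline_pct = c(mean = 97.3, sd = 0.4),
    spo2_noise_pct = 0.15,
    spo2_dropout_rate_per_h = 0.1,
    fidelity = c("beats", "waveform"),
    sampling_hz = 250) {
  fidelity <- match.arg(fidelity)
  cats <- c("normal", "primary_snoring", "uars", "osa")
  if (!setequal(names(category_probs), cats))
    stop("`category_probs` must name exactly: ", paste(cats, collapse = ", "))
  category_probs <- category_probs[cats]
  if (abs(sum(category_probs) - 1) > 1e-9)
    stop("`category_probs` must sum to 1")
  if (any(category_probs < 0))
    stop("`category_probs` must be non-negative")
  rates <- c(arousal_rate_per_h, desat_rate_per_h,
             artifact_spike_rate_per_h, spo2_dropout_rate_per_h)
  if (any(rates < 0)) stop("all event rates must be >= 0")
  if (ptt_baseline_ms[["mean"]] < 150 || ptt_baseline_ms[["mean"]] > 500)
    stop("`ptt_baseline_ms` mean must lie within the valid range [150, 500] ms")
  if (n_children < 1) stop("`n_children` must be at least 1")
  if (study_hours <= 0) stop("`study_hours` must be positive")
  structure(
    list(n_children = as.integer(n_children), seed = as.integer(seed),
         category_probs = category_probs, study_hours = study_hours,
         ptt_baseline_ms = ptt_baseline_ms, swing_params = swing_params,
         arousal_rate_per_h = arousal_rate_per_h,
         desat_rate_per_h = desat_rate_per_h,
         desat_depth_pct = desat_depth_pct,
         artifact_spike_rate_per_h = artifact_spike_rate_per_h,
         spike_ms = spike_ms, breath_period_s = breath_period_s,
         heart_rate_bpm = heart_rate_bpm, ptt_noise_ms = ptt_noise_ms,
         spo2_baseline_pct = spo2_baseline_pct,
         spo2_noise_pct = spo2_noise_pct,
         spo2_dropout_rate_per_h = spo2_dropout_rate_per_h,
         fidelity = fidelity, sampling_hz = sampling_hz),
    class = "cohort_config")
}

# uniform placement of n event start times in [lo, hi] with minimum gap,
# via the standard shifted-uniform construction for a hard-core process
place_events <- function(n, lo, hi, gap) {
  if (n <= 0) return(numeric())
  span <- hi - lo - (n - 1) * gap
  while (span <= 0 && n > 1) {           # clamp to what fits
    n <- n - 1L
    span <- hi - lo - (n - 1) * gap
  }
  if (span <= 0) return(numeric())
  sort(stats::runif(n, 0, span)) + lo + (seq_len(n) - 1) * gap
}

#' Draw the per-child ground-truth parameters of a cohort
#'
#' The generative layer of [generate_cohort()]: diagnostic category,
#' PTT baseline, planted respiratory swing amplitude, breath period, heart
#' rate, event counts and annotation summaries for each child, without
#' synthesising any signal. Useful for studies of the threshold-selection
#' procedure that only need the generative values.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per child.
#' @export
draw_cohort_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, draw_cohort_truth_impl(config))
}

draw_cohort_truth_impl <- function(config) {
  n <- config$n_children
  cats <- names(config$category_probs)
  category <- sample(cats, n, replace = TRUE, prob = config$category_probs)
  swing_mean <- vapply(category, function(g) config$swing_params[[g]][["mean"]], numeric(1))
  swing_sd <- vapply(category, function(g) config$swing_params[[g]][["sd"]], numeric(1))
  true_swing <- pmax(2, stats::rnorm(n, swing_mean, swing_sd))
  baseline <- pmin(500, pmax(150, stats::rnorm(n, config$ptt_baseline_ms[["mean"]],
                                               config$ptt_baseline_ms[["sd"]])))
  hrs <- config$study_hours
  data.frame(
    child_id = sprintf("child_%03d", seq_len(n)),
    category = category,
    ptt_baseline_ms = baseline,
    true_swing_ms = true_swing,
    breath_period_s = stats::runif(n, config$breath_period_s[1],
                                   config$breath_period_s[2]),
    heart_rate_bpm = pmin(130, pmax(65, stats::rnorm(
      n, config$heart_rate_bpm[["mean"]], config$heart_rate_bpm[["sd"]]))),
    n_arousals = stats::rpois(n, config$arousal_rate_per_h[category] * hrs),
    n_desats = stats::rpois(n, config$desat_rate_per_h[category] * hrs),
    n_artifacts = stats::rpois(n, config$artifact_spike_rate_per_h * hrs),
    spo2_baseline_pct = pmin(98.5, pmax(96.5, stats::rnorm(
      n, config$spo2_baseline_pct[["mean"]], config$spo2_baseline_pct[["sd"]]))),
    n_obstructive = ifelse(category %in% c("uars", "osa"),
                           3L + stats::rpois(n, 4),
                           ifelse(category == "primary_snoring",
                                  sample(0:2, n, replace = TRUE), 0L)),
    snoring = category != "normal",
    stringsAsFactors = FALSE)
}

#' Plant a PTT arousal into a beat series
#'
#' Subtracts a drop-hold-recover profile from the per-beat PTT values: the
#' PTT falls linearly by `drop_ms` over `fall_s` seconds starting at `at`,
#' holds for `hold_s`, then recovers linearly over `recover_s`. Only beats
#' inside the profile are changed.
#'
#' @param series A [beat_ptt_series()].
#' @param at Start time of the drop, seconds; must lie within the series.
#' @param drop_ms Size of the drop, ms.
#' @param fall_s Duration of the fall, seconds (detectable arousals use
#'   5–45 s).
#' @param hold_s Plateau at the bottom, seconds.
#' @param recover_s Recovery duration, seconds; defaults to `fall_s`.
#' @return The modified [beat_ptt_series()].
#' @export
plant_arousal <- function(series, at, drop_ms, fall_s, hold_s = 2,
                          recover_s = fall_s) {
  stopifnot(inherits(series, "beat_ptt_series"))
  bt <- series$beat_time_s
  if (at < bt[1] || at > bt[length(bt)])
    stop("`at` lies outside the beat series span")
  knots <- c(at, at + fall_s, at + fall_s + hold_s,
             at + fall_s + hold_s + recover_s)
  prof <- stats::approx(knots, c(0, -drop_ms, -drop_ms, 0), xout = bt,
                        yleft = 0, yright = 0)$y
  beat_ptt_series(bt, series$ptt_ms + prof, series$valid)
}

# one child's signal bundle from its truth row
generate_child_impl <- function(tr, config) {
  hrs <- config$study_hours
  dur <- hrs * 3600
  rr <- 60 / tr$heart_rate_bpm
  n_beats <- ceiling(dur / rr) + 1L
  gaps <- pmax(0.35, stats::rnorm(n_beats, rr, 0.015))
  bt <- cumsum(gaps) - gaps[1]
  bt <- bt[bt <= dur]
  n <- length(bt)
  phase <- stats::runif(1, 0, 2 * pi)
  ptt <- tr$ptt_baseline_ms +
    (tr$true_swing_ms / 2) * sin(2 * pi * bt / tr$breath_period_s + phase) +
    stats::rnorm(n, 0, config$ptt_noise_ms)
  beats <- beat_ptt_series(bt, ptt)

  # arousals: drop-hold-recover profiles, well separated so each planted
  # event maps to one detected event
  arousal_t <- place_events(tr$n_arousals, 60, dur - 120, gap = 100)
  # drops and falls sit in the interior of the 15 ms / 5-45 s detection
  # rule so planted events are not boundary cases
  arousal_drop <- stats::runif(length(arousal_t), 18, 30)
  arousal_fall <- stats::runif(length(arousal_t), 12, 28)
  for (k in seq_along(arousal_t))
    beats <- plant_arousal(beats, arousal_t[k], arousal_drop[k], arousal_fall[k])

  # isolated high-amplitude artifact spikes, 1-3 beats long
  artifact_spans <- event_list(type = "artifact_truth")
  n_art <- tr$n_artifacts
  if (n_art > 0 && n > 30) {
    art_i <- sort(sample(10:(n - 10), n_art))
    art_len <- sample(1:3, n_art, replace = TRUE)
    sp_s <- sp_e <- numeric(0)
    pv <- beats$ptt_ms
    for (k in seq_len(n_art)) {
      i0 <- art_i[k]; i1 <- min(n - 1L, i0 + art_len[k] - 1L)
      pv[i0:i1] <- pv[i0:i1] + config$spike_ms
      sp_s <- c(sp_s, bt[i0]); sp_e <- c(sp_e, bt[i1 + 1L])
    }
    beats <- beat_ptt_series(bt, pv, beats$valid)
    artifact_spans <- event_list(sp_s, sp_e, type = "artifact_truth")
  }

  # SpO2 trace at 1 Hz with planted flat-bottomed dips
  tt <- seq(0, dur - 1, by = 1)
  sp <- tr$spo2_baseline_pct + stats::rnorm(length(tt), 0, config$spo2_noise_pct)
  # gap exceeds the longest dip footprint (100 s) so dips never overlap
  desat_t <- place_events(tr$n_desats, 60, dur - 200, gap = 130)
  depth_rng <- config$desat_depth_pct[[tr$category]]
  desat_truth <- event_list(type = "desat_truth")
  if (length(desat_t)) {
    d_s <- d_e <- numeric(0)
    for (k in seq_along(desat_t)) {
      depth <- stats::runif(1, depth_rng[1], depth_rng[2])
      flat <- stats::runif(1, 15, 90)
      t0 <- desat_t[k]
      knots <- c(t0, t0 + 5, t0 + 5 + flat, t0 + 10 + flat)
      prof <- stats::approx(knots, c(0, -depth, -depth, 0), xout = tt,
                            yleft = 0, yright = 0)$y
      sp <- sp + prof
      d_s <- c(d_s, t0); d_e <- c(d_e, t0 + 10 + flat)
    }
    desat_truth <- event_list(d_s, d_e, type = "desat_truth")
  }
  n_drop <- stats::rpois(1, config$spo2_dropout_rate_per_h * hrs)
  drop_t <- place_events(n_drop, 30, dur - 60, gap = 60)
  for (t0 in drop_t) sp[tt >= t0 & tt < t0 + stats::runif(1, 5, 20)] <- NA
  spo2 <- uniform_series(pmin(100, sp), step_s = 1, start_s = 0)

  # video/sound annotations consistent with the category
  n_obs <- tr$n_obstructive
  ep <- if (n_obs > 0) {
    ep_t <- place_events(n_obs, 60, dur - 120, gap = 60)
    event_list(ep_t, ep_t + stats::runif(length(ep_t), 10, 30),
               type = "obstructive",
               arousal_linked = rep(tr$category %in% c("uars", "osa"),
                                    length(ep_t)))
  } else NULL
  video <- video_annotations(tr$snoring, ep, study_span_s = c(0, dur))

  bundle <- list(
    child_id = tr$child_id, category = tr$category,
    beats = beats, spo2 = spo2, video = video,
    truth = list(category = tr$category,
                 arousal_times = arousal_t,
                 desat_intervals = desat_truth,
                 artifact_spans = artifact_spans,
                 true_swing_ms = tr$true_swing_ms,
                 n_obstructive = n_obs))
  if (config$fidelity == "waveform") {
    wf <- synthesize_waveforms(beats$beat_time_s, beats$ptt_ms,
                               sampling_hz = config$sampling_hz)
    bundle$ecg <- wf$ecg
    bundle$pleth <- wf$pleth
  }
  bundle
}

#' Generate a synthetic sleep-study cohort with known ground truth
#'
#' Draws per-child generative parameters ([draw_cohort_truth()]) and
#' synthesises, for each child, a per-beat PTT series with breath-cycle
#' modulation, planted arousal drops and artifact spikes; a 1 Hz SpO2 trace
#' with planted desaturation dips and dropouts; and video/sound annotations
#' consistent with the diagnostic category (OSA children receive at least 3
#' arousal-linked obstructive episodes and oximetry meeting the abnormal
#' criteria; normal children receive none). The output is a deterministic
#' function of the configuration.
#'
#' @param config A [cohort_config()].
#' @return A list with `children` (one signal bundle per child) and
#'   `truth` (the per-child generative data.frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    truth <- draw_cohort_truth_impl(config)
    children <- lapply(seq_len(nrow(truth)),
                       function(i) generate_child_impl(truth[i, ], config))
    # realised (placed) event counts can fall short of the drawn counts
    # when the study is too short to fit them all
    truth$n_arousals <- vapply(children,
                               function(ch) length(ch$truth$arousal_times),
                               numeric(1))
    truth$n_desats <- vapply(children,
                             function(ch) nrow(ch$truth$desat_intervals),
                             numeric(1))
    list(children = children, truth = truth, config = config)
  })
}

#' Synthesise ECG and plethysmograph waveforms from a beat/PTT plan
#'
#' Builds an idealised waveform pair realising a given per-beat PTT plan:
#' the ECG carries one narrow symmetric R wave per beat (midpoint at the
#' beat time), and the plethysmograph pulse has a raised-cosine upstroke
#' whose half-maximum point — by the symmetry of the raised cosine, the
#' midpoint of the upstroke — occurs exactly `ptt_ms` after the R midpoint.
#'
#' @param beat_times R-wave midpoint times, seconds; intervals must exceed
#'   0.3 s.
#' @param ptt_ms Positive per-beat PTT plan, ms.
#' @param sampling_hz Sampling rate; must resolve the smallest PTT with at
#'   least 4 samples.
#' @param upstroke_s Duration of the pulse upstroke, seconds.
#' @return A list with `ecg` and `pleth` ([uniform_series()]) and
#'   `sampling_hz`.
#' @export
synthesize_waveforms <- function(beat_times, ptt_ms, sampling_hz = 250,
                                 upstroke_s = 0.2) {
  beat_times <- as.numeric(beat_times)
  ptt_ms <- as.numeric(ptt_ms)
  if (length(beat_times) != length(ptt_ms))
    stop("`beat_times` and `ptt_ms` must have equal length")
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0.3))
    stop("beat intervals must exceed 0.3 s")
  if (any(!is.finite(ptt_ms) | ptt_ms <= 0))
    stop("`ptt_ms` must be positive")
  if (sampling_hz < 4 / (min(ptt_ms) / 1000))
    stop("sampling too coarse: need at least 4 samples per smallest PTT")
  ptt_s <- ptt_ms / 1000
  gaps <- diff(beat_times)
  if (length(gaps) && any(ptt_s[-length(ptt_s)] + upstroke_s / 2 >= gaps))
    stop("PTT plus half the upstroke must fit inside each beat interval")

  n_b <- length(beat_times)
  dur <- beat_times[n_b] + ptt_s[n_b] + upstroke_s + 0.5
  n <- ceiling(dur * sampling_hz) + 1L
  tt <- (seq_len(n) - 1) / sampling_hz
  ecg <- numeric(n)
  pleth <- numeric(n)

  r_width <- 0.02                              # narrow symmetric R wave
  for (i in seq_len(n_b)) {
    sel <- which(abs(tt - beat_times[i]) <= r_width)
    ecg[sel] <- pmax(ecg[sel], 1 - abs(tt[sel] - beat_times[i]) / r_width)
  }
  feet <- beat_times + ptt_s - upstroke_s / 2
  peaks <- feet + upstroke_s
  decay_end <- c(feet[-1], peaks[n_b] + 0.4)
  for (i in seq_len(n_b)) {
    up <- which(tt >= feet[i] & tt <= peaks[i])
    pleth[up] <- 0.5 - 0.5 * cos(pi * (tt[up] - feet[i]) / upstroke_s)
    dn <- which(tt > peaks[i] & tt < decay_end[i])
    if (length(dn))
      pleth[dn] <- 0.5 + 0.5 * cos(pi * (tt[dn] - peaks[i]) /
                                     (decay_end[i] - peaks[i]))
  }
  list(ecg = uniform_series(ecg, step_s = 1 / sampling_hz),
       pleth = uniform_series(pleth, step_s = 1 / sampling_hz),
       sampling_hz = sampling_hz)
}
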