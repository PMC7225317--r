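#' Detect R-wave peaks in an ECG trace
#'
#' Amplitude-threshold QRS detector intended for clean or synthetic signals:
#' within consecutive analysis blocks the threshold is 60% of the block's
#' 99th-percentile amplitude; runs of supra-threshold samples yield one peak
#' each (the maximum of the run, plateau centre on ties), and a refractory
#' period suppresses peaks closer than `refractory_s`. Flat or empty blocks
#' yield no peaks, so an all-zero trace returns an empty vector rather than
#' an error.
#'
#' @param ecg Numeric vector, the ECG waveform (R waves upright).
#' @param sampling_hz Sampling rate in Hz.
#' @param refractory_s Minimum spacing between peaks, seconds.
#' @param block_s Length of the threshold-adaptation block, seconds.
#' @param threshold_frac Fraction of the block's 99th-percentile amplitude
#'   used as detection threshold.
#' @return Numeric vector of R-wave midpoint times in seconds.
#' @export
detect_r_peaks <- function(ecg, sampling_hz, refractory_s = 0.25,
                           block_s = 10, threshold_frac = 0.6) {
  ecg <- as.numeric(ecg)
  n <- length(ecg)
  if (n < 10 * sampling_hz)
    stop("need at least 10 s of ECG signal")
  block <- max(1L, round(block_s * sampling_hz))
  above <- rep(FALSE, n)
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(n, b0 + block - 1L)
    seg <- ecg[b0:b1]
    if (!any(is.finite(seg))) next
    rng <- range(seg, finite = TRUE)
    if (diff(rng) < 1e-12) next                     # flat block: no beats
    thr <- threshold_frac * stats::quantile(seg, 0.99, names = FALSE, na.rm = TRUE)
    if (thr <= rng[1]) next
    above[b0:b1] <- is.finite(seg) & seg > thr
  }
  if (!any(above)) return(numeric())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  peak_idx <- mapply(function(s, e) {
    seg <- ecg[s:e]
    cand <- which(seg == max(seg))
    s + cand[ceiling(length(cand) / 2)] - 1L        # plateau centre
  }, starts, ends)
  peak_amp <- ecg[peak_idx]
  # refractory: strongest peak wins inside any refractory_s neighbourhood
  ord <- order(peak_amp, decreasing = TRUE)
  keep <- logical(length(peak_idx))
  taken <- numeric(0)
  for (j in ord) {
    t_j <- (peak_idx[j] - 1) / sampling_hz
    if (!length(taken) || min(abs(taken - t_j)) >= refractory_s) {
      keep[j] <- TRUE
      taken <- c(taken, t_j)
    }
  }
  sort((peak_idx[keep] - 1) / sampling_hz)
}

#' Half-maximum crossing times of plethysmograph pulse upstrokes
#'
#' For each beat window, locates the pulse foot (minimum preceding the
#' in-window peak) and reports the time at which the upstroke first crosses
#' 50% of the foot-to-peak amplitude, by linear interpolation between the
#' bracketing samples. Windows whose foot-to-peak amplitude is below
#' `min_amp_frac` of the median beat amplitude are treated as perfusion
#' dropout and yield no event.
#'
#' @param pleth Numeric vector, the plethysmograph waveform.
#' @param sampling_hz Sampling rate in Hz.
#' @param windows Two-column matrix or data.frame of half-open beat windows
#'   `[start_s, end_s)`, non-overlapping and sorted.
#' @param min_amp_frac Amplitude floor, as a fraction of the median
#'   foot-to-peak amplitude over all windows.
#' @return Numeric vector of crossing times in seconds (one per accepted
#'   window; rejected windows contribute nothing).
#' @export
pleth_half_max_times <- function(pleth, sampling_hz, windows,
                                 min_amp_frac = 0.05) {
  pleth <- as.numeric(pleth)
  w <- as.matrix(windows)[, 1:2, drop = FALSE]
  n <- length(pleth)
  dur <- (n - 1) / sampling_hz
  if (any(w[, 1] < 0) || any(w[, 2] > dur + 1 / sampling_hz))
    stop("beat window outside the signal span")
  if (nrow(w) > 1L && any(w[-1, 1] < w[-nrow(w), 2]))
    stop("beat windows must be non-overlapping and sorted")

  info <- lapply(seq_len(nrow(w)), function(i) {
    i0 <- max(1L, floor(w[i, 1] * sampling_hz) + 1L)
    i1 <- min(n, ceiling(w[i, 2] * sampling_hz))
    seg <- pleth[i0:i1]
    if (length(seg) < 3L) return(NULL)
    pk <- which.max(seg)
    if (pk == 1L) return(list(amp = 0, i0 = i0))
    ft <- which.min(seg[1:pk])
    list(amp = seg[pk] - seg[ft], i0 = i0, seg = seg, pk = pk, ft = ft)
  })
  amps <- vapply(info, function(z) if (is.null(z)) 0 else z$amp, numeric(1))
  if (!any(amps > 0)) return(numeric(0))          # no pulses at all
  floor_amp <- min_amp_frac * stats::median(amps[amps > 0])

  out <- numeric(0)
  for (z in info) {
    if (is.null(z) || z$amp <= 0 || z$amp < floor_amp) next
    half <- z$seg[z$ft] + 0.5 * z$amp
    up <- z$seg[z$ft:z$pk]
    k <- which(up >= half)[1]
    if (is.na(k)) next
    if (k == 1L) {
      cross <- z$ft
    } else {
      frac <- (half - up[k - 1]) / (up[k] - up[k - 1])
      cross <- z$ft + (k - 2) + frac
    }
    out <- c(out, (z$i0 - 1 + cross - 1) / sampling_hz)
  }
  out
}

#' Match R-wave and pulse-arrival times into a per-beat PTT series
#'
#' Each R wave is paired with the first pulse (half-maximum) time that
#' follows it and precedes the next R wave; the pulse transit time is the
#' difference in milliseconds. Beats with no pulse arrival in their window
#' are kept but flagged invalid.
#'
#' @param r_times Sorted R-wave midpoint times, seconds.
#' @param pleth_times Sorted pulse half-maximum times, seconds.
#' @return A [beat_ptt_series()].
#' @export
compute_beat_ptt <- function(r_times, pleth_times) {
  r_times <- as.numeric(r_times)
  pleth_times <- as.numeric(pleth_times)
  if (is.unsorted(r_times, strictly = TRUE) || is.unsorted(pleth_times))
    stop("`r_times` and `pleth_times` must be sorted")
  n <- length(r_times)
  ptt <- rep(NA_real_, n)
  if (length(pleth_times)) {
    nxt <- findInterval(r_times, pleth_times) + 1L   # first pleth strictly after
    upper <- c(r_times[-1], Inf)
    ok <- nxt <= length(pleth_times)
    ok[ok] <- pleth_times[nxt[ok]] < upper[ok] & pleth_times[nxt[ok]] > r_times[ok]
    ptt[ok] <- (pleth_times[nxt[ok]] - r_times[ok]) * 1000
  }
  beat_ptt_series(r_times, ptt, valid = is.finite(ptt) & ptt > 0)
}

#' Resample a per-beat PTT series onto a uniform grid
#'
#' Linear interpolation of the valid beats onto a grid at `target_hz`,
#' spanning the first to the last valid beat. Grid samples that bridge an
#' invalid beat (either neighbouring beat in the full beat sequence is
#' invalid) are masked.
#'
#' @param series A [beat_ptt_series()].
#' @param target_hz Grid rate in Hz; 5 Hz makes the 17-point PTT2 window
#'   span ~3.2 s, matching the instrument's ~3.5 s smoothing.
#' @return A [uniform_series()] in milliseconds.
#' @export
resample_ptt <- function(series, target_hz = 5) {
  stopifnot(inherits(series, "beat_ptt_series"))
  v <- series$valid
  if (sum(v) < 2L) stop("need at least 2 valid beats to resample")
  bt <- series$beat_time_s
  step <- 1 / target_hz
  grid <- seq(bt[v][1], bt[v][sum(v)], by = step)
  vals <- stats::approx(bt[v], series$ptt_ms[v], xout = grid)$y
  # mask samples lying in an inter-beat interval touching an invalid beat
  j <- findInterval(grid, bt)
  j <- pmin(pmax(j, 1L), length(bt) - 1L)
  bad <- !v[j] | !v[j + 1L]
  uniform_series(vals, step_s = step, start_s = grid[1], mask = bad)
}
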