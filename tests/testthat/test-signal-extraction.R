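test_that("R-peak detection handles impulse trains, silence and noise", {
  fs <- 100
  tt <- seq(0, 60, by = 1 / fs)
  beats <- seq(1, 59, by = 1)
  ecg <- numeric(length(tt))
  for (b in beats) {
    sel <- abs(tt - b) < 0.02
    ecg[sel] <- 1 - abs(tt[sel] - b) / 0.02
  }
  r <- detect_r_peaks(ecg, fs)
  expect_length(r, length(beats))
  expect_true(all(abs(r - beats) <= 1 / fs + 1e-9))

  expect_identical(detect_r_peaks(numeric(20 * fs), fs), numeric())
  expect_error(detect_r_peaks(numeric(5), fs), "10 s")

  # additive noise at SNR 10: at least 98% of beats matched within 20 ms
  withr::with_seed(4, {
    noisy <- ecg + rnorm(length(ecg), 0, sqrt(mean(ecg^2) / 10))
    rn <- detect_r_peaks(noisy, fs)
    matched <- vapply(beats, function(b) any(abs(rn - b) <= 0.02), logical(1))
    expect_gte(mean(matched), 0.98)
  })
})

test_that("pleth half-maximum timing is exact for raised-cosine pulses", {
  fs <- 200
  tt <- seq(0, 3, by = 1 / fs)
  # foot at 1.0 s, peak at 1.2 s: half-maximum at 1.1 s by symmetry
  pl <- numeric(length(tt))
  up <- tt >= 1 & tt <= 1.2
  pl[up] <- 0.5 - 0.5 * cos(pi * (tt[up] - 1) / 0.2)
  pl[tt > 1.2] <- 1
  out <- pleth_half_max_times(pl, fs, matrix(c(0.5, 2.5), 1))
  expect_equal(out, 1.1, tolerance = 1 / fs)

  # flat window yields no event
  expect_length(pleth_half_max_times(rep(0.2, 401), fs, matrix(c(0.5, 1.5), 1)), 0)
  expect_error(pleth_half_max_times(pl, fs, matrix(c(2, 9), 1)), "span")
})

test_that("beat matching equals the brute-force all-pairs matcher", {
  expect_equal(compute_beat_ptt(10, 10.25)$ptt_ms, 250)
  b <- compute_beat_ptt(c(10, 11), 10.25)
  expect_identical(b$valid, c(TRUE, FALSE))

  withr::with_seed(8, {
    for (case in 1:1000) {
      n <- sample(2:15, 1)
      r <- sort(runif(n, 0, 30))
      r <- r[c(TRUE, diff(r) > 1e-3)]
      p <- sort(runif(sample(0:15, 1), 0, 30))
      got <- compute_beat_ptt(r, p)
      want <- oracle_beat_match(r, p)
      expect_equal(got$ptt_ms, want)
    }
  })
})

test_that("resampling is piecewise-linear and masks invalid bridges", {
  b <- const_beats(10, rr = 1, ptt = 300)
  u <- resample_ptt(b, target_hz = 5)
  expect_true(all(abs(u$values - 300) < 1e-9))
  expect_false(any(u$mask))

  b2 <- beat_ptt_series(c(0, 1), c(300, 310))
  u2 <- resample_ptt(b2, target_hz = 2)
  expect_equal(u2$values[series_times(u2) == 0.5], 305)

  expect_error(resample_ptt(beat_ptt_series(0, 300)), "2 valid beats")

  withr::with_seed(9, {
    for (case in 1:50) {
      n <- sample(5:40, 1)
      bt <- cumsum(runif(n, 0.4, 1.2))
      ptt <- runif(n, 200, 400)
      valid <- runif(n) > 0.15
      valid[c(1, n)] <- TRUE
      b <- beat_ptt_series(bt, ifelse(valid, ptt, NA), valid)
      u <- resample_ptt(b, target_hz = 5)
      tt <- series_times(u)
      want <- oracle_interp(bt[valid], ptt[valid], tt)
      expect_equal(u$values, want, tolerance = 1e-10)
      expect_true(all(diff(tt) > 0))
      # samples bridging an invalid beat are masked
      for (j in which(!valid)) {
        inside <- tt >= bt[max(1, j - 1)] & tt < bt[min(n, j + 1)]
        expect_true(all(u$mask[inside]))
      }
    }
  })
})

test_that("synthesize -> extract round trip recovers planted PTT (sampled seeds)", {
  for (sd in 1:10) {
    withr::with_seed(sd, {
      n <- 25
      bt <- cumsum(runif(n, 0.7, 0.9))
      ptt <- runif(n, 200, 400)
      fs <- 250
      wf <- synthesize_waveforms(bt, ptt, sampling_hz = fs)
      r <- detect_r_peaks(wf$ecg$values, fs)
      expect_length(r, n)
      win <- cbind(r, c(r[-1], r[n] + 0.9))
      pl <- pleth_half_max_times(wf$pleth$values, fs, win)
      b <- compute_beat_ptt(r, pl)
      expect_true(all(b$valid))
      expect_lte(max(abs(b$ptt_ms - ptt)), 1000 / fs)
    })
  }
})
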