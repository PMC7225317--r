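test_that("PTT2 smoothing matches the brute-force windowed mean", {
  u <- us(rep(250, 60))
  s <- smooth_ptt2(u)
  expect_true(all(abs(s$values[!s$mask] - 250) < 1e-9))

  v <- numeric(33); v[17] <- 170
  s2 <- smooth_ptt2(us(v))
  expect_equal(s2$values[17], 10)

  expect_error(smooth_ptt2(us(rep(1, 10))), "shorter")

  withr::with_seed(11, {
    for (case in 1:200) {
      n <- sample(17:80, 1)
      vals <- runif(n, 150, 500)
      mask <- runif(n) < 0.2
      s <- smooth_ptt2(us(vals, mask = mask))
      want <- oracle_moving_mean(vals, mask, 17)
      expect_equal(s$mask, want$mask)
      expect_equal(s$values[!s$mask], want$values[!want$mask])
    }
  })
})

test_that("turning points match the plain-R state machine", {
  withr::with_seed(12, {
    for (case in 1:1000) {
      n <- sample(5:60, 1)
      x <- cumsum(rnorm(n))
      prom <- runif(1, 0.1, 2)
      got <- turning_points(us(x), prominence_ms = prom)
      want <- oracle_turning_points(x, prom)
      expect_equal(got$idx, want$idx)
      expect_equal(got$type,
                   if (length(want$type))
                     ifelse(want$type > 0, "max", "min")
                   else character(0))
    }
  })
})

test_that("PTT artifact spans follow the spike and valid-range rules", {
  expect_equal(nrow(detect_ptt_artifact(us(rep(300, 100)))), 0)

  v <- rep(300, 200); v[100:102] <- 420          # +120 ms spike
  ev <- detect_ptt_artifact(us(v))
  expect_equal(nrow(ev), 1)
  expect_lte(ev$start_s[1], 99 * 0.2 - 2 + 0.21)
  expect_gte(ev$end_s[1], 102 * 0.2 + 2)

  v2 <- rep(300, 200); v2[50:60] <- 600          # outside 150-500 ms
  ev2 <- detect_ptt_artifact(us(v2))
  expect_equal(nrow(ev2), 1)
  tt <- series_times(us(v2))
  expect_true(all(times_in <- tt[50:60] >= ev2$start_s[1] &
                    tt[50:60] < ev2$end_s[1]))
})

test_that("arousal detection follows the drop/duration/valid-range rule", {
  ramp <- function(drop, fall_s, base = 300, step = 0.2) {
    pre <- rep(base, 500)
    fall <- seq(base, base - drop, length.out = round(fall_s / step) + 1)
    post <- rep(base - drop, 500)
    us(c(pre, fall[-1], post), step = step)
  }
  expect_equal(nrow(detect_arousals(us(rep(300, 1000)))), 0)
  expect_equal(nrow(detect_arousals(ramp(20, 10))), 1)
  expect_equal(nrow(detect_arousals(ramp(20, 2))), 0)
  expect_equal(nrow(detect_arousals(ramp(20, 50))), 0)
  expect_equal(nrow(detect_arousals(ramp(14.9, 10))), 0)
  # drop from outside the valid range is ignored
  expect_equal(nrow(detect_arousals(ramp(20, 10, base = 600))), 0)
})

test_that("the arousal index is events per artifact-free hour", {
  ev <- event_list(c(1, 2, 3, 4, 5, 6, 7, 8) * 100,
                   c(1, 2, 3, 4, 5, 6, 7, 8) * 100 + 10, type = "arousal")
  expect_equal(arousal_index(ev, 4), 2)
  expect_equal(arousal_index(event_list(type = "arousal"), 4), 0)
  expect_error(arousal_index(ev, 0), "positive")
})

test_that("respiratory swing matches the closed-form attenuation of a sinusoid", {
  # beats exactly on the 1 s grid, period 4 s: the 3-sample moving mean has
  # gain (1 + 2 cos(pi/2))/3 = 1/3, so a planted peak-to-trough A yields A/3
  bt <- seq(0, 1800, by = 1)
  A <- 30
  b <- beat_ptt_series(bt, 300 + (A / 2) * sin(2 * pi * bt / 4))
  expect_equal(respiratory_swing(b), A / 3, tolerance = 1e-6)

  # scale equivariance: doubling the modulation doubles the swing
  b2 <- beat_ptt_series(bt, 300 + A * sin(2 * pi * bt / 4))
  expect_equal(respiratory_swing(b2) / respiratory_swing(b), 2,
               tolerance = 0.01)

  expect_error(respiratory_swing(const_beats(1200)), "no trough-to-peak")
  expect_error(respiratory_swing(const_beats(120)), "10 min")
})

test_that("swing is scale-equivariant across modulation amplitudes", {
  withr::with_seed(14, {
    bt <- cumsum(runif(2000, 0.6, 0.8))
    base <- sin(2 * pi * bt / 4.5)
    for (k in c(2, 5)) {
      b1 <- beat_ptt_series(bt, 300 + 6 * base)
      bk <- beat_ptt_series(bt, 300 + 6 * k * base)
      expect_equal(respiratory_swing(bk) / respiratory_swing(b1), k,
                   tolerance = 0.01)
    }
  })
})

test_that("adding artifact spans never increases the arousal count", {
  withr::with_seed(15, {
    for (case in 1:40) {
      b <- const_beats(1500)
      for (at in runif(3, 100, 1300))
        b <- plant_arousal(b, at, runif(1, 16, 30), runif(1, 8, 20))
      raw <- resample_ptt(b)
      base_spans <- detect_ptt_artifact(raw)
      n0 <- nrow(detect_arousals(smooth_ptt2(mask_events(raw, base_spans))))
      s0 <- runif(1, 0, 1400)
      extra <- event_list(s0, s0 + runif(1, 5, 120), type = "artifact")
      n1 <- nrow(detect_arousals(smooth_ptt2(mask_events(raw, rbind(base_spans, extra)))))
      expect_lte(n1, n0)
    }
  })
})

test_that("the per-record feature set composes the pipeline and flags exclusions", {
  f <- ptt_features_for_record(const_beats(1200))
  expect_equal(f$ptt_arousal_count, 0)
  expect_equal(f$respiratory_swing_ms, 0)
  expect_false(f$included_ptt)                      # 20 min < 3 h

  b <- plant_arousal(const_beats(4 * 3600, rr = 0.8), 7000, 20, 15)
  f2 <- ptt_features_for_record(b)
  expect_equal(f2$ptt_arousal_count, 1)
  expect_true(f2$included_ptt)
  expect_equal(f2$ptt_arousal_index,
               1 / f2$artifact_free_hours)
})
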