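test_that("cohort generation is deterministic and respects the category mixture", {
  cfg <- cohort_config(n_children = 6, seed = 99, study_hours = 0.5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # degenerate mixture: everyone normal, no obstruction planted
  cfg_n <- cohort_config(n_children = 12, seed = 3, study_hours = 0.5,
                         category_probs = c(normal = 1, primary_snoring = 0,
                                            uars = 0, osa = 0))
  coh <- generate_cohort(cfg_n)
  expect_true(all(coh$truth$category == "normal"))
  expect_true(all(vapply(coh$children,
                         function(ch) nrow(ch$video$episodes), numeric(1)) == 0))

  # realised category counts stay inside binomial 99% bounds at n = 368
  cfg_full <- cohort_config(seed = 12)
  truth <- draw_cohort_truth(cfg_full)
  n_pos <- sum(truth$category %in% c("uars", "osa"))
  p <- sum(cfg_full$category_probs[c("uars", "osa")])
  bounds <- qbinom(c(0.005, 0.995), 368, p)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(category_probs = c(normal = 0.7, primary_snoring = 0.2,
                                                uars = 0.2, osa = 0.1)),
               "sum to 1")
  expect_error(cohort_config(category_probs = c(normal = 1.2, primary_snoring = -0.2,
                                                uars = 0, osa = 0)),
               "non-negative")
  expect_error(cohort_config(ptt_baseline_ms = c(mean = 100, sd = 10)),
               "valid range")
  expect_error(cohort_config(artifact_spike_rate_per_h = -1), ">= 0")
})

test_that("planted arousals follow the drop/duration rule downstream", {
  run_one <- function(drop, fall) {
    b <- plant_arousal(const_beats(1200), at = 600, drop_ms = drop,
                       fall_s = fall)
    ptt_features_for_record(b)$ptt_arousal_count
  }
  expect_equal(run_one(20, 10), 1)   # inside the rule
  expect_equal(run_one(10, 10), 0)   # sub-threshold drop
  expect_equal(run_one(20, 2), 0)    # faster than the 5 s gate
  expect_equal(run_one(20, 50), 0)   # slower than the 45 s gate
  expect_error(plant_arousal(const_beats(100), at = 500, drop_ms = 20,
                             fall_s = 10),
               "outside")
})

test_that("category labels are consistent with planted oximetry and annotations", {
  cfg <- cohort_config(n_children = 40, seed = 21, study_hours = 2)
  coh <- generate_cohort(cfg)
  agree <- vapply(seq_along(coh$children), function(i) {
    ch <- coh$children[[i]]
    ox <- oximetry_summary(ch$spo2, min_hours = 1.5)
    assigned <- classify_study(ox$category, ch$video)
    ok_label <- assigned == ch$category
    abn <- ox$category %in% c("abnormal_low_risk", "abnormal_high_risk")
    ok_ox <- if (ch$category == "osa") abn else !abn
    ok_ep <- if (ch$category == "osa")
      nrow(ch$video$episodes) >= 3 else TRUE
    ok_label && ok_ox && ok_ep
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("synthesized waveforms realise the planted PTT geometry", {
  # single beat: pleth half-maximum lands at R + ptt within one sample
  fs <- 250
  wf <- synthesize_waveforms(c(5), 250, sampling_hz = fs)
  pl <- pleth_half_max_times(wf$pleth$values, fs,
                             matrix(c(4.8, 5.8), 1))
  expect_equal(pl, 5.25, tolerance = 1 / fs)

  # an impulse train of beats is fully recovered by the detector
  bt <- seq(1, 60, by = 1)
  wf <- synthesize_waveforms(bt, rep(300, length(bt)), sampling_hz = 100)
  r <- detect_r_peaks(wf$ecg$values, 100)
  expect_length(r, length(bt))
  expect_true(all(abs(r - bt) <= 1 / 100 + 1e-9))

  # sampling too coarse to resolve the smallest PTT
  expect_error(synthesize_waveforms(c(5), 200, sampling_hz = 10), "coarse")
})
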