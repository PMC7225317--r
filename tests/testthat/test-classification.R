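mk_video <- function(snoring, n_ep, n_arousal) {
  ep <- if (n_ep > 0) {
    starts <- seq(100, by = 200, length.out = n_ep)
    event_list(starts, starts + 20, type = "obstructive",
               arousal_linked = seq_len(n_ep) <= n_arousal)
  } else NULL
  video_annotations(snoring, ep)
}

test_that("study classification follows the five-category truth table", {
  # expected outcomes written directly from the category definitions
  cases <- list(
    #    oximetry              snore  ep  ar  expected
    list("normal",             FALSE,  0,  0, "normal"),
    list("inconclusive",       FALSE,  0,  0, "normal"),
    list("normal",             TRUE,   0,  0, "primary_snoring"),
    list("inconclusive",       TRUE,   2,  0, "primary_snoring"),
    list("normal",             TRUE,   2,  2, "primary_snoring"),
    list("normal",             TRUE,   3,  3, "uars"),
    list("inconclusive",       TRUE,   5,  4, "uars"),
    list("normal",             FALSE,  3,  3, "uars"),
    list("abnormal_low_risk",  TRUE,   3,  3, "osa"),
    list("abnormal_high_risk", TRUE,   1,  1, "osa"),
    list("abnormal_low_risk",  FALSE,  0,  0, "abnormal_other"),
    list("abnormal_high_risk", TRUE,   2,  0, "abnormal_other"))
  for (cs in cases)
    expect_equal(classify_study(cs[[1]], mk_video(cs[[2]], cs[[3]], cs[[4]])),
                 cs[[5]])

  # total: every combination yields exactly one known category
  for (ox in c("normal", "inconclusive", "abnormal_low_risk",
               "abnormal_high_risk"))
    for (sn in c(TRUE, FALSE))
      for (ep in c(0, 2, 3, 5))
        for (ar in unique(c(0, ep)))
          expect_true(classify_study(ox, mk_video(sn, ep, ar)) %in%
                        c("normal", "primary_snoring", "uars", "osa",
                          "abnormal_other"))
})

test_that("exclusion rules implement the 4 h / 3 h thresholds and abnormal-other", {
  mk_record <- function(ox_hours, ptt_hours, category = "normal") {
    ox <- structure(list(mean_spo2_pct = 97, min_spo2_pct = 95,
                         baseline_spo2_pct = 97, dip_index_per_hour = 0,
                         desat_events = event_list(type = "desaturation"),
                         artifact_spans = event_list(type = "spo2_artifact"),
                         artifact_free_hours = ox_hours,
                         category = category, included_oximetry = NA),
                    class = "oximetry_feature_set")
    ptt <- structure(list(ptt_arousal_count = 0, ptt_arousal_index = 0,
                          respiratory_swing_ms = 5,
                          artifact_free_hours = ptt_hours,
                          arousal_events = event_list(type = "arousal"),
                          artifact_spans = event_list(type = "artifact"),
                          included_ptt = NA),
                     class = "ptt_feature_set")
    study_record("x", ox, mk_video(FALSE, 0, 0), ptt)
  }
  r <- apply_exclusions(mk_record(4.1, 3.0))
  expect_true(r$included_oximetry)
  expect_true(r$included_ptt)
  expect_true(r$in_roc_set)

  r2 <- apply_exclusions(mk_record(3.9, 5))
  expect_false(r2$included_oximetry)
  expect_false(r2$included_ptt)
  expect_true(is.na(r2$study_category))

  r3 <- apply_exclusions(mk_record(8, 2.9))
  expect_true(r3$included_oximetry)
  expect_false(r3$included_ptt)

  # abnormal oximetry without obstruction: included for oximetry, excluded
  # from the PTT threshold analysis
  r4 <- apply_exclusions(mk_record(8, 5, category = "abnormal_low_risk"))
  expect_true(r4$included_oximetry)
  expect_equal(r4$study_category, "abnormal_other")
  expect_false(r4$in_roc_set)
})

test_that("assigned categories recover generator labels on a clean cohort", {
  cfg <- cohort_config(n_children = 60, seed = 31, study_hours = 2)
  coh <- generate_cohort(cfg)
  assigned <- vapply(coh$children, function(ch) {
    ox <- oximetry_summary(ch$spo2, min_hours = 1.5)
    classify_study(ox$category, ch$video)
  }, character(1))
  expect_gte(mean(assigned == coh$truth$category), 0.99)
})
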