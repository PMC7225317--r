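test_that("the train/test split is an exact seeded half split", {
  s <- split_train_test(10, seed = 1)
  expect_length(s$train, 5)
  expect_length(s$test, 5)
  expect_setequal(c(s$train, s$test), 1:10)

  s368 <- split_train_test(368, seed = 2)
  expect_length(s368$train, 184)
  expect_length(s368$test, 184)

  s_odd <- split_train_test(11, seed = 3)
  expect_length(s_odd$train, 6)

  expect_identical(split_train_test(50, seed = 9), split_train_test(50, seed = 9))
  expect_error(split_train_test(3, seed = 1), "at least 4")
})

test_that("ROC counting matches brute force and behaves at the extremes", {
  sep <- labeled_values(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  roc <- roc_curve(sep)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  expect_true(all(diff(order(roc$thresholds)) > 0))
  expect_true(all(diff(roc$sensitivity[order(roc$thresholds)]) <= 0))

  expect_error(roc_curve(labeled_values(1:5, rep(TRUE, 5))), "each class")

  withr::with_seed(21, {
    for (case in 1:100) {
      n <- sample(4:50, 1)
      v <- round(rnorm(n), 2)
      lab <- runif(n) > 0.5
      if (!any(lab)) lab[1] <- TRUE
      if (all(lab)) lab[1] <- FALSE
      roc <- roc_curve(labeled_values(v, lab))
      for (i in seq_along(roc$thresholds)) {
        want <- oracle_sens_spec(v, lab, roc$thresholds[i])
        expect_equal(roc$sensitivity[i], unname(want["sens"]))
        expect_equal(roc$specificity[i], unname(want["spec"]))
      }
    }
    # permuted labels: AUC concentrates at 1/2
    v <- rnorm(2000)
    lab <- sample(rep(c(TRUE, FALSE), 1000))
    expect_lt(abs(roc_curve(labeled_values(v, lab))$auc - 0.5), 0.05)
  })
})

test_that("threshold selection matches exhaustive search and handles targets", {
  sep <- labeled_values(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  sel <- select_thresholds(roc_curve(sep))
  expect_equal(sel$sens90$threshold, sel$spec90$threshold)
  expect_equal(sel$sens90$threshold, sel$max_sum$threshold)

  withr::with_seed(22, {
    for (case in 1:100) {
      n <- sample(6:60, 1)
      v <- rnorm(n, ifelse(runif(n) > 0.5, 1, 0))
      lab <- runif(n) > 0.4
      if (!any(lab)) lab[1] <- TRUE
      if (all(lab)) lab[1] <- FALSE
      roc <- roc_curve(labeled_values(v, lab))
      sel <- select_thresholds(roc)
      ssum <- roc$sensitivity + roc$specificity
      expect_equal(sel$max_sum$sensitivity + sel$max_sum$specificity,
                   max(ssum))
      # ties resolved toward the higher specificity
      best <- which(ssum == max(ssum))
      expect_equal(sel$max_sum$specificity, max(roc$specificity[best]))
    }
  })

  # fully overlapping classes: the targets are only reachable at the
  # degenerate endpoint thresholds (call everything / call nothing)
  one_sided <- labeled_values(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE))
  sel2 <- select_thresholds(roc_curve(one_sided))
  expect_equal(sel2$spec90$threshold, Inf)
  expect_equal(sel2$spec90$sensitivity, 0)
  expect_equal(sel2$sens90$threshold, -Inf)
  expect_equal(sel2$sens90$specificity, 0)
})

test_that("threshold evaluation reproduces counts and rates", {
  lv <- labeled_values(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE))
  ev <- evaluate_threshold(lv, 25)
  expect_equal(unname(ev$table), c(2, 0, 0, 2))
  ev_all <- evaluate_threshold(lv, 5)
  expect_equal(ev_all$sensitivity, 1)
  expect_equal(ev_all$specificity, 0)
})

test_that("bootstrap percentile intervals behave on degenerate and regular data", {
  same <- labeled_values(rep(5, 40), rep(c(TRUE, FALSE), 20))
  ci <- bootstrap_ci(same, 4, n_boot = 200, seed = 1)
  expect_true(all(ci$sensitivity == 1))
  expect_true(all(ci$specificity == 0))

  withr::with_seed(23, {
    v <- c(rnorm(150, 1.5), rnorm(150, 0))
    lab <- rep(c(TRUE, FALSE), each = 150)
    lv <- labeled_values(v, lab)
    ci <- bootstrap_ci(lv, 0.7, n_boot = 2000, seed = 5)
    pt <- evaluate_threshold(lv, 0.7)
    expect_lt(abs(ci$sensitivity[["50%"]] - pt$sensitivity), 0.02)
    expect_lt(abs(ci$specificity[["50%"]] - pt$specificity), 0.02)
  })
  expect_error(bootstrap_ci(same, 4, n_boot = 50, seed = 1), "100")
})

test_that("oximetry-vs-study accuracy matches its definition", {
  ident <- matrix(c(10, 10, 0, 0, 0, 7), 3, 2,
                  dimnames = list(c("normal", "inconclusive", "abnormal"),
                                  c("normal_ps", "uars_osa")))
  acc <- contingency_accuracy(ident)
  expect_equal(acc$sensitivity, 1)
  expect_equal(acc$specificity, 1)

  withr::with_seed(24, {
    for (case in 1:100) {
      m <- matrix(rpois(6, 30) + 1, 3, 2,
                  dimnames = dimnames(ident))
      acc <- contingency_accuracy(m)
      expect_equal(acc$sensitivity, m[3, 2] / sum(m[, 2]))
      expect_equal(acc$specificity, sum(m[1:2, 1]) / sum(m[, 1]))
    }
  })
  bad <- ident; bad[, 2] <- 0
  expect_error(contingency_accuracy(bad), "zero")
})

test_that("the chi-square statistic equals the closed form, without correction", {
  flat <- matrix(c(50, 50, 50, 50), 2, 2)
  expect_equal(chi_square_2x2(flat)$statistic, 0)

  withr::with_seed(25, {
    for (case in 1:100) {
      m <- matrix(rpois(4, 40) + 1, 2, 2)
      got <- chi_square_2x2(m)
      expect_equal(got$statistic, oracle_chisq(m), tolerance = 1e-12)
      expect_equal(got$p_value, pchisq(oracle_chisq(m), 1, lower.tail = FALSE))
    }
  })
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(26, {
    v <- c(rnorm(60, 1), rnorm(60))
    lab <- rep(c(TRUE, FALSE), each = 60)
    ours <- roc_curve(labeled_values(v, lab))$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-9)
  })
})
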