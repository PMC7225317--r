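#' Labelled index values for threshold analysis
#'
#' @param values Numeric vector (PTT respiratory swing in ms, or PTT
#'   arousal index in events/hour).
#' @param labels Logical vector: `TRUE` = condition positive (UARS/OSA),
#'   `FALSE` = condition negative (normal/primary snoring).
#' @return A list of class `labeled_values`.
#' @export
labeled_values <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.logical(labels)
  if (length(values) != length(labels))
    stop("`values` and `labels` must have equal length")
  if (any(!is.finite(values)) || any(is.na(labels)))
    stop("`values` must be finite and `labels` non-missing")
  structure(list(values = values, labels = labels), class = "labeled_values")
}

#' Random half split into training and test sets
#'
#' Uniform, unstratified 50/50 split without replacement; when n is odd the
#' training set receives the extra record. Seeded and reproducible.
#'
#' @param x A `labeled_values`, a data.frame, or an integer count.
#' @param seed Integer seed.
#' @return A list with `train` and `test` index vectors (and, for
#'   `labeled_values`/data.frame input, the corresponding subsets).
#' @export
split_train_test <- function(x, seed) {
  n <- if (inherits(x, "labeled_values")) length(x$values)
       else if (is.data.frame(x)) nrow(x)
       else as.integer(x)
  if (n < 4L) stop("need at least 4 records to split")
  idx <- with_seed(seed, sample.int(n, ceiling(n / 2)))
  train <- sort(idx)
  test <- setdiff(seq_len(n), train)
  out <- list(train = train, test = test)
  if (inherits(x, "labeled_values")) {
    out$train_data <- labeled_values(x$values[train], x$labels[train])
    out$test_data <- labeled_values(x$values[test], x$labels[test])
  } else if (is.data.frame(x)) {
    out$train_data <- x[train, , drop = FALSE]
    out$test_data <- x[test, , drop = FALSE]
  }
  out
}

#' ROC curve over all decision thresholds
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' values, plus -Inf and +Inf; a record is called positive when its value is
#' at or above the threshold. Sensitivity, specificity and the trapezoidal
#' AUC are computed by exhaustive counting.
#'
#' @param data A [labeled_values()] containing both classes.
#' @return A list of class `ptt_roc` with `thresholds`, `sensitivity`,
#'   `specificity` and `auc`.
#' @export
roc_curve <- function(data) {
  stopifnot(inherits(data, "labeled_values"))
  if (!any(data$labels) || all(data$labels))
    stop("ROC analysis needs at least one record of each class")
  u <- sort(unique(data$values))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  npos <- sum(data$labels); nneg <- sum(!data$labels)
  sens <- vapply(thr, function(th) sum(data$values >= th & data$labels) / npos,
                 numeric(1))
  spec <- vapply(thr, function(th) sum(data$values < th & !data$labels) / nneg,
                 numeric(1))
  # trapezoid over the ROC polygon ordered by increasing false-positive rate
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = npos, n_neg = nneg),
            class = "ptt_roc")
}

#' @export
print.ptt_roc <- function(x, ...) {
  cat(sprintf("<ptt_roc> %d thresholds, %d pos / %d neg, AUC %.3f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Plot a ROC curve
#' @param x A `ptt_roc`.
#' @param ... Passed to [plot()].
#' @export
plot.ptt_roc <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  plot(1 - x$specificity[ord], x$sensitivity[ord], type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select screening thresholds from a ROC curve
#'
#' Three cut-offs of clinical interest: the largest threshold retaining at
#' least `target_sens` sensitivity, the smallest threshold attaining at
#' least `target_spec` specificity, and the threshold maximising the
#' arithmetic sum of sensitivity and specificity (ties resolved toward the
#' higher specificity). An unattainable target yields `NA` with a warning.
#'
#' @param roc A `ptt_roc` from [roc_curve()].
#' @param target_sens,target_spec Sensitivity/specificity targets.
#' @return A list with elements `sens90`, `spec90` and `max_sum`, each a
#'   list of `threshold`, `sensitivity`, `specificity`.
#' @export
select_thresholds <- function(roc, target_sens = 0.9, target_spec = 0.9) {
  stopifnot(inherits(roc, "ptt_roc"))
  pick <- function(i) {
    if (length(i) == 0L || is.na(i))
      return(list(threshold = NA_real_, sensitivity = NA_real_,
                  specificity = NA_real_))
    list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
         specificity = roc$specificity[i])
  }
  ok_sens <- which(roc$sensitivity >= target_sens)
  i_sens <- if (length(ok_sens)) ok_sens[which.max(roc$thresholds[ok_sens])] else NA
  ok_spec <- which(roc$specificity >= target_spec)
  i_spec <- if (length(ok_spec)) ok_spec[which.min(roc$thresholds[ok_spec])] else NA
  if (!length(ok_sens) || !length(ok_spec))
    warning("a sensitivity or specificity target is unattainable on this data")
  ssum <- roc$sensitivity + roc$specificity
  best <- which(ssum == max(ssum))
  i_max <- best[which.max(roc$specificity[best])]   # ties -> higher specificity
  list(sens90 = pick(i_sens), spec90 = pick(i_spec), max_sum = pick(i_max))
}

#' Evaluate one threshold on labelled values
#'
#' Positive call = value at or above threshold. Returns the 2x2 contingency
#' table and the sensitivity and specificity.
#'
#' @param data A [labeled_values()].
#' @param threshold Decision threshold.
#' @return A list with `table` (named tp/fn/fp/tn), `sensitivity`,
#'   `specificity`.
#' @export
evaluate_threshold <- function(data, threshold) {
  stopifnot(inherits(data, "labeled_values"))
  pos <- data$values >= threshold
  tp <- sum(pos & data$labels); fn <- sum(!pos & data$labels)
  fp <- sum(pos & !data$labels); tn <- sum(!pos & !data$labels)
  list(table = c(tp = tp, fn = fn, fp = fp, tn = tn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Reconstruct labelled values from above/below-threshold counts
#'
#' Builds a `labeled_values` object consistent with a published 2x2
#' above/below contingency table, placing counted records one unit above or
#' below the stated threshold. Useful for recomputing sensitivity and
#' specificity from printed tables.
#'
#' @param above_pos,below_pos Condition-positive counts above/below the
#'   threshold.
#' @param above_neg,below_neg Condition-negative counts above/below.
#' @param threshold The published threshold.
#' @return A [labeled_values()].
#' @export
labeled_values_from_counts <- function(above_pos, below_pos,
                                       above_neg, below_neg, threshold) {
  labeled_values(
    c(rep(threshold + 1, above_pos), rep(threshold - 1, below_pos),
      rep(threshold + 1, above_neg), rep(threshold - 1, below_neg)),
    c(rep(TRUE, above_pos + below_pos), rep(FALSE, above_neg + below_neg)))
}

#' Bootstrap percentile intervals for sensitivity and specificity
#'
#' Case resampling with replacement over the whole sample; a degenerate
#' resample containing only one class is redrawn. Reports the 2.5th, 50th
#' and 97.5th percentiles of each metric.
#'
#' @param data A [labeled_values()].
#' @param threshold Decision threshold.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param probs Percentiles to report.
#' @return A list with matrices `sensitivity` and `specificity` of the
#'   requested percentiles, plus the point estimates.
#' @export
bootstrap_ci <- function(data, threshold, n_boot = 2000, seed = 1,
                         probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(data, "labeled_values"))
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  n <- length(data$values)
  point <- evaluate_threshold(data, threshold)
  sens <- spec <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        lb <- data$labels[idx]
        if (any(lb) && !all(lb)) break            # redraw one-class resamples
      }
      ev <- evaluate_threshold(
        labeled_values(data$values[idx], lb), threshold)
      sens[b] <- ev$sensitivity; spec[b] <- ev$specificity
    }
  })
  list(sensitivity = stats::quantile(sens, probs, names = TRUE),
       specificity = stats::quantile(spec, probs, names = TRUE),
       point = c(sensitivity = point$sensitivity,
                 specificity = point$specificity),
       n_boot = n_boot)
}

#' Sensitivity and specificity of abnormal oximetry for UARS/OSA
#'
#' From a 3x2 table of oximetry categories (rows: normal, inconclusive,
#' abnormal) against video/multi-channel findings (columns: normal or
#' primary snoring, UARS or OSA): abnormal oximetry is the screening call,
#' UARS/OSA the condition.
#'
#' @param table A 3x2 matrix of counts with rows
#'   `c("normal","inconclusive","abnormal")` and columns
#'   `c("normal_ps","uars_osa")` (order is taken from the row/col names
#'   when present, otherwise positional).
#' @return A list with `sensitivity`, `specificity` and the collapsed 2x2
#'   counts.
#' @export
contingency_accuracy <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(3L, 2L))) stop("expected a 3x2 table of counts")
  if (any(m < 0)) stop("counts must be non-negative")
  if (!is.null(rownames(m))) m <- m[c("normal", "inconclusive", "abnormal"), ]
  if (!is.null(colnames(m))) m <- m[, c("normal_ps", "uars_osa")]
  if (any(colSums(m) == 0)) stop("a condition column has zero total")
  tp <- m["abnormal", "uars_osa"]
  fn <- sum(m[c("normal", "inconclusive"), "uars_osa"])
  tn <- sum(m[c("normal", "inconclusive"), "normal_ps"])
  fp <- m["abnormal", "normal_ps"]
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       table = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (expected counts in this application are
#' large, so the correction is immaterial; omitting it keeps results
#' bit-reproducible against the closed-form statistic).
#'
#' @param table A 2x2 matrix of counts, or a named vector
#'   `c(tp =, fn =, fp =, tn =)`.
#' @return A list with `statistic`, `p_value` and `df = 1`.
#' @export
chi_square_2x2 <- function(table) {
  m <- if (is.matrix(table)) table
       else matrix(table[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive")
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), df = 1)
}
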