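#' Detect artifact spans in an SpO2 trace
#'
#' Flags signal dropout (non-finite samples), physiologically impossible
#' values (below `min_valid_pct`), and movement/low-perfusion artifact seen
#' as steps faster than `max_rate_pct_s` percentage points per second.
#'
#' @param spo2 A [uniform_series()] of SpO2 in percent.
#' @param min_valid_pct Values below this are artifact.
#' @param max_rate_pct_s Maximum plausible rate of change, %/s.
#' @return An [event_list()] of artifact spans.
#' @export
detect_spo2_artifact <- function(spo2, min_valid_pct = 50, max_rate_pct_s = 4) {
  stopifnot(inherits(spo2, "uniform_series"))
  v <- spo2$values
  step <- spo2$step_s
  bad <- !is.finite(v) | v < min_valid_pct
  d <- abs(diff(v)) / step
  jump <- which(is.finite(d) & d > max_rate_pct_s)
  bad[jump] <- TRUE
  bad[jump + 1L] <- TRUE
  if (!any(bad)) return(event_list(type = "spo2_artifact"))
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  tt <- series_times(spo2)
  event_list(tt[starts], tt[ends] + step, type = "spo2_artifact")
}

#' Baseline oxygen saturation
#'
#' Median of the unmasked SpO2 samples over the whole recording — a robust,
#' reproducible baseline (rolling baselines are out of scope).
#'
#' @param spo2 A [uniform_series()] with artifact already masked.
#' @return Baseline SpO2 in percent.
#' @export
oximetry_baseline <- function(spo2) {
  stopifnot(inherits(spo2, "uniform_series"))
  stats::median(spo2$values[!spo2$mask])
}

#' Detect oxygen desaturation (dip) events
#'
#' Maximal spans where the saturation is strictly more than `drop_pct`
#' percentage points below baseline, lasting more than `min_s` and less than
#' `max_s` seconds. Spans touching any artifact sample are discarded, as are
#' spans failing either duration gate.
#'
#' @param spo2 A [uniform_series()] with artifact masked.
#' @param baseline Baseline saturation (percent), computed on artifact-free
#'   data.
#' @param drop_pct Dip threshold below baseline, percentage points.
#' @param min_s,max_s Duration gates in seconds (strict).
#' @return An [event_list()] of desaturations with a `nadir_pct` column.
#' @export
detect_desaturations <- function(spo2, baseline, drop_pct = 4,
                                 min_s = 5, max_s = 180) {
  stopifnot(inherits(spo2, "uniform_series"))
  v <- spo2$values
  below <- is.finite(v) & v < baseline - drop_pct
  if (!any(below)) return(event_list(type = "desaturation", nadir_pct = numeric()))
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  step <- spo2$step_s
  tt <- series_times(spo2)
  keep_s <- keep_e <- nadir <- numeric(0)
  for (i in seq_along(starts)) {
    if (any(spo2$mask[starts[i]:ends[i]])) next       # must be artifact-free
    dur <- (ends[i] - starts[i] + 1L) * step
    if (dur <= min_s || dur >= max_s) next
    keep_s <- c(keep_s, tt[starts[i]])
    keep_e <- c(keep_e, tt[ends[i]] + step)
    nadir <- c(nadir, min(v[starts[i]:ends[i]]))
  }
  event_list(keep_s, keep_e, type = "desaturation", nadir_pct = nadir)
}

#' Oximetry risk category
#'
#' Four-level perioperative risk category from baseline saturation, dip
#' index and minimum saturation. The published criteria are reconstructed as
#' an exhaustive, mutually exclusive rule with explicit precedence:
#' \enumerate{
#'   \item abnormal, high risk: minimum < 80\% and dip index > 4/h and
#'     baseline < 94\%;
#'   \item abnormal, low risk: any remaining study with minimum <= 90\%;
#'   \item inconclusive: minimum > 90\% but baseline <= 94\% or dip index
#'     >= 4/h;
#'   \item normal: baseline > 94\%, dip index < 4/h and minimum > 90\%.
#' }
#' The rule is total and lowering the minimum saturation can never move a
#' study toward normal.
#'
#' @param baseline Baseline SpO2, percent.
#' @param dip_index Desaturations per artifact-free hour.
#' @param min_spo2 Minimum SpO2, percent.
#' @return One of `"normal"`, `"inconclusive"`, `"abnormal_low_risk"`,
#'   `"abnormal_high_risk"`.
#' @export
categorize_oximetry <- function(baseline, dip_index, min_spo2) {
  if (!all(is.finite(c(baseline, dip_index, min_spo2))))
    stop("oximetry category inputs must be finite")
  if (min_spo2 < 80 && dip_index > 4 && baseline < 94) return("abnormal_high_risk")
  if (min_spo2 <= 90) return("abnormal_low_risk")
  if (baseline <= 94 || dip_index >= 4) return("inconclusive")
  "normal"
}

#' Oximetry feature set for one record
#'
#' Masks artifact, computes baseline (whole-night median), detects dips,
#' and summarises mean/minimum saturation, the dip index per artifact-free
#' hour and the risk category. Records with fewer than `min_hours`
#' artifact-free hours are flagged excluded (`included_oximetry = FALSE`)
#' rather than silently reported.
#'
#' @param spo2 A [uniform_series()] of SpO2 in percent.
#' @param min_hours Inclusion threshold on artifact-free oximetry hours.
#' @param drop_pct,min_s,max_s Dip rule constants.
#' @return A list of class `oximetry_feature_set`.
#' @export
oximetry_summary <- function(spo2, min_hours = 4, drop_pct = 4,
                             min_s = 5, max_s = 180) {
  stopifnot(inherits(spo2, "uniform_series"))
  spans <- detect_spo2_artifact(spo2)
  spo2 <- mask_events(spo2, spans)
  hours <- artifact_free_hours(spo2)
  base <- oximetry_baseline(spo2)
  ev <- detect_desaturations(spo2, baseline = base, drop_pct = drop_pct,
                             min_s = min_s, max_s = max_s)
  ok <- !spo2$mask
  mean_spo2 <- mean(spo2$values[ok])
  min_spo2 <- min(spo2$values[ok])
  di <- if (hours > 0) nrow(ev) / hours else NA_real_
  structure(
    list(mean_spo2_pct = mean_spo2,
         min_spo2_pct = min_spo2,
         baseline_spo2_pct = base,
         dip_index_per_hour = di,
         desat_events = ev,
         artifact_spans = spans,
         artifact_free_hours = hours,
         category = categorize_oximetry(base, di, min_spo2),
         included_oximetry = hours >= min_hours),
    class = "oximetry_feature_set"
  )
}

#' @export
print.oximetry_feature_set <- function(x, ...) {
  cat(sprintf(
    "<oximetry_feature_set> baseline %.1f%%, mean %.1f%%, min %.1f%%, DI %.2f/h -> %s%s\n",
    x$baseline_spo2_pct, x$mean_spo2_pct, x$min_spo2_pct,
    x$dip_index_per_hour, x$category,
    if (x$included_oximetry) "" else " [excluded: <4 h]"))
  invisible(x)
}
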