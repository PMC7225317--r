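#' Reference cohort contingency counts
#'
#' Printed contingency counts from the reference paediatric sleep-study
#' cohort on which the screening thresholds were developed (521 children
#' with oximetry and video; 368 with analysable PTT), shipped as plain-text
#' fixtures so that the published accuracy statistics can be recomputed
#' from the package's own functions.
#'
#' @name reference_tables
NULL

ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "pttsdb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn reference_tables 3x2 table of oximetry categories (normal,
#'   inconclusive, abnormal) against multi-channel video findings
#'   (normal/primary snoring vs UARS/OSA), as a matrix of counts.
#' @export
reference_oximetry_table <- function() {
  d <- ref_csv("reference_oximetry_video_counts.csv")
  m <- as.matrix(d[, c("normal_ps", "uars_osa")])
  rownames(m) <- d$oximetry_category
  m
}

#' @describeIn reference_tables 2x2 above/below-threshold counts of the
#'   PTT respiratory swing for a given dataset (`"training"` or `"test"`),
#'   rows UARS/OSA then normal/snoring.
#' @param dataset `"training"` or `"test"`.
#' @export
reference_swing_table <- function(dataset = c("training", "test")) {
  dataset <- match.arg(dataset)
  d <- ref_csv("reference_swing_threshold_counts.csv")
  d <- d[d$dataset == dataset, ]
  m <- as.matrix(d[, c("above_threshold", "below_threshold")])
  rownames(m) <- d$group
  m[c("uars_osa", "normal_snoring"), ]
}

#' @describeIn reference_tables 2x2 above/below-threshold counts in the
#'   normal/inconclusive-oximetry subgroup (UARS vs normal/snoring).
#' @export
reference_uars_subgroup_table <- function() {
  d <- ref_csv("reference_uars_subgroup_counts.csv")
  m <- as.matrix(d[, c("above_threshold", "below_threshold")])
  rownames(m) <- d$group
  m[c("uars", "normal_snoring"), ]
}
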