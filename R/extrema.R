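#' Alternating turning points of a masked uniform series
#'
#' Finds the zigzag sequence of local maxima and minima of a signal,
#' ignoring reversals smaller than `prominence`. Masked samples split the
#' series into independent segments; no extremum crosses a mask. A maximum
#' is timed at the last sample of its plateau (the departure into the fall)
#' and a minimum at the first sample of its plateau (the arrival at the
#' bottom), so `t_min - t_max` measures the full duration of a drop.
#'
#' @param x A [uniform_series()].
#' @param prominence_ms Minimum reversal, in the units of the series,
#'   for a turning point to be kept.
#' @return A data.frame with columns `idx` (sample index), `time_s`,
#'   `value`, `type` (`"max"`/`"min"`) and `segment`.
#' @export
turning_points <- function(x, prominence_ms = 1) {
  stopifnot(inherits(x, "uniform_series"))
  ok <- !x$mask
  tt <- series_times(x)
  segs <- split(seq_along(ok)[ok], cumsum(!ok)[ok])
  out <- list()
  for (k in seq_along(segs)) {
    ii <- segs[[k]]
    if (length(ii) < 2L) next
    tp <- .turning_points_cpp(x$values[ii], prominence_ms)
    if (length(tp$idx) == 0L) next
    gi <- ii[tp$idx]
    out[[length(out) + 1L]] <- data.frame(
      idx = gi, time_s = tt[gi], value = x$values[gi],
      type = ifelse(tp$type > 0, "max", "min"), segment = k
    )
  }
  if (length(out) == 0L)
    return(data.frame(idx = integer(), time_s = numeric(), value = numeric(),
                      type = character(), segment = integer()))
  do.call(rbind, out)
}
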