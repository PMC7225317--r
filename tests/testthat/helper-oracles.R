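# Independent brute-force reference implementations used to cross-check the
# package's vectorised/compiled routines. These deliberately share no code
# with the implementations they verify.

# O(n*w) centred moving mean with mask handling
oracle_moving_mean <- function(values, mask, window) {
  n <- length(values)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  out_mask <- rep(TRUE, n)
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half
    if (lo < 1 || hi > n) next                       # truncated window: masked
    idx <- lo:hi
    ok <- !mask[idx]
    if (sum(!ok) >= window / 2) next                 # >50% masked
    out[i] <- mean(values[idx][ok])
    out_mask[i] <- FALSE
  }
  list(values = out, mask = out_mask)
}

# pointwise piecewise-linear evaluator (independent of stats::approx)
oracle_interp <- function(x, y, xout) {
  vapply(xout, function(t) {
    if (t <= x[1]) return(y[1])
    if (t >= x[length(x)]) return(y[length(y)])
    j <- max(which(x <= t))
    if (x[j] == t) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (t - x[j]) / (x[j + 1] - x[j])
  }, numeric(1))
}

# all-pairs beat matcher: first pulse after each R and before the next R
oracle_beat_match <- function(r, p) {
  n <- length(r)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    upper <- if (i < n) r[i + 1] else Inf
    cand <- p[p > r[i] & p < upper]
    if (length(cand)) out[i] <- (min(cand) - r[i]) * 1000
  }
  out
}

# exhaustive scan for maximal below-threshold spans with duration gates
oracle_dips <- function(values, mask, step, baseline, drop, min_s, max_s) {
  below <- is.finite(values) & values < baseline - drop
  n <- length(values)
  spans <- list()
  i <- 1
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      dur <- (j - i + 1) * step
      if (dur > min_s && dur < max_s && !any(mask[i:j]))
        spans[[length(spans) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  spans
}

# sensitivity/specificity at a threshold by direct counting
oracle_sens_spec <- function(values, labels, thr) {
  call_pos <- values >= thr
  c(sens = sum(call_pos & labels) / sum(labels),
    spec = sum(!call_pos & !labels) / sum(!labels))
}

# Pearson chi-square statistic from the definition
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# plain-R reference for the compiled turning-point finder: explicit
# state-machine over samples (max timed at last attainment, min at first)
oracle_turning_points <- function(x, prom) {
  n <- length(x)
  idx <- integer(); typ <- integer()
  if (n >= 2) {
    dir <- 0L
    maxv <- minv <- x[1]; maxi <- mini <- 1L
    for (i in 2:n) {
      v <- x[i]
      if (dir == 0L) {
        if (v >= maxv) { maxv <- v; maxi <- i }
        if (v < minv) { minv <- v; mini <- i }
        if (maxv - minv >= prom) {
          if (mini > maxi) { idx <- c(idx, maxi); typ <- c(typ, 1L); dir <- -1L }
          else { idx <- c(idx, mini); typ <- c(typ, -1L); dir <- 1L }
        }
      } else if (dir == 1L) {
        if (v >= maxv) { maxv <- v; maxi <- i }
        else if (maxv - v >= prom) {
          idx <- c(idx, maxi); typ <- c(typ, 1L)
          dir <- -1L; minv <- v; mini <- i
        }
      } else {
        if (v < minv) { minv <- v; mini <- i }
        else if (v - minv >= prom) {
          idx <- c(idx, mini); typ <- c(typ, -1L)
          dir <- 1L; maxv <- v; maxi <- i
        }
      }
    }
    if (dir == 1L) { idx <- c(idx, maxi); typ <- c(typ, 1L) }
    if (dir == -1L) { idx <- c(idx, mini); typ <- c(typ, -1L) }
  }
  list(idx = idx, type = typ)
}

# quick constructor for a uniform series
us <- function(values, step = 0.2, start = 0, mask = NULL)
  uniform_series(values, step_s = step, start_s = start, mask = mask)

# constant-baseline beat series covering `dur` seconds
const_beats <- function(dur = 1200, rr = 0.7, ptt = 300)
  beat_ptt_series(seq(0, dur, by = rr), rep(ptt, length(seq(0, dur, by = rr))))
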