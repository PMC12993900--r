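# Turning points of a series: indices of alternating local extrema,
# endpoints included. Plateaus are compressed to their first index, so the
# result is strictly alternating in direction.
turning_points <- function(g) {
  n <- length(g)
  if (n < 2) return(seq_len(n))
  keep <- c(TRUE, diff(g) != 0)      # first index of each plateau
  idx <- which(keep)
  v <- g[idx]
  m <- length(v)
  if (m < 3) return(idx[c(1L, m)][!duplicated(idx[c(1L, m)])])
  s <- sign(diff(v))
  interior <- which(s[-1] != s[-(m - 1)]) + 1L
  idx[c(1L, interior, m)]
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Scans the trace for alternating local extrema (turning points,
#' endpoints included, plateaus taken at their first sample) and keeps the
#' swings between consecutive extrema whose absolute amplitude exceeds one
#' sample standard deviation of the whole window. `mage` is the mean of
#' all qualifying absolute amplitudes; `mage_up` and `mage_down` split
#' them by direction. Computed on the unsmoothed repaired trace by
#' default semantics; compose with [smooth_savgol()] first if desired.
#'
#' @param trace a repaired [glucose_trace()] covering at least 2 h.
#' @return list with `mage`, `mage_up`, `mage_down` (mg/dL; `NA` when no
#'   swing qualifies — deliberately not 0), `sd` (the qualifying
#'   threshold) and `n_qualifying`.
#' @export
compute_mage <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  assert_repaired(trace, "compute_mage")
  tmin <- trace_minutes(trace)
  if (tmin[length(tmin)] - tmin[1] < 120) {
    stop("MAGE needs a window of at least 2 h", call. = FALSE)
  }
  g <- trace$glucose
  s <- stats::sd(g)
  tp <- turning_points(g)
  amps <- diff(g[tp])
  qual <- amps[abs(amps) > s]
  up <- qual[qual > 0]
  down <- -qual[qual < 0]
  list(
    mage = if (length(qual)) mean(abs(qual)) else NA_real_,
    mage_up = if (length(up)) mean(up) else NA_real_,
    mage_down = if (length(down)) mean(down) else NA_real_,
    sd = s,
    n_qualifying = length(qual)
  )
}

#' Continuous overall net glycemic action, CONGA(n)
#'
#' Sample standard deviation of the differences `g(t) - g(t - n hours)`
#' over every sample `t` for which the lagged sample exists on the
#' uniform grid.
#'
#' @param trace a repaired [glucose_trace()] on a uniform grid.
#' @param n_hours lag in hours (classically 1, 2 or 6).
#' @return mg/dL (single number).
#' @export
compute_conga <- function(trace, n_hours) {
  stopifnot(inherits(trace, "glucose_trace"))
  assert_repaired(trace, "compute_conga")
  dt <- trace_interval(trace)
  tmin <- trace_minutes(trace)
  if (max(abs(diff(tmin) - dt)) > 1e-6) {
    stop("CONGA requires a uniform sampling grid", call. = FALSE)
  }
  k <- n_hours * 60 / dt
  if (abs(k - round(k)) > 1e-8) {
    stop("n_hours must be a whole number of sampling intervals", call. = FALSE)
  }
  k <- as.integer(round(k))
  n <- length(trace)
  if (k >= n) stop("trace shorter than the CONGA lag", call. = FALSE)
  d <- trace$glucose[(k + 1):n] - trace$glucose[1:(n - k)]
  stats::sd(d)
}

#' Time in / below / above the euglycemic range
#'
#' Per-sample classification: below when `g < lo`, above when `g >= hi`
#' (the asymmetric hypo/hyper convention: < 70 mg/dL hypoglycemia,
#' >= 180 mg/dL hyperglycemia), within otherwise. Fractions of the sample
#' count; they always sum to 1.
#'
#' @param trace a repaired [glucose_trace()].
#' @param lo,hi range bounds in mg/dL (default 70 and 180).
#' @return named numeric vector `c(below, within, above)`.
#' @export
compute_time_in_range <- function(trace, lo = 70, hi = 180) {
  stopifnot(inherits(trace, "glucose_trace"))
  assert_repaired(trace, "compute_time_in_range")
  if (lo >= hi) stop("`lo` must be < `hi`", call. = FALSE)
  g <- trace$glucose
  n <- length(g)
  below <- sum(g < lo) / n
  above <- sum(g >= hi) / n
  c(below = below, within = 1 - below - above, above = above)
}

#' All variability metrics for one trace or window
#'
#' Convenience wrapper bundling [compute_mage()], [compute_conga()] at the
#' requested lags (lags longer than the trace are reported `NA`) and
#' [compute_time_in_range()].
#'
#' @param trace a repaired [glucose_trace()].
#' @param conga_hours CONGA lags in hours.
#' @param range euglycemic range `c(lo, hi)`.
#' @return one-row data.frame of metrics.
#' @export
variability_metrics <- function(trace, conga_hours = c(1, 2, 6),
                                range = c(70, 180)) {
  m <- compute_mage(trace)
  span_h <- diff(range(trace_minutes(trace))) / 60
  congas <- vapply(conga_hours, function(h) {
    if (h >= span_h) NA_real_ else compute_conga(trace, h)
  }, numeric(1))
  tir <- compute_time_in_range(trace, range[1], range[2])
  out <- data.frame(mage = m$mage, mage_up = m$mage_up,
                    mage_down = m$mage_down)
  for (i in seq_along(conga_hours)) {
    out[[sprintf("conga_%gh", conga_hours[i])]] <- congas[i]
  }
  out$tir_below <- tir[["below"]]
  out$tir_within <- tir[["within"]]
  out$tir_above <- tir[["above"]]
  out
}
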