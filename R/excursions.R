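#' Per-animal baseline band (mean +/- 1 SD) from a reference window
#'
#' Each animal's reference for excursion detection is the mean plus or
#' minus one sample standard deviation of its observed glucose over a
#' stated window — by convention the night preceding the analysed day, so
#' that postprandial peaks are judged against the fasted nocturnal state.
#'
#' @param trace a [glucose_trace()] (missing points are ignored).
#' @param start,end `POSIXct` bounds of the reference window (inclusive).
#' @return an object of class `baseline_band`: list with `mean`, `sd`,
#'   `lower`, `upper`, `reference_window`, `animal_id`.
#' @export
compute_baseline <- function(trace, start, end) {
  stopifnot(inherits(trace, "glucose_trace"))
  w <- trace_window(trace, start, end)
  g <- w$glucose[!w$missing]
  if (length(g) == 0) stop("baseline window contains no observed samples",
                           call. = FALSE)
  if (length(g) < 10) {
    stop(sprintf("baseline window has only %d observed samples (need >= 10)",
                 length(g)), call. = FALSE)
  }
  m <- mean(g)
  s <- stats::sd(g)
  structure(
    list(mean = m, sd = s, lower = m - s, upper = m + s,
         reference_window = c(start, end), animal_id = trace$animal_id),
    class = "baseline_band"
  )
}

#' @export
print.baseline_band <- function(x, ...) {
  cat(sprintf("<baseline_band> %s | mean %.1f +/- %.1f mg/dL -> [%.1f, %.1f]\n",
              x$animal_id, x$mean, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Detect peak and nadir excursions against a baseline band
#'
#' A peak is a maximal run of consecutive samples strictly above the
#' band's upper edge; a nadir a maximal run strictly below the lower
#' edge. Each excursion carries its extremum value and time, its duration
#' (minutes between the first and the last sample of the run — a
#' single-sample excursion has duration 0) and its area under the curve:
#' the trapezoidal integral of the excess beyond the crossed band edge
#' over the run samples only (mg/dL x min), with no extrapolation to the
#' band-crossing instants.
#'
#' @param trace a repaired [glucose_trace()].
#' @param band a [compute_baseline()] band.
#' @param start,end optional `POSIXct` window (default: whole trace).
#' @return data.frame with one row per excursion, ordered by start time:
#'   columns `kind` ("peak"/"nadir"), `start`, `end`, `duration_min`,
#'   `extremum_value`, `extremum_time`, `auc`, `n_samples`.
#' @export
detect_excursions <- function(trace, band, start = NULL, end = NULL) {
  stopifnot(inherits(trace, "glucose_trace"), inherits(band, "baseline_band"))
  assert_repaired(trace, "detect_excursions")
  if (!is.null(start) || !is.null(end)) {
    if (is.null(start)) start <- trace$times[1]
    if (is.null(end)) end <- trace$times[length(trace)]
    trace <- trace_window(trace, start, end)
  }
  if (band$sd == 0) {
    warning("degenerate baseline band (sd = 0): every off-mean sample opens an excursion")
  }
  g <- trace$glucose
  tmin <- trace_minutes(trace)
  state <- ifelse(g > band$upper, 1L, ifelse(g < band$lower, -1L, 0L))
  out <- empty_excursions()
  if (!length(state)) return(out)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    i <- starts[k]:ends[k]
    peak <- r$values[k] == 1L
    edge <- if (peak) band$upper else band$lower
    dev <- abs(g[i] - edge)
    auc <- if (length(i) > 1) {
      sum(diff(tmin[i]) * (dev[-length(dev)] + dev[-1]) / 2)
    } else 0
    ext <- if (peak) which.max(g[i]) else which.min(g[i])
    rows[[length(rows) + 1L]] <- data.frame(
      kind = if (peak) "peak" else "nadir",
      start = trace$times[i[1]],
      end = trace$times[i[length(i)]],
      duration_min = tmin[i[length(i)]] - tmin[i[1]],
      extremum_value = g[i][ext],
      extremum_time = trace$times[i[ext]],
      auc = auc,
      n_samples = length(i)
    )
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

empty_excursions <- function() {
  data.frame(kind = character(), start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             duration_min = numeric(), extremum_value = numeric(),
             extremum_time = as.POSIXct(character(), tz = "UTC"),
             auc = numeric(), n_samples = integer())
}

#' Summarize excursions over one analysis period
#'
#' Produces the per-window summary used throughout the analysis: counts of
#' peaks and nadirs, their total durations and total AUCs, the window-wide
#' maximal and minimal glucose, the sharpest peak (highest extremum;
#' earliest wins ties) and sharpest nadir (lowest extremum) with their
#' duration and AUC, the fractions of window samples above / below /
#' within the band, and the relative range
#' `100 * (max - min) / max` (percent of the window maximum).
#'
#' @param excursions data.frame from [detect_excursions()], restricted to
#'   the period.
#' @param trace a repaired [glucose_trace()] (will be cut to the period).
#' @param band the [compute_baseline()] band the excursions were detected
#'   against.
#' @param start,end `POSIXct` period bounds (inclusive).
#' @param period label, e.g. `"night"`, `"day"`, `"postprandial"`.
#' @return one-row data.frame of period metrics; sharpest-excursion
#'   columns are `NA` when the window has no excursion of that kind.
#' @export
summarize_period <- function(excursions, trace, band, start, end,
                             period = "window") {
  stopifnot(inherits(trace, "glucose_trace"), inherits(band, "baseline_band"))
  w <- trace_window(trace, start, end)
  assert_repaired(w, "summarize_period")
  g <- w$glucose
  if (!length(g)) stop("period contains no samples", call. = FALSE)
  pk <- excursions[excursions$kind == "peak", , drop = FALSE]
  nd <- excursions[excursions$kind == "nadir", , drop = FALSE]
  sharp <- function(e, decreasing) {
    if (!nrow(e)) return(e[NA_integer_, , drop = FALSE])
    o <- order(e$extremum_value, e$start,
               decreasing = c(decreasing, FALSE), method = "radix")
    e[o[1], , drop = FALSE]
  }
  sp <- sharp(pk, TRUE)
  sn <- sharp(nd, FALSE)
  frac_above <- mean(g > band$upper)
  frac_below <- mean(g < band$lower)
  mx <- max(g); mn <- min(g)
  data.frame(
    period = period,
    n_peaks = nrow(pk), n_nadirs = nrow(nd),
    total_peak_duration = sum(pk$duration_min),
    total_nadir_duration = sum(nd$duration_min),
    total_peak_auc = sum(pk$auc),
    total_nadir_auc = sum(nd$auc),
    max_glucose = mx, min_glucose = mn,
    sharpest_peak_value = sp$extremum_value,
    sharpest_peak_duration = sp$duration_min,
    sharpest_peak_auc = sp$auc,
    sharpest_nadir_value = sn$extremum_value,
    sharpest_nadir_duration = sn$duration_min,
    sharpest_nadir_auc = sn$auc,
    frac_above = frac_above,
    frac_below = frac_below,
    frac_within_band = 1 - frac_above - frac_below,
    relative_range_pct = 100 * (mx - mn) / mx
  )
}

#' Resolve night/day/postprandial windows to concrete timestamps
#'
#' Expands the clock-time windows of a [study_design()] into absolute
#' `POSIXct` intervals for each calendar day covered by a trace span.
#' The night window wraps midnight (e.g. 21:00 on day d to 06:55 on day
#' d+1) and is labelled with the day it starts on; windows are
#' endpoint-inclusive on the 5-min grid, so a sample at exactly 06:55
#' belongs to the night. Only windows fully inside the span are returned.
#'
#' @param design a [study_design()].
#' @param span_start,span_end `POSIXct` trace span.
#' @return data.frame with columns `period`, `day`, `start`, `end`.
#' @export
resolve_windows <- function(design, span_start, span_end) {
  stopifnot(inherits(design, "study_design"))
  tz <- attr(span_start, "tzone")
  if (is.null(tz) || !nzchar(tz)) tz <- "UTC"
  day0 <- as.POSIXct(format(span_start, "%Y-%m-%d"), tz = tz)
  ndays <- as.integer(ceiling(as.numeric(span_end - day0, units = "days"))) + 1L
  rows <- list()
  add <- function(period, day, s, e) {
    if (s >= span_start && e <= span_end) {
      rows[[length(rows) + 1L]] <<- data.frame(
        period = period, day = day, start = s, end = e)
    }
  }
  for (d in seq_len(ndays)) {
    base <- day0 + (d - 1L) * 86400
    cm <- clock_minutes
    dw <- cm(design$day_window)
    add("day", d, base + 60 * dw[1], base + 60 * dw[2])
    pw <- cm(design$postprandial_window)
    add("postprandial", d, base + 60 * pw[1], base + 60 * pw[2])
    nw <- cm(design$night_window)
    nend <- if (nw[2] <= nw[1]) base + 86400 + 60 * nw[2] else base + 60 * nw[2]
    add("night", d, base + 60 * nw[1], nend)
  }
  if (!length(rows)) {
    stop("trace span too short: no complete analysis window fits", call. = FALSE)
  }
  do.call(rbind, rows)
}
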