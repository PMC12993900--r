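#' Construct a glucose trace
#'
#' The central container of the package: a uniformly sampled (nominally
#' 5-minute) interstitial or blood glucose series for one animal, with a
#' per-sample missingness flag. Off-scale sensor readings arrive as `NA`
#' glucose with `missing = TRUE`; every downstream computation requires the
#' trace to be repaired first (see [repair_missing()]).
#'
#' @param times `POSIXct` vector, strictly increasing.
#' @param glucose numeric vector, mg/dL; must be finite wherever
#'   `missing` is `FALSE`.
#' @param animal_id single string identifying the animal.
#' @param missing logical vector flagging off-scale/absent readings;
#'   defaults to `is.na(glucose)`.
#' @param source provenance tag, one of `"raw"`, `"repaired"`,
#'   `"smoothed"`, `"shifted"`, `"simulated"`.
#' @return An object of class `glucose_trace`: a list with elements
#'   `animal_id`, `times`, `glucose`, `missing`, `source`.
#' @examples
#' tr <- glucose_trace(
#'   times = as.POSIXct("2024-01-01", tz = "UTC") + 300 * (0:3),
#'   glucose = c(100, NA, 110, 115), animal_id = "pig1"
#' )
#' tr
#' @export
glucose_trace <- function(times, glucose, animal_id = "animal",
                          missing = is.na(glucose), source = "raw") {
  if (!inherits(times, "POSIXct")) {
    stop("`times` must be POSIXct", call. = FALSE)
  }
  n <- length(times)
  if (length(glucose) != n || length(missing) != n) {
    stop("`times`, `glucose` and `missing` must have equal length",
         call. = FALSE)
  }
  if (n > 1 && any(diff(as.numeric(times)) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  source <- match.arg(source,
                      c("raw", "repaired", "smoothed", "shifted", "simulated"))
  missing <- as.logical(missing)
  bad <- !missing & (!is.finite(glucose))
  if (any(bad)) {
    stop(sprintf("non-finite glucose at %d position(s) not flagged missing",
                 sum(bad)), call. = FALSE)
  }
  structure(
    list(animal_id = as.character(animal_id)[1],
         times = times,
         glucose = as.numeric(glucose),
         missing = missing,
         source = source),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<glucose_trace> %s | %d samples | source: %s\n",
              x$animal_id, n, x$source))
  if (n) {
    cat(sprintf("  span: %s .. %s\n",
                format(x$times[1], usetz = TRUE),
                format(x$times[n], usetz = TRUE)))
    obs <- x$glucose[!x$missing]
    cat(sprintf("  missing: %d (%.1f%%)  glucose: %.0f..%.0f mg/dL\n",
                sum(x$missing), 100 * mean(x$missing),
                if (length(obs)) min(obs) else NA,
                if (length(obs)) max(obs) else NA))
  }
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$times)

#' @export
as.data.frame.glucose_trace <- function(x, ...) {
  data.frame(timestamp = x$times, glucose_mg_dl = x$glucose,
             missing = x$missing)
}

#' Minutes since the first sample
#' @param trace a [glucose_trace()].
#' @return numeric vector, minutes, starting at 0.
#' @export
trace_minutes <- function(trace) {
  as.numeric(trace$times - trace$times[1], units = "mins")
}

#' Nominal sampling interval of a trace, in minutes
#' @param trace a [glucose_trace()].
#' @return median spacing in minutes.
#' @export
trace_interval <- function(trace) {
  if (length(trace) < 2) return(NA_real_)
  stats::median(diff(as.numeric(trace$times))) / 60
}

#' Subset a trace to a closed time window
#'
#' Endpoint-inclusive: a sample landing exactly on either boundary belongs
#' to the window.
#'
#' @param trace a [glucose_trace()].
#' @param start,end `POSIXct` window boundaries.
#' @return a `glucose_trace` restricted to `[start, end]`.
#' @export
trace_window <- function(trace, start, end) {
  keep <- trace$times >= start & trace$times <= end
  glucose_trace(trace$times[keep], trace$glucose[keep],
                animal_id = trace$animal_id,
                missing = trace$missing[keep], source = trace$source)
}

# internal: require a fully observed (repaired) trace
assert_repaired <- function(trace, what = "this operation") {
  if (any(trace$missing)) {
    stop(sprintf("%s requires a repaired trace (no missing points); run repair_missing() first",
                 what), call. = FALSE)
  }
  invisible(trace)
}

#' Construct a sparse blood-sample series
#'
#' Catheter-drawn plasma glucose values at scheduled times around a test
#' meal, plus the animal's hematocrit measured at sensor placement. The
#' hematocrit drives the plasma-to-blood conversion (porcine erythrocytes
#' are impermeable to glucose, so whole-blood glucose is confined to the
#' plasma fraction).
#'
#' @param times `POSIXct`, strictly increasing.
#' @param plasma_glucose numeric, mg/dL, strictly positive.
#' @param hematocrit single fraction in (0.15, 0.60).
#' @param animal_id single string.
#' @param medium `"plasma"` or `"blood_equivalent"`.
#' @return An object of class `blood_samples`.
#' @export
blood_samples <- function(times, plasma_glucose, hematocrit,
                          animal_id = "animal", medium = "plasma") {
  if (!inherits(times, "POSIXct")) stop("`times` must be POSIXct", call. = FALSE)
  if (length(times) != length(plasma_glucose)) {
    stop("`times` and `plasma_glucose` lengths differ", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(as.numeric(times)) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(plasma_glucose)) || any(plasma_glucose <= 0)) {
    stop("`plasma_glucose` must be finite and > 0", call. = FALSE)
  }
  hematocrit <- as.numeric(hematocrit)[1]
  if (!is.finite(hematocrit) || hematocrit <= 0.15 || hematocrit >= 0.60) {
    stop("`hematocrit` must lie in (0.15, 0.60)", call. = FALSE)
  }
  medium <- match.arg(medium, c("plasma", "blood_equivalent"))
  structure(
    list(animal_id = as.character(animal_id)[1],
         times = times,
         plasma_glucose = as.numeric(plasma_glucose),
         hematocrit = hematocrit,
         medium = medium),
    class = "blood_samples"
  )
}

#' @export
print.blood_samples <- function(x, ...) {
  cat(sprintf("<blood_samples> %s | %d samples | medium: %s | Hct %.2f\n",
              x$animal_id, length(x$times), x$medium, x$hematocrit))
  invisible(x)
}

#' @export
length.blood_samples <- function(x) length(x$times)
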