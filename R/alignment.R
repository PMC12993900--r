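#' Estimate the CGM-vs-blood time shift by cross-correlation
#'
#' Both series are mean-centered and their cross-correlation is computed
#' by frequency-domain convolution (FFT); the lag maximising the
#' normalized correlation over `[-max_lag, +max_lag]` whole minutes is
#' reported. Sign convention: a positive lag means the CGM trace trails
#' blood glucose, i.e. `cgm(t) ~ blood(t - lag)` — the physiological
#' interstitial delay. Per-lag normalization uses the overlapping
#' segments only, so the peak correlation of two identical series is
#' exactly 1 at lag 0.
#'
#' @param cgm_1min,blood_1min [glucose_trace()]s on a common 1-minute grid
#'   (see [resample_minutely()]); overlapping span must be at least
#'   `4 * max_lag`.
#' @param max_lag search bound in minutes (default 60).
#' @return an `alignment_result`: list with `lag` (min), `peak_correlation`,
#'   `shifted_trace` (the CGM trace advanced by the estimated lag so that
#'   it aligns with blood), and `correlations` (data.frame lag/r).
#' @export
estimate_lag <- function(cgm_1min, blood_1min, max_lag = 60) {
  stopifnot(inherits(cgm_1min, "glucose_trace"),
            inherits(blood_1min, "glucose_trace"))
  assert_repaired(cgm_1min, "estimate_lag")
  assert_repaired(blood_1min, "estimate_lag")
  if (abs(trace_interval(cgm_1min) - 1) > 1e-9 ||
      abs(trace_interval(blood_1min) - 1) > 1e-9) {
    stop("both series must be on a 1-min grid (use resample_minutely)",
         call. = FALSE)
  }
  # restrict to the common time span
  s <- max(cgm_1min$times[1], blood_1min$times[1])
  e <- min(cgm_1min$times[length(cgm_1min)], blood_1min$times[length(blood_1min)])
  x <- trace_window(cgm_1min, s, e)$glucose
  y <- trace_window(blood_1min, s, e)$glucose
  n <- length(x)
  if (n < 4 * max_lag) {
    stop(sprintf("insufficient overlap: %d min < 4 * max_lag = %d min",
                 n, 4 * as.integer(max_lag)), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series: correlation undefined", call. = FALSE)
  }
  x <- x - mean(x); y <- y - mean(y)
  max_lag <- as.integer(max_lag)
  # raw cross-covariance via FFT: num[k] = sum_t x[t] * y[t - k]
  m <- stats::nextn(n + max_lag, 2)
  fx <- stats::fft(c(x, numeric(m - n)))
  fy <- stats::fft(c(y, numeric(m - n)))
  cc <- Re(stats::fft(fx * Conj(fy), inverse = TRUE)) / m
  lags <- -max_lag:max_lag
  num <- cc[ifelse(lags >= 0, lags + 1L, m + lags + 1L)]
  # exact per-lag normalization over the overlapping segments
  cx <- cumsum(x^2); cy <- cumsum(y^2)
  segsum <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  denom <- vapply(lags, function(k) {
    if (k >= 0) {
      sqrt(segsum(cx, k + 1, n) * segsum(cy, 1, n - k))
    } else {
      sqrt(segsum(cx, 1, n + k) * segsum(cy, 1 - k, n))
    }
  }, numeric(1))
  r <- num / denom
  best <- which.max(r)
  lag <- lags[best]
  structure(
    list(lag = lag,
         peak_correlation = r[best],
         shifted_trace = shift_trace(cgm_1min, -lag),
         correlations = data.frame(lag = lags, r = r)),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> lag %+d min (CGM trails blood), peak r = %.3f\n",
              x$lag, x$peak_correlation))
  invisible(x)
}

#' Shift a trace in time, padding with edge values
#'
#' Translates the value sequence by `lag` samples on its own grid while
#' keeping timestamps fixed: for `lag > 0` every value moves to a later
#' position and the vacated leading positions are padded with the first
#' original value; for `lag < 0` values move earlier and the tail is
#' padded with the last original value. To align a CGM trace that trails
#' blood by `L` minutes, apply `shift_trace(cgm, -L)` (this is what
#' [estimate_lag()] returns as `shifted_trace`).
#'
#' @param trace a repaired 1-min-grid [glucose_trace()].
#' @param lag whole minutes.
#' @return the shifted trace, `source = "shifted"`.
#' @export
shift_trace <- function(trace, lag) {
  stopifnot(inherits(trace, "glucose_trace"))
  assert_repaired(trace, "shift_trace")
  n <- length(trace)
  lag <- as.integer(round(lag))
  if (abs(lag) >= n) stop("|lag| must be smaller than the trace length",
                          call. = FALSE)
  g <- trace$glucose
  if (lag > 0) {
    g <- c(rep(g[1], lag), g[1:(n - lag)])
  } else if (lag < 0) {
    k <- -lag
    g <- c(g[(k + 1):n], rep(g[n], k))
  }
  glucose_trace(trace$times, g, animal_id = trace$animal_id,
                missing = rep(FALSE, n), source = "shifted")
}

#' Convert plasma glucose to whole-blood-equivalent glucose
#'
#' Porcine erythrocytes are impermeable to glucose, so all of the glucose
#' in whole blood is carried by the plasma fraction:
#' `blood = plasma * (1 - hematocrit)`.
#'
#' @param plasma plasma glucose, mg/dL (vectorized).
#' @param hematocrit fraction in (0, 1).
#' @param factor conversion model; `"plasma_fraction"` (default) uses
#'   `1 - hematocrit`, `"identity"` disables the conversion.
#' @return blood-equivalent glucose, mg/dL.
#' @export
plasma_to_blood <- function(plasma, hematocrit,
                            factor = c("plasma_fraction", "identity")) {
  factor <- match.arg(factor)
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must lie in [0, 1)", call. = FALSE)
  }
  if (factor == "identity") return(plasma)
  plasma * (1 - hematocrit)
}

#' Bland-Altman agreement between two paired methods
#'
#' Differences are taken as `a - b`; `bias` is their mean, `sd_diff`
#' their sample standard deviation (n-1), and the 95% limits of
#' agreement are `bias +/- 1.96 * sd_diff`.
#'
#' @param a,b paired measurements (equal length, >= 2 pairs).
#' @return a `bland_altman` object: list with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n_pairs`, and the per-pair `means` and
#'   `differences` for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired", call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         n_pairs = n, means = (a + b) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d | bias %.2f mg/dL | 95%% LoA [%.2f, %.2f]\n",
              x$n_pairs, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}
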