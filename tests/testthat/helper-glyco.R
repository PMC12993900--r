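# shared fixtures and independent brute-force oracles
T0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

# build a trace from raw values on a uniform grid
make_trace <- function(values, by_min = 5, start = T0, source = "raw",
                       id = "test") {
  glucose_trace(start + 60 * by_min * (seq_along(values) - 1), values,
                animal_id = id, source = source)
}

# independent MAGE oracle: enumerate local extrema by direct comparison of
# each (plateau-compressed) point with its neighbours, then average the
# consecutive-extremum amplitudes exceeding one sample SD
oracle_mage <- function(values) {
  s <- stats::sd(values)
  v <- values[c(TRUE, diff(values) != 0)]
  m <- length(v)
  if (m < 2) return(list(mage = NA_real_, n = 0L))
  is_ext <- rep(FALSE, m)
  is_ext[1] <- TRUE; is_ext[m] <- TRUE
  if (m > 2) {
    for (i in 2:(m - 1)) {
      if ((v[i] > v[i - 1] && v[i] > v[i + 1]) ||
          (v[i] < v[i - 1] && v[i] < v[i + 1])) is_ext[i] <- TRUE
    }
  }
  amps <- diff(v[is_ext])
  qual <- abs(amps)[abs(amps) > s]
  list(mage = if (length(qual)) mean(qual) else NA_real_,
       n = length(qual),
       up = {u <- amps[amps > s]; if (length(u)) mean(u) else NA_real_},
       down = {d <- -amps[amps < -s]; if (length(d)) mean(d) else NA_real_})
}

# independent excursion oracle: plain index scan over a values vector on a
# uniform dt-minute grid, trapezoidal AUC beyond the crossed band edge
oracle_excursions <- function(values, lower, upper, dt = 5) {
  n <- length(values)
  state <- integer(n)
  state[values > upper] <- 1L
  state[values < lower] <- -1L
  out <- list()
  i <- 1L
  while (i <= n) {
    if (state[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == state[i]) j <- j + 1L
    edge <- if (state[i] == 1L) upper else lower
    dev <- abs(values[i:j] - edge)
    auc <- if (j > i) sum((dev[-1] + dev[-length(dev)]) / 2 * dt) else 0
    out[[length(out) + 1L]] <- data.frame(
      kind = if (state[i] == 1L) "peak" else "nadir",
      first = i, last = j,
      duration = (j - i) * dt,
      extremum = if (state[i] == 1L) max(values[i:j]) else min(values[i:j]),
      auc = auc)
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), first = integer(), last = integer(),
               duration = numeric(), extremum = numeric(), auc = numeric())
}
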