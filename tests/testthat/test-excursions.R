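band_of <- function(trace, start = trace$times[1],
                    end = trace$times[length(trace)]) {
  compute_baseline(trace, start, end)
}

toy_band <- function(mean = 100, sd = 10, id = "test") {
  structure(list(mean = mean, sd = sd, lower = mean - sd, upper = mean + sd,
                 reference_window = c(T0, T0), animal_id = id),
            class = "baseline_band")
}

test_that("baseline band is the window mean +/- one sample SD", {
  tr <- make_trace(rep(100, 12), source = "repaired")
  b <- band_of(tr)
  expect_equal(c(b$lower, b$mean, b$upper), c(100, 100, 100))

  vals <- rep(c(90, 110), 10)
  b2 <- band_of(make_trace(vals, source = "repaired"))
  s_hand <- sqrt(sum((vals - 100)^2) / (length(vals) - 1))  # n-1 convention
  expect_equal(b2$mean, 100)
  expect_equal(b2$upper - b2$lower, 2 * s_hand)

  # missing samples are excluded; an all-missing window errors
  vals3 <- c(100, rep(NA, 12), 100)
  tr3 <- make_trace(c(rep(100, 12), vals3))
  expect_error(compute_baseline(tr3, tr3$times[14], tr3$times[25]),
               "observed")
  expect_error(band_of(make_trace(rep(100, 5), source = "repaired")),
               ">= 10")
})

test_that("detect_excursions reproduces the hand-worked toy trace", {
  tr <- make_trace(c(100, 105, 120, 130, 115, 100, 85, 80, 95, 100),
                   source = "repaired")
  e <- detect_excursions(tr, toy_band())
  expect_equal(nrow(e), 2)
  pk <- e[e$kind == "peak", ]; nd <- e[e$kind == "nadir", ]
  expect_equal(pk$duration_min, 10)
  expect_equal(pk$extremum_value, 130)
  expect_equal(pk$auc, 137.5)  # trapezoid over excesses {10, 20, 5}
  expect_equal(nd$duration_min, 5)
  expect_equal(nd$extremum_value, 80)
  expect_equal(nd$auc, 37.5)   # trapezoid over deficits {5, 10}
})

test_that("excursion edge cases: inside band, single sample, degenerate band", {
  tr <- make_trace(c(95, 100, 105, 102, 98), source = "repaired")
  expect_equal(nrow(detect_excursions(tr, toy_band())), 0)

  tr2 <- make_trace(c(100, 120, 100), source = "repaired")
  e <- detect_excursions(tr2, toy_band())
  expect_equal(e$duration_min, 0)
  expect_equal(e$auc, 0)
  expect_equal(e$n_samples, 1L)

  expect_warning(detect_excursions(tr2, toy_band(sd = 0)), "degenerate")
})

test_that("excursions match the brute-force oracle on short integer traces", {
  set.seed(7)
  band <- toy_band()
  for (rep in 1:400) {
    n <- sample(3:15, 1)
    vals <- sample(c(80, 95, 100, 115, 130), n, replace = TRUE)
    tr <- make_trace(vals, source = "repaired")
    got <- detect_excursions(tr, band)
    want <- oracle_excursions(vals, band$lower, band$upper)
    expect_equal(nrow(got), nrow(want), info = paste(vals, collapse = ","))
    if (nrow(got)) {
      expect_identical(got$kind, want$kind)
      expect_equal(got$duration_min, want$duration)
      expect_equal(got$extremum_value, want$extremum)
      expect_equal(got$auc, want$auc, tolerance = 1e-12)
    }
  }
})

test_that("excursion runs partition the out-of-band samples", {
  set.seed(17)
  band <- toy_band()
  for (rep in 1:30) {
    vals <- round(runif(60, 70, 140))
    tr <- make_trace(vals, source = "repaired")
    e <- detect_excursions(tr, band)
    expect_equal(sum(e$n_samples), sum(vals > band$upper | vals < band$lower))
    if (nrow(e) > 1) {
      expect_true(all(diff(as.numeric(e$start)) > 0))  # ordered, disjoint
      expect_true(all(e$start[-1] > e$end[-nrow(e)]))
    }
  }
})

test_that("detection is shift-equivariant and band-monotone", {
  set.seed(23)
  for (rep in 1:25) {
    vals <- round(runif(40, 70, 140))
    tr <- make_trace(vals, source = "repaired")
    b1 <- toy_band()
    e1 <- detect_excursions(tr, b1)
    # adding a constant to trace and band changes nothing
    e2 <- detect_excursions(make_trace(vals + 25, source = "repaired"),
                            toy_band(mean = 125))
    expect_equal(nrow(e1), nrow(e2))
    if (nrow(e1)) expect_equal(e1$auc, e2$auc)
    # widening the band never increases the excursion count
    wide <- toy_band(sd = 18)
    expect_lte(nrow(detect_excursions(tr, wide)), nrow(e1))
  }
})

test_that("summarize_period aggregates counts, totals and the sharpest runs", {
  tr <- make_trace(c(100, 105, 120, 130, 115, 100, 85, 80, 95, 100),
                   source = "repaired")
  band <- toy_band()
  e <- detect_excursions(tr, band)
  s <- summarize_period(e, tr, band, tr$times[1], tr$times[10],
                        period = "night")
  expect_equal(s$n_peaks, 1); expect_equal(s$n_nadirs, 1)
  expect_equal(s$total_peak_auc, 137.5)
  expect_equal(s$total_nadir_auc, 37.5)
  expect_equal(s$max_glucose, 130); expect_equal(s$min_glucose, 80)
  expect_equal(s$relative_range_pct, 100 * 50 / 130)
  expect_equal(s$sharpest_peak_value, 130)
  expect_equal(s$frac_above + s$frac_below + s$frac_within_band, 1)

  # no excursions: zero counts, fractions {0, 0, 1}, undefined sharpest
  tr2 <- make_trace(rep(c(98, 102), 5), source = "repaired")
  s2 <- summarize_period(detect_excursions(tr2, band), tr2, band,
                         tr2$times[1], tr2$times[10])
  expect_equal(s2$n_peaks, 0)
  expect_equal(s2$total_peak_auc, 0)
  expect_true(is.na(s2$sharpest_peak_value))
  expect_equal(c(s2$frac_above, s2$frac_below, s2$frac_within_band),
               c(0, 0, 1))
})

test_that("ties for the sharpest excursion go to the earlier run", {
  vals <- c(100, 125, 100, 125, 100)
  tr <- make_trace(vals, source = "repaired")
  band <- toy_band()
  e <- detect_excursions(tr, band)
  expect_equal(nrow(e), 2)
  s <- summarize_period(e, tr, band, tr$times[1], tr$times[5])
  expect_equal(s$sharpest_peak_value, 125)
  first_peak <- min(e$start[e$kind == "peak"])
  # re-detect and confirm the summary picked the earlier of the tied runs
  expect_equal(s$sharpest_peak_duration, e$duration_min[e$start == first_peak])
})

test_that("totals equal the sums over member excursions", {
  set.seed(31)
  vals <- 100 + 25 * sin(2 * pi * (0:199) / 40) + rnorm(200, 0, 5)
  tr <- make_trace(vals, source = "repaired")
  band <- toy_band()
  e <- detect_excursions(tr, band)
  s <- summarize_period(e, tr, band, tr$times[1], tr$times[200])
  expect_equal(s$total_peak_auc, sum(e$auc[e$kind == "peak"]),
               tolerance = 1e-9)
  expect_equal(s$total_nadir_duration,
               sum(e$duration_min[e$kind == "nadir"]), tolerance = 1e-9)
})

test_that("resolve_windows expands clock windows onto the calendar", {
  d <- study_design()
  # two full days: nights starting day 1 only (night 2 runs past the span)
  span_end <- T0 + 2 * 86400 - 300
  win <- resolve_windows(d, T0, span_end)
  expect_equal(sum(win$period == "night"), 1)
  expect_equal(sum(win$period == "day"), 2)
  night <- win[win$period == "night", ]
  expect_equal(format(night$start, "%H:%M"), "21:00")
  expect_equal(format(night$end, "%H:%M"), "06:55")
  # 5-min grid, endpoint-inclusive: 120 samples in a night
  grid <- T0 + 300 * (0:575)
  expect_equal(sum(grid >= night$start & grid <= night$end), 120)
  pp <- win[win$period == "postprandial", ][1, ]
  expect_equal(format(pp$start, "%H:%M"), "08:45")
  expect_equal(format(pp$end, "%H:%M"), "13:00")
})
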