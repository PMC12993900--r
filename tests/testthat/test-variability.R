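test_that("MAGE matches the hand-worked toy trace", {
  # 30-min spacing so the 5 samples span the required 2 h
  tr <- make_trace(c(100, 140, 100, 120, 100), by_min = 30,
                   source = "repaired")
  m <- compute_mage(tr)
  # amplitudes {40, 40, 20, 20}, all above the window SD (~17.9)
  expect_equal(m$mage, 30)
  expect_equal(m$mage_up, 30)
  expect_equal(m$mage_down, 30)
  expect_equal(m$n_qualifying, 4L)
})

test_that("MAGE is undefined (not zero) without qualifying excursions", {
  m <- compute_mage(make_trace(rep(100, 30), source = "repaired"))
  expect_true(is.na(m$mage))
  expect_identical(m$n_qualifying, 0L)
})

test_that("MAGE is symmetric on a triangle wave", {
  # closes on the starting value so ascending and descending swings pair up
  vals <- c(rep(c(100, 110, 120, 130, 120, 110), 8), 100)  # amplitude 30 > SD
  m <- compute_mage(make_trace(vals, by_min = 15, source = "repaired"))
  expect_lt(sd(vals), 30)
  expect_equal(m$mage_up, m$mage_down)
})

test_that("MAGE agrees with the brute-force oracle on random short traces", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(5:12, 1)
    vals <- sample(c(80, 95, 100, 120, 150), n, replace = TRUE)
    tr <- make_trace(vals, by_min = 30, source = "repaired")
    got <- compute_mage(tr)
    want <- oracle_mage(vals)
    expect_equal(got$mage, want$mage,
                 info = paste(vals, collapse = ","))
    expect_identical(got$n_qualifying, want$n)
  }
})

test_that("CONGA matches direct differencing and the sinusoid closed form", {
  expect_equal(compute_conga(make_trace(rep(100, 30), source = "repaired"), 1),
               0)
  tt <- seq(0, 72 * 60 - 5, by = 5)
  g <- 100 + 10 * sin(2 * pi * tt / (24 * 60))
  tr <- make_trace(g, source = "repaired")
  # exact finite-window closed form: differences are a pure sinusoid in t,
  # evaluated on the same grid the implementation sees
  conga_closed <- function(n_hours) {
    keep <- tt >= n_hours * 60
    d <- 2 * 10 * sin(pi * n_hours / 24) *
      cos(2 * pi * (tt[keep] - n_hours * 30) / (24 * 60))
    sd(d)
  }
  expect_equal(compute_conga(tr, 1), conga_closed(1), tolerance = 1e-9)
  expect_equal(compute_conga(tr, 12), conga_closed(12), tolerance = 1e-9)
  # the infinite-window limit for CONGA(1 h)
  expect_equal(compute_conga(tr, 1), sqrt(2) * 10 * abs(sin(pi / 24)),
               tolerance = 0.01)
})

test_that("CONGA is shift-invariant and scales linearly", {
  set.seed(9)
  vals <- 110 + cumsum(rnorm(100))
  tr <- make_trace(vals, source = "repaired")
  base <- compute_conga(tr, 2)
  shifted <- compute_conga(make_trace(vals + 37, source = "repaired"), 2)
  scaled <- compute_conga(make_trace(3 * vals, source = "repaired"), 2)
  expect_equal(shifted, base)
  expect_equal(scaled, 3 * base)
  expect_error(compute_conga(make_trace(vals[1:10], source = "repaired"), 2),
               "shorter")
})

test_that("time-in-range fractions classify with the asymmetric convention", {
  tr <- make_trace(c(60, 100, 200, 150), source = "repaired")
  tir <- compute_time_in_range(tr, 70, 180)
  expect_equal(unname(tir), c(0.25, 0.50, 0.25))
  # boundary: exactly 70 is within, exactly 180 is above
  tir2 <- compute_time_in_range(make_trace(c(70, 180), source = "repaired"),
                                70, 180)
  expect_equal(unname(tir2), c(0, 0.5, 0.5))
  expect_equal(unname(compute_time_in_range(
    make_trace(rep(100, 5), source = "repaired"))), c(0, 1, 0))
  expect_error(compute_time_in_range(tr, 180, 70), "lo")
})

test_that("TIR is a partition on random traces", {
  set.seed(13)
  for (i in 1:20) {
    tr <- make_trace(runif(50, 40, 260), source = "repaired")
    expect_equal(sum(compute_time_in_range(tr)), 1, tolerance = 1e-12)
  }
})

test_that("variability_metrics bundles MAGE, CONGA and TIR", {
  set.seed(21)
  vals <- 120 + 30 * sin(2 * pi * (0:575) / 288) + rnorm(576, 0, 8)
  v <- variability_metrics(make_trace(vals, source = "repaired"))
  expect_true(all(c("mage", "conga_1h", "conga_6h", "tir_within") %in%
                    names(v)))
  expect_gt(v$mage, 0)
  expect_equal(v$tir_below + v$tir_within + v$tir_above, 1)
  # lags longer than the trace come back NA rather than erroring
  v2 <- variability_metrics(make_trace(vals[1:30], source = "repaired"),
                            conga_hours = c(1, 6))
  expect_true(is.na(v2$conga_6h))
})
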