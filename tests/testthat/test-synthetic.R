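quiet_cfg <- function(...) {
  sim_config(circadian_amplitude = 0, meal_amplitude_hs = 0,
             meal_amplitude_hf = 0, wavelet_rate = 0, sensor_bias = 0,
             sensor_noise_sd = 0, sensor_lag = 0, missing_rate = 0, ...)
}

test_that("zero amplitudes give a constant basal trace", {
  tb <- simulate_true_blood(quiet_cfg(days = 1), animal = 1)
  expect_equal(tb$glucose, rep(100, 288))
  expect_identical(tb$source, "simulated")
})

test_that("a single meal peaks at time_to_peak on the grid", {
  cfg <- sim_config(days = 1, circadian_amplitude = 0, wavelet_rate = 0,
                    meal_amplitude_hs = 60, time_to_peak_hs = c(40, 40),
                    sensor_noise_sd = 0, missing_rate = 0,
                    design = study_design(meal_times = "09:00",
                                          meal_test_days = integer()))
  tb <- simulate_true_blood(cfg, animal = 1)
  peak_t <- trace_minutes(tb)[which.max(tb$glucose)]
  expect_lte(abs(peak_t - (9 * 60 + 40)), 5)  # within one grid step
  expect_equal(max(tb$glucose) - 100, 60, tolerance = 0.5)
})

test_that("simulation is deterministic per seed and differs across seeds", {
  cfg <- sim_config(n_animals = 2, days = 2, seed = 5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cgm[[1]]$glucose, s2$cgm[[1]]$glucose)
  expect_identical(s1$truth$wavelets, s2$truth$wavelets)
  s3 <- simulate_study(sim_config(n_animals = 2, days = 2, seed = 6))
  expect_false(identical(s1$cgm[[1]]$glucose, s3$cgm[[1]]$glucose))
  # animals within one study differ
  expect_false(identical(s1$cgm[[1]]$glucose, s1$cgm[[2]]$glucose))
})

test_that("the ideal sensor reads back the true blood trace", {
  cfg <- sim_config(days = 1, sensor_bias = 0, sensor_noise_sd = 0,
                    sensor_lag = 0, missing_rate = 0)
  tb <- simulate_true_blood(cfg, 1)
  cgm <- simulate_cgm(tb, cfg, 1)
  expect_equal(cgm$glucose, tb$glucose)
})

test_that("constant sensor bias shifts every sample by exactly that bias", {
  cfg <- sim_config(days = 1, sensor_bias = 37, sensor_noise_sd = 0,
                    sensor_lag = 0, missing_rate = 0)
  tb <- simulate_true_blood(cfg, 1)
  cgm <- simulate_cgm(tb, cfg, 1)
  expect_equal(cgm$glucose - tb$glucose, rep(37, length(tb)))
})

test_that("the injected sensor lag is recovered by estimate_lag", {
  cfg <- sim_config(days = 1, sensor_lag = 14, sensor_bias = 20,
                    sensor_noise_sd = 2, missing_rate = 0, seed = 3)
  tb <- simulate_true_blood(cfg, 1)
  cgm <- simulate_cgm(tb, cfg, 1)
  al <- estimate_lag(resample_minutely(cgm), resample_minutely(tb),
                     max_lag = 60)
  expect_lte(abs(al$lag - 14), 1)
})

test_that("blood samples follow the schedule and invert exactly", {
  cfg <- sim_config(days = 1, seed = 2)
  tb <- simulate_true_blood(cfg, 1)
  meal <- T0 + 9 * 3600
  bs <- simulate_blood_samples(tb, meal, hematocrit = 0.42,
                               assay_noise_sd = 0)
  expect_length(bs, 15)  # -15 min draw + 14 postprandial draws
  expect_equal(bs$times[1], meal - 15 * 60)
  expect_equal(bs$times[15], meal + 240 * 60)
  # zero assay noise: plasma / (1 - hct) inverts through plasma_to_blood
  idx <- match(as.numeric(bs$times), as.numeric(tb$times))
  expect_equal(plasma_to_blood(bs$plasma_glucose, 0.42),
               tb$glucose[idx], tolerance = 1e-12)

  bs5 <- simulate_blood_samples(tb, meal, hematocrit = 0.5,
                                assay_noise_sd = 0)
  expect_equal(bs5$plasma_glucose, 2 * tb$glucose[idx], tolerance = 1e-12)
  expect_error(simulate_blood_samples(tb, T0 + 23.9 * 3600, 0.42),
               "outside")
})

test_that("simulate_study produces a complete, writable cohort", {
  cfg <- sim_config(n_animals = 2, days = 5, seed = 9)
  st <- simulate_study(cfg)
  expect_length(st$cgm, 2)
  expect_equal(length(st$cgm[[1]]), 5 * 288)
  expect_named(st$samples[[1]], c("2", "5"))
  expect_true(all(c("sensor_lag", "meals", "wavelets") %in% names(st$truth)))
  # truth meals cover every animal and day
  expect_setequal(unique(st$truth$meals$animal_id), names(st$cgm))

  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "pig01_cgm.csv")))
  expect_true(file.exists(file.path(dir, "design.yaml")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_study_dir(dir)
  expect_length(back$cgm, 2)
  expect_equal(back$cgm[["pig01"]]$glucose, st$cgm[["pig01"]]$glucose)
  expect_length(back$samples[["pig01"]], 2)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(sensor_ar1 = 1), "ar1")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(circadian_amplitude = -1), "amplitudes")
  # nadir wavelets deep enough to cross zero are rejected
  cfg <- sim_config(basal_mean = 10, wavelet_amplitude = c(40, 40),
                    wavelet_rate = 8, days = 2, seed = 1)
  expect_error(simulate_true_blood(cfg, 1), "non-positive")
})
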