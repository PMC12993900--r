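# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-(seed, animal, stream) sub-seed, kept below 2^31
sub_seed <- function(seed, animal, stream) {
  (as.numeric(seed) * 7919 + animal * 104729 + stream * 1299709) %% 2147483647
}

#' Simulation configuration for a synthetic CGM cohort
#'
#' Defaults state the world the analysis was built for: eight growing
#' pigs over a 5-day trial, 5-min sampling, basal glycemia around
#' 100 mg/dL with a mild circadian swing, two daily meals whose response
#' amplitude depends on the diet mix (high-starch ~60 mg/dL with peak
#' 35-55 min after eating; high-fat ~35 mg/dL, peak 20-155 min),
#' nocturnal glucose wavelets at ~2 per night with 15-35 mg/dL amplitude,
#' and a sensor that trails blood by 14 min, over-reads by a constant
#' bias and adds AR(1) noise. Missing readings are rare (receivers drop
#' the occasional sample only).
#'
#' @param n_animals number of animals (default 8).
#' @param days trial length in days (default 5).
#' @param sample_interval sampling interval in minutes (default 5).
#' @param basal_mean basal glucose, mg/dL (default 100).
#' @param circadian_amplitude circadian sinusoid amplitude, mg/dL
#'   (default 8; peak mid-afternoon).
#' @param meal_amplitude_hs,meal_amplitude_hf peak meal response for the
#'   pure high-starch / high-fat formulas, mg/dL (defaults 60 and 35).
#' @param time_to_peak_hs,time_to_peak_hf `c(min, max)` minutes from meal
#'   to peak, sampled per animal and diet (defaults `c(35, 55)` and
#'   `c(20, 155)`).
#' @param decay_halflife exponential decay half-life of the meal
#'   response after the peak, minutes (default 45).
#' @param wavelet_rate expected nocturnal wavelets per night (default 2).
#' @param wavelet_amplitude `c(min, max)` wavelet amplitude, mg/dL
#'   (default `c(15, 35)`); sign (peak vs dip) is random.
#' @param wavelet_duration `c(min, max)` wavelet full duration, minutes
#'   (default `c(30, 90)`).
#' @param sensor_bias constant CGM over-read, mg/dL (default 20).
#' @param sensor_noise_sd AR(1) innovation scale such that the marginal
#'   noise SD equals this value, mg/dL (default 5).
#' @param sensor_ar1 AR(1) coefficient in `[0, 1)` (default 0.7).
#' @param sensor_lag interstitial lag, minutes (default 14).
#' @param missing_rate fraction of interior samples dropped, in
#'   `[0, 0.2]` (default 0.005).
#' @param hematocrit per-animal hematocrit; recycled (default 0.42).
#' @param assay_noise_sd plasma assay noise SD, mg/dL (default 2).
#' @param seed master seed (default 1).
#' @param start trace start (`POSIXct`, midnight of trial day 1).
#' @param design a [study_design()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_animals = 8L, days = 5L, sample_interval = 5,
                       basal_mean = 100, circadian_amplitude = 8,
                       meal_amplitude_hs = 60, meal_amplitude_hf = 35,
                       time_to_peak_hs = c(35, 55),
                       time_to_peak_hf = c(20, 155),
                       decay_halflife = 45,
                       wavelet_rate = 2,
                       wavelet_amplitude = c(15, 35),
                       wavelet_duration = c(30, 90),
                       sensor_bias = 20, sensor_noise_sd = 5,
                       sensor_ar1 = 0.7, sensor_lag = 14,
                       missing_rate = 0.005,
                       hematocrit = 0.42,
                       assay_noise_sd = 2,
                       seed = 1L,
                       start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                       design = study_design()) {
  if (sensor_ar1 < 0 || sensor_ar1 >= 1) stop("sensor_ar1 must be in [0, 1)",
                                              call. = FALSE)
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("missing_rate must be in [0, 0.2]", call. = FALSE)
  }
  amps <- c(circadian_amplitude, meal_amplitude_hs, meal_amplitude_hf,
            wavelet_amplitude, sensor_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  cfg <- list(n_animals = as.integer(n_animals), days = as.integer(days),
              sample_interval = sample_interval, basal_mean = basal_mean,
              circadian_amplitude = circadian_amplitude,
              meal_amplitude_hs = meal_amplitude_hs,
              meal_amplitude_hf = meal_amplitude_hf,
              time_to_peak_hs = time_to_peak_hs,
              time_to_peak_hf = time_to_peak_hf,
              decay_halflife = decay_halflife,
              wavelet_rate = wavelet_rate,
              wavelet_amplitude = wavelet_amplitude,
              wavelet_duration = wavelet_duration,
              sensor_bias = sensor_bias, sensor_noise_sd = sensor_noise_sd,
              sensor_ar1 = sensor_ar1, sensor_lag = sensor_lag,
              missing_rate = missing_rate,
              hematocrit = rep_len(hematocrit, n_animals),
              assay_noise_sd = assay_noise_sd,
              seed = as.integer(seed), start = start, design = design)
  class(cfg) <- "sim_config"
  cfg
}

# smooth meal impulse response: smoothstep rise to `amp` at `tp` minutes
# after the meal, then exponential decay with half-life `hl`
meal_response <- function(t_since_meal, amp, tp, hl) {
  r <- numeric(length(t_since_meal))
  up <- t_since_meal >= 0 & t_since_meal < tp
  u <- t_since_meal[up] / tp
  r[up] <- amp * u^2 * (3 - 2 * u)
  dn <- t_since_meal >= tp
  r[dn] <- amp * 2^(-(t_since_meal[dn] - tp) / hl)
  r
}

# raised-cosine bump of amplitude a and full duration d centred at c
wavelet_bump <- function(t, centre, a, d) {
  z <- (t - centre) / d
  ifelse(abs(z) < 0.5, a * cos(pi * z)^2, 0)
}

# per-animal meal schedule: data.frame(day, time_min (since trace start),
# hs_fraction, amplitude, time_to_peak)
animal_meal_table <- function(config, animal) {
  d <- config$design
  seq_tab <- d$diet_sequence
  tp <- with_seed(sub_seed(config$seed, animal, 1L), c(
    stats::runif(1, config$time_to_peak_hs[1], config$time_to_peak_hs[2]),
    stats::runif(1, config$time_to_peak_hf[1], config$time_to_peak_hf[2])
  ))
  rows <- list()
  for (day in seq_len(config$days)) {
    fr <- seq_tab$hs_fraction[match(day, seq_tab$day)]
    if (is.na(fr)) fr <- seq_tab$hs_fraction[nrow(seq_tab)]
    is_test <- day %in% d$meal_test_days
    mt <- if (is_test) c(d$test_meal_time, d$meal_times[-1]) else d$meal_times
    for (clock in mt) {
      rows[[length(rows) + 1L]] <- data.frame(
        day = day,
        time_min = (day - 1) * 1440 + clock_minutes(clock),
        hs_fraction = fr,
        amplitude = fr * config$meal_amplitude_hs +
          (1 - fr) * config$meal_amplitude_hf,
        time_to_peak = fr * tp[1] + (1 - fr) * tp[2],
        test_meal = is_test && clock == d$test_meal_time
      )
    }
  }
  do.call(rbind, rows)
}

# nocturnal wavelets for one animal: Poisson count per night, uniform
# centre within the night window, amplitude with random sign
animal_wavelets <- function(config, animal) {
  d <- config$design
  nw <- clock_minutes(d$night_window)
  night_len <- if (nw[2] <= nw[1]) 1440 - nw[1] + nw[2] else nw[2] - nw[1]
  with_seed(sub_seed(config$seed, animal, 2L), {
    rows <- list()
    for (night in seq_len(config$days - 1L)) {
      k <- stats::rpois(1, config$wavelet_rate)
      if (k == 0) next
      centres <- (night - 1) * 1440 + nw[1] +
        sort(stats::runif(k, 0, night_len))
      amps <- stats::runif(k, config$wavelet_amplitude[1],
                           config$wavelet_amplitude[2]) *
        sample(c(-1, 1), k, replace = TRUE)
      durs <- stats::runif(k, config$wavelet_duration[1],
                           config$wavelet_duration[2])
      rows[[length(rows) + 1L]] <- data.frame(
        night = night, centre_min = centres, amplitude = amps,
        duration = durs)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(night = integer(), centre_min = numeric(),
                 amplitude = numeric(), duration = numeric())
  })
}

#' Simulate an animal's true blood glucose trace
#'
#' Blood glucose = basal + circadian sinusoid (peak mid-afternoon) + the
#' sum of meal impulse responses (smooth rise to the diet-dependent
#' amplitude at `time_to_peak`, then exponential decay) + nocturnal
#' raised-cosine wavelets at Poisson-distributed times within the night
#' window. Fully deterministic given `(config$seed, animal)`.
#'
#' @param config a [sim_config()].
#' @param animal animal index (1-based).
#' @return a [glucose_trace()] with `source = "simulated"`, plus
#'   attributes `meals` and `wavelets` (the injected truth).
#' @export
simulate_true_blood <- function(config, animal = 1L) {
  stopifnot(inherits(config, "sim_config"))
  t_min <- seq(0, config$days * 1440 - config$sample_interval,
               by = config$sample_interval)
  hours <- (t_min / 60) %% 24
  g <- config$basal_mean +
    config$circadian_amplitude * sin(2 * pi * (hours - 9) / 24)
  meals <- animal_meal_table(config, animal)
  for (i in seq_len(nrow(meals))) {
    g <- g + meal_response(t_min - meals$time_min[i], meals$amplitude[i],
                           meals$time_to_peak[i], config$decay_halflife)
  }
  wl <- animal_wavelets(config, animal)
  for (i in seq_len(nrow(wl))) {
    g <- g + wavelet_bump(t_min, wl$centre_min[i], wl$amplitude[i],
                          wl$duration[i])
  }
  if (any(g <= 0)) {
    stop("configuration yields non-positive blood glucose; reduce nadir amplitudes",
         call. = FALSE)
  }
  tr <- glucose_trace(config$start + 60 * t_min, g,
                      animal_id = sprintf("pig%02d", animal),
                      missing = rep(FALSE, length(g)), source = "simulated")
  attr(tr, "meals") <- meals
  attr(tr, "wavelets") <- wl
  tr
}

#' Simulate the CGM sensor reading of a true blood trace
#'
#' CGM = true blood delayed by the interstitial `sensor_lag` (linear
#' interpolation on the trace's own grid, edge-padded), plus the constant
#' sensor bias, plus AR(1) noise with the configured marginal SD; finally
#' interior samples are dropped at `missing_rate` (never the first or
#' last sample). Deterministic given `(config$seed, animal)`.
#'
#' @param true_blood trace from [simulate_true_blood()].
#' @param config a [sim_config()].
#' @param animal animal index (used for the noise stream).
#' @return a [glucose_trace()] with `source = "simulated"` and flagged
#'   missing points (`NA` glucose).
#' @export
simulate_cgm <- function(true_blood, config, animal = 1L) {
  stopifnot(inherits(true_blood, "glucose_trace"), inherits(config, "sim_config"))
  t_min <- trace_minutes(true_blood)
  gb <- true_blood$glucose
  lagged <- stats::approx(t_min, gb, xout = t_min - config$sensor_lag,
                          rule = 2)$y
  n <- length(gb)
  with_seed(sub_seed(config$seed, animal, 3L), {
    if (config$sensor_noise_sd > 0) {
      innov_sd <- config$sensor_noise_sd * sqrt(1 - config$sensor_ar1^2)
      eps <- stats::rnorm(n, 0, innov_sd)
      noise <- as.numeric(stats::filter(eps, config$sensor_ar1,
                                        method = "recursive"))
    } else {
      noise <- numeric(n)
    }
    g <- lagged + config$sensor_bias + noise
    miss <- rep(FALSE, n)
    if (config$missing_rate > 0 && n > 2) {
      interior <- 2:(n - 1)
      miss[interior] <- stats::runif(n - 2) < config$missing_rate
    }
    g[miss] <- NA_real_
    glucose_trace(true_blood$times, g, animal_id = true_blood$animal_id,
                  missing = miss, source = "simulated")
  })
}

#' Simulate scheduled catheter blood samples
#'
#' Plasma glucose at the scheduled draw times: true blood divided by the
#' plasma fraction `1 - hematocrit` (porcine red cells carry no glucose),
#' plus assay noise. With zero assay noise, [plasma_to_blood()] recovers
#' the true blood values exactly.
#'
#' @param true_blood trace from [simulate_true_blood()].
#' @param meal_time `POSIXct` time of the test meal.
#' @param hematocrit fraction in (0.15, 0.60).
#' @param schedule minutes relative to the meal (default: the -15 min
#'   pre-meal draw plus 10, 20, 30, 40, 50, 60, 75, 90, 105, 120, 150,
#'   180, 210, 240 min postprandially).
#' @param assay_noise_sd mg/dL (default 2).
#' @param seed RNG seed for the assay noise.
#' @return a [blood_samples()] series (`medium = "plasma"`).
#' @export
simulate_blood_samples <- function(true_blood, meal_time, hematocrit,
                                   schedule = c(-15, 10, 20, 30, 40, 50, 60,
                                                75, 90, 105, 120, 150, 180,
                                                210, 240),
                                   assay_noise_sd = 2, seed = 1L) {
  stopifnot(inherits(true_blood, "glucose_trace"))
  times <- meal_time + 60 * schedule
  if (min(times) < true_blood$times[1] ||
      max(times) > true_blood$times[length(true_blood)]) {
    stop("sampling schedule extends outside the trace span", call. = FALSE)
  }
  t_min <- trace_minutes(true_blood)
  xout <- as.numeric(times - true_blood$times[1], units = "mins")
  gb <- stats::approx(t_min, true_blood$glucose, xout = xout)$y
  plasma <- gb / (1 - hematocrit)
  if (assay_noise_sd > 0) {
    plasma <- with_seed(seed,
                        plasma + stats::rnorm(length(plasma), 0, assay_noise_sd))
  }
  blood_samples(times, plasma, hematocrit = hematocrit,
                animal_id = true_blood$animal_id, medium = "plasma")
}

#' Simulate a full study cohort
#'
#' Generates, per animal: the true blood trace, its CGM reading, and
#' sparse plasma samples around the test meal on each meal-test day. A
#' `truth` record retains everything injected (sensor lag and bias, meal
#' amplitudes and peak times, wavelet times) so parameter-recovery tests
#' can close the loop. Byte-reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with elements `cgm` (list of
#'   traces), `true_blood` (list), `samples` (list of lists, one per
#'   meal-test day), `design`, `config`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$design
  cgm <- true_blood <- vector("list", config$n_animals)
  samples <- vector("list", config$n_animals)
  truth_meals <- list(); truth_wavelets <- list()
  for (a in seq_len(config$n_animals)) {
    tb <- simulate_true_blood(config, a)
    true_blood[[a]] <- tb
    cgm[[a]] <- simulate_cgm(tb, config, a)
    m <- attr(tb, "meals"); m$animal_id <- tb$animal_id
    w <- attr(tb, "wavelets")
    if (nrow(w)) w$animal_id <- tb$animal_id else w$animal_id <- character()
    truth_meals[[a]] <- m; truth_wavelets[[a]] <- w
    day_samples <- list()
    for (day in d$meal_test_days) {
      meal_time <- config$start + 60 *
        ((day - 1) * 1440 + clock_minutes(d$test_meal_time))
      # drop test days whose sampling schedule falls outside the trace
      if (meal_time - 15 * 60 < tb$times[1] ||
          meal_time + 240 * 60 > tb$times[length(tb)]) next
      day_samples[[as.character(day)]] <- simulate_blood_samples(
        tb, meal_time, config$hematocrit[a],
        assay_noise_sd = config$assay_noise_sd,
        seed = sub_seed(config$seed, a, 10L + day))
    }
    samples[[a]] <- day_samples
  }
  names(cgm) <- names(true_blood) <- names(samples) <-
    vapply(cgm, function(x) x$animal_id, character(1))
  structure(
    list(cgm = cgm, true_blood = true_blood, samples = samples,
         design = d, config = config,
         truth = list(
           sensor_lag = config$sensor_lag,
           sensor_bias = config$sensor_bias,
           hematocrit = stats::setNames(config$hematocrit, names(cgm)),
           meals = do.call(rbind, truth_meals),
           wavelets = do.call(rbind, truth_wavelets))),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d animals x %d days | seed %d\n",
              x$config$n_animals, x$config$days, x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One CGM CSV and one blood-sample CSV per animal in the canonical
#' dialects, plus `design.yaml` and `truth.json`.
#'
#' @param study a [simulate_study()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(study$cgm)) {
    write_cgm_csv(study$cgm[[id]], file.path(dir, sprintf("%s_cgm.csv", id)))
    for (day in names(study$samples[[id]])) {
      write_blood_samples(
        study$samples[[id]][[day]],
        file.path(dir, sprintf("%s_blood_day%s.csv", id, day)))
    }
  }
  d <- study$design
  yaml::write_yaml(list(
    night_window = d$night_window, day_window = d$day_window,
    postprandial_window = d$postprandial_window,
    meal_times = d$meal_times, test_meal_time = d$test_meal_time,
    meal_test_days = d$meal_test_days,
    euglycemic_range = d$euglycemic_range
  ), file.path(dir, "design.yaml"))
  tr <- study$truth
  tr$meals$time_min <- NULL
  jsonlite::write_json(
    list(sensor_lag = tr$sensor_lag, sensor_bias = tr$sensor_bias,
         hematocrit = as.list(tr$hematocrit),
         meals = tr$meals, wavelets = tr$wavelets),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
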