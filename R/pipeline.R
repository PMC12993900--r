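#' Run the full study analysis end-to-end
#'
#' For each animal: repair missing points, Savitzky-Golay smooth, resolve
#' the night/day/postprandial windows, establish the baseline band
#' (night windows use their own span; day and postprandial windows use
#' the preceding night, the convention anchoring postprandial analysis to
#' the fasted nocturnal state), detect excursions and summarize each
#' period, and compute variability metrics (MAGE/CONGA on the unsmoothed
#' repaired trace — the convention for those whole-signal metrics — and
#' time-in-range). Where serial blood samples exist, the
#' plasma-to-blood-converted samples and the CGM are resampled to 1 min,
#' the CGM-vs-blood lag estimated, the CGM shifted, and Bland-Altman
#' agreement computed. Cohort level: one-way diet ANOVA on postprandial
#' metrics, the night-vs-postprandial Spearman screen per diet,
#' night-vs-day ANOVA and variance F-tests, repeated-measures CGM/blood
#' correlation per diet, and a PCA of night and day metrics.
#'
#' Per-animal failures are caught, logged and skipped; the pipeline only
#' fails if every animal fails.
#'
#' @param study a [simulate_study()] bundle, or any list with elements
#'   `cgm` (named list of [glucose_trace()]s), optional `samples` (per
#'   animal, per meal-test day [blood_samples()]), and `design`.
#' @param out_dir optional directory; when given, tidy CSV reports and a
#'   run log are written there.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param max_lag cross-correlation search bound, minutes.
#' @param conga_hours CONGA lags, hours.
#' @return list of class `glyco_report`: `period_metrics`,
#'   `variability`, `excursions`, `alignment`, `screens`, `night_day`,
#'   `rmcorr`, `pca`, `failures`, `log`.
#' @export
run_pipeline <- function(study, out_dir = NULL, sg_window = 9L, sg_order = 3L,
                         max_lag = 60, conga_hours = c(1, 2, 6)) {
  design <- study$design
  stopifnot(inherits(design, "study_design"))
  eug <- design$euglycemic_range
  per_rows <- list(); var_rows <- list(); exc_rows <- list()
  align_rows <- list(); pair_rows <- list()
  failures <- character()
  log_lines <- c(
    sprintf("glyco %s", as.character(utils::packageVersion("glyco"))),
    sprintf("run at (fixed for determinism): trace-defined"),
    sprintf("params: sg_window=%d sg_order=%d max_lag=%g conga=%s range=%g-%g",
            sg_window, sg_order, max_lag,
            paste(conga_hours, collapse = ","), eug[1], eug[2]),
    if (inherits(study, "sim_study"))
      sprintf("sim seed: %d", study$config$seed) else "input: external files"
  )
  diet_of_day <- function(day) {
    ds <- design$diet_sequence
    i <- match(day, ds$day)
    if (is.na(i)) NA_character_ else ds$diet[i]
  }
  for (id in names(study$cgm)) {
    res <- tryCatch({
      analyze_animal(study$cgm[[id]], design, sg_window, sg_order,
                     conga_hours, eug, diet_of_day)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, id)
      log_lines <- c(log_lines,
                     sprintf("FAIL %s: %s", id, conditionMessage(res)))
      next
    }
    per_rows[[id]] <- res$period_metrics
    var_rows[[id]] <- res$variability
    exc_rows[[id]] <- res$excursions
    # alignment against blood samples, per meal-test day
    day_samp <- study$samples[[id]]
    for (day in names(day_samp)) {
      al <- tryCatch({
        align_animal_day(res$smoothed, day_samp[[day]], design,
                         as.integer(day), max_lag)
      }, error = function(e) e)
      if (inherits(al, "error")) {
        log_lines <- c(log_lines,
                       sprintf("ALIGN-FAIL %s day %s: %s", id, day,
                               conditionMessage(al)))
        next
      }
      al$summary$diet <- diet_of_day(as.integer(day))
      align_rows[[paste(id, day)]] <- al$summary
      al$pairs$diet <- diet_of_day(as.integer(day))
      pair_rows[[paste(id, day)]] <- al$pairs
    }
  }
  if (!length(per_rows)) {
    stop(sprintf("all animals failed: %s", paste(failures, collapse = ", ")),
         call. = FALSE)
  }
  period_metrics <- do.call(rbind, c(per_rows, list(make.row.names = FALSE)))
  variability <- do.call(rbind, c(var_rows, list(make.row.names = FALSE)))
  excursions <- do.call(rbind, c(exc_rows, list(make.row.names = FALSE)))
  alignment <- if (length(align_rows)) {
    do.call(rbind, c(align_rows, list(make.row.names = FALSE)))
  } else NULL
  pairs <- if (length(pair_rows)) {
    do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  } else NULL
  report <- list(period_metrics = period_metrics, variability = variability,
                 excursions = excursions, alignment = alignment,
                 pairs = pairs, failures = failures)
  report <- c(report, cohort_stats(period_metrics, pairs, design))
  report$log <- c(log_lines,
                  sprintf("animals analysed: %d, failed: %d",
                          length(per_rows), length(failures)))
  class(report) <- "glyco_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# per-animal stage: repair -> smooth -> windows -> baseline -> excursions
analyze_animal <- function(cgm, design, sg_window, sg_order, conga_hours,
                           eug, diet_of_day) {
  repaired <- repair_missing(cgm)
  smoothed <- smooth_savgol(repaired, sg_window, sg_order)
  win <- resolve_windows(design, smoothed$times[1],
                         smoothed$times[length(smoothed)])
  nights <- win[win$period == "night", , drop = FALSE]
  per <- list(); vr <- list(); ex <- list()
  for (i in seq_len(nrow(win))) {
    w <- win[i, ]
    ref <- if (w$period == "night") {
      w
    } else {
      nights[nights$day == w$day - 1L, , drop = FALSE]
    }
    if (!nrow(ref)) next  # no preceding night: baseline undefined
    band <- tryCatch(compute_baseline(smoothed, ref$start, ref$end),
                     error = function(e) NULL)
    if (is.null(band)) next
    e <- detect_excursions(smoothed, band, w$start, w$end)
    s <- summarize_period(e, smoothed, band, w$start, w$end,
                          period = w$period)
    s <- cbind(data.frame(animal_id = cgm$animal_id, day = w$day,
                          diet = diet_of_day(w$day)), s)
    s$baseline_mean <- band$mean; s$baseline_sd <- band$sd
    per[[i]] <- s
    wtrace <- trace_window(repaired, w$start, w$end)
    v <- tryCatch(
      variability_metrics(wtrace, conga_hours = conga_hours, range = eug),
      error = function(e) NULL)
    if (!is.null(v)) {
      vr[[i]] <- cbind(data.frame(animal_id = cgm$animal_id, day = w$day,
                                  period = w$period,
                                  diet = diet_of_day(w$day)), v)
    }
    if (nrow(e)) {
      ex[[i]] <- cbind(data.frame(animal_id = cgm$animal_id, day = w$day,
                                  period = w$period), e)
    }
  }
  if (!length(per)) stop("no analysable window (trace too short?)")
  list(
    smoothed = smoothed,
    period_metrics = do.call(rbind, per),
    variability = if (length(vr)) do.call(rbind, vr) else NULL,
    excursions = if (length(ex)) do.call(rbind, ex) else empty_excursions()
  )
}

# lag + agreement for one animal x meal-test day
align_animal_day <- function(smoothed, samples, design, day, max_lag) {
  pw <- clock_minutes(design$postprandial_window)
  day0 <- as.POSIXct(format(smoothed$times[1], "%Y-%m-%d"),
                     tz = attr(smoothed$times, "tzone"))
  w_start <- day0 + ((day - 1) * 1440 + pw[1]) * 60
  w_end <- day0 + ((day - 1) * 1440 + pw[2]) * 60
  cgm_w <- trace_window(smoothed, w_start, w_end)
  blood_eq <- plasma_to_blood(samples$plasma_glucose, samples$hematocrit)
  blood_tr <- glucose_trace(samples$times, blood_eq,
                            animal_id = samples$animal_id,
                            missing = rep(FALSE, length(samples$times)),
                            source = "repaired")
  cgm_1 <- resample_minutely(cgm_w)
  blood_1 <- resample_minutely(blood_tr)
  al <- estimate_lag(cgm_1, blood_1, max_lag = max_lag)
  # pair the shifted CGM with blood at the scheduled draw times
  shifted <- al$shifted_trace
  idx <- vapply(samples$times, function(tt) {
    which.min(abs(as.numeric(shifted$times - tt, units = "mins")))
  }, integer(1))
  pairs <- data.frame(animal_id = samples$animal_id, day = day,
                      time = samples$times,
                      cgm = shifted$glucose[idx], blood = blood_eq)
  ba <- bland_altman(pairs$cgm, pairs$blood)
  list(
    summary = data.frame(animal_id = samples$animal_id, day = day,
                         lag_min = al$lag,
                         peak_correlation = al$peak_correlation,
                         bias = ba$bias, loa_lower = ba$loa_lower,
                         loa_upper = ba$loa_upper, n_pairs = ba$n_pairs),
    pairs = pairs
  )
}

# cohort-level statistics over the per-period tables
cohort_stats <- function(pm, pairs, design) {
  out <- list(screens = NULL, night_day = NULL, rmcorr = NULL, pca = NULL,
              diet_tests = NULL)
  metric_cols <- c("n_peaks", "n_nadirs", "total_peak_duration",
                   "total_nadir_duration", "total_peak_auc",
                   "total_nadir_auc", "max_glucose", "min_glucose",
                   "sharpest_peak_duration", "sharpest_peak_auc",
                   "sharpest_nadir_duration", "sharpest_nadir_auc")
  # diet effect on postprandial metrics (meal-test days)
  pp <- pm[pm$period == "postprandial" & pm$day %in% design$meal_test_days, ,
           drop = FALSE]
  if (nrow(pp) && length(unique(pp$diet)) >= 2) {
    rows <- list()
    for (mcol in metric_cols) {
      v <- pp[[mcol]]
      ok <- is.finite(v)
      if (length(unique(pp$diet[ok])) < 2) next
      tab <- table(pp$diet[ok])
      if (any(tab < 2)) next
      a <- diet_anova(v[ok], pp$diet[ok])
      rows[[mcol]] <- data.frame(metric = mcol, F = a$F, p = a$p)
    }
    if (length(rows)) out$diet_tests <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  # night -> postprandial Spearman screen, per meal-test day (per diet)
  screens <- list()
  for (day in design$meal_test_days) {
    night <- pm[pm$period == "night" & pm$day == day - 1L, , drop = FALSE]
    post <- pm[pm$period == "postprandial" & pm$day == day, , drop = FALSE]
    if (nrow(night) >= 4 && nrow(post) >= 4) {
      sc <- tryCatch(
        suppressWarnings(spearman_screen(night[, c("animal_id", metric_cols)],
                                         post[, c("animal_id", metric_cols)])),
        error = function(e) NULL)
      if (!is.null(sc) && nrow(sc)) {
        sc$diet <- unique(post$diet)[1]; sc$day <- day
        screens[[as.character(day)]] <- sc
      }
    }
  }
  if (length(screens)) out$screens <- do.call(rbind, c(screens, list(make.row.names = FALSE)))
  # night vs day comparison (means by ANOVA, variances by F-test)
  nd <- pm[pm$period %in% c("night", "day"), , drop = FALSE]
  if (nrow(nd)) {
    # the free-feeding day: the first non-meal-test day with a preceding night
    free_days <- setdiff(unique(nd$day[nd$period == "day"]),
                         design$meal_test_days)
    fd <- free_days[free_days - 1L %in% nd$day[nd$period == "night"]]
    if (length(fd)) {
      fd <- fd[1]
      sub <- rbind(nd[nd$period == "night" & nd$day == fd - 1L, ],
                   nd[nd$period == "day" & nd$day == fd, ])
      rows <- list()
      for (mcol in metric_cols) {
        v <- sub[[mcol]]; g <- sub$period
        ok <- is.finite(v)
        if (length(unique(g[ok])) < 2 || any(table(g[ok]) < 2)) next
        a <- diet_anova(v[ok], g[ok])
        f <- tryCatch(variance_f_test(v[ok & g == "night"], v[ok & g == "day"]),
                      error = function(e) list(F = NA_real_, p = NA_real_))
        rows[[mcol]] <- data.frame(
          metric = mcol, day = fd,
          mean_night = mean(v[ok & g == "night"]),
          mean_day = mean(v[ok & g == "day"]),
          anova_p = a$p, f_ratio = f$F, f_p = f$p)
      }
      if (length(rows)) {
        out$night_day <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
        # PCA over the night and day metric rows of the free-feeding pair
        pca_in <- sub[, metric_cols, drop = FALSE]
        keep <- vapply(pca_in, function(x) all(is.finite(x)) &&
                         stats::sd(x) > 0, logical(1))
        if (sum(keep) >= 2 && nrow(pca_in) >= 3) {
          out$pca <- pca_metrics(pca_in[, keep, drop = FALSE])
        }
      }
    }
  }
  # repeated-measures CGM/blood correlation per diet
  if (!is.null(pairs) && nrow(pairs)) {
    rows <- list()
    for (diet in unique(pairs$diet)) {
      sub <- pairs[pairs$diet == diet, , drop = FALSE]
      if (length(unique(sub$animal_id)) >= 2) {
        rc <- tryCatch(rm_correlation(sub$cgm, sub$blood, sub$animal_id),
                       error = function(e) NULL)
        if (!is.null(rc)) {
          rows[[diet]] <- data.frame(diet = diet, r = rc$r, df = rc$df,
                                     p = rc$p, n_obs = rc$n_obs,
                                     n_subjects = rc$n_subjects)
        }
      }
    }
    if (length(rows)) out$rmcorr <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' @export
print.glyco_report <- function(x, ...) {
  cat("<glyco_report>\n")
  cat(sprintf("  animals: %d | period rows: %d | excursions: %d\n",
              length(unique(x$period_metrics$animal_id)),
              nrow(x$period_metrics), nrow(x$excursions)))
  if (!is.null(x$alignment)) {
    cat(sprintf("  mean lag: %.1f min | mean bias: %.1f mg/dL\n",
                mean(x$alignment$lag_min), mean(x$alignment$bias)))
  }
  if (length(x$failures)) {
    cat(sprintf("  failed animals: %s\n", paste(x$failures, collapse = ", ")))
  }
  invisible(x)
}

# write tidy CSV reports + run log; fixed column order and full precision
# so reruns are byte-identical
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible())
    for (cl in names(df)) {
      if (inherits(df[[cl]], "POSIXct")) {
        df[[cl]] <- format(df[[cl]], "%Y-%m-%d %H:%M:%S")
      }
    }
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(report$period_metrics, "period_metrics.csv")
  wr(report$variability, "variability.csv")
  wr(report$excursions, "excursions.csv")
  wr(report$alignment, "alignment.csv")
  wr(report$pairs, "pairs.csv")
  wr(report$screens, "spearman_screen.csv")
  wr(report$night_day, "night_day.csv")
  wr(report$diet_tests, "diet_tests.csv")
  wr(report$rmcorr, "rmcorr.csv")
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
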