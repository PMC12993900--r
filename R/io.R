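#' Read a CGM trace from CSV
#'
#' The canonical dialect is comma-separated with header
#' `timestamp,glucose_mg_dl` and ISO-8601 timestamps
#' (`YYYY-MM-DD HH:MM:SS`, optionally with a `T` separator). The reader is
#' permissive about the column names actually used by receiver exports:
#' the timestamp column may be named `timestamp`, `time` or `datetime`,
#' and the glucose column anything starting with `glucose`. Readings the
#' receiver flagged off-scale are serialized as the literal string `NaN`
#' (or `NA`, or an empty field) and come back with `missing = TRUE`.
#'
#' @param path CSV file path.
#' @param animal_id animal identifier to stamp on the trace; defaults to
#'   the file name without extension.
#' @param unit `"mg/dl"` (default) or `"mmol/l"`; the latter is converted
#'   at the boundary with the factor 18.016.
#' @param tz timezone used to parse timestamps (default `"UTC"`).
#' @return a [glucose_trace()], sorted by time.
#' @export
read_cgm_csv <- function(path, animal_id = NULL, unit = c("mg/dl", "mmol/l"),
                         tz = "UTC") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop(sprintf("empty CGM file: %s", path), call. = FALSE)
  tcol <- intersect(c("timestamp", "time", "datetime"), names(df))
  gcol <- grep("^glucose", names(df), value = TRUE)
  if (!length(tcol) || !length(gcol)) {
    stop("CGM CSV needs a timestamp column (timestamp/time/datetime) and a glucose* column",
         call. = FALSE)
  }
  times <- parse_iso_times(df[[tcol[1]]], tz)
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop(sprintf("unparseable timestamp at row %d: '%s'", bad, df[[tcol[1]]][bad]),
         call. = FALSE)
  }
  if (anyDuplicated(times)) {
    stop(sprintf("duplicate timestamp at row %d", anyDuplicated(times)),
         call. = FALSE)
  }
  graw <- trimws(df[[gcol[1]]])
  miss <- graw == "" | toupper(graw) %in% c("NAN", "NA")
  glucose <- suppressWarnings(as.numeric(graw))
  glucose[miss] <- NA_real_
  unparsed <- !miss & is.na(glucose)
  if (any(unparsed)) {
    stop(sprintf("unparseable glucose value at row %d: '%s'",
                 which(unparsed)[1], graw[which(unparsed)[1]]), call. = FALSE)
  }
  if (unit == "mmol/l") glucose <- glucose * 18.016
  o <- order(times)
  if (is.null(animal_id)) {
    animal_id <- tools::file_path_sans_ext(basename(path))
  }
  glucose_trace(times[o], glucose[o], animal_id = animal_id,
                missing = miss[o], source = "raw")
}

#' Write a CGM trace to CSV
#'
#' Serializes in the canonical dialect (`timestamp,glucose_mg_dl`,
#' ISO-8601 timestamps); missing points are written as the literal `NaN`,
#' matching the receiver convention. Values are printed with enough digits
#' that [read_cgm_csv()] inverts the write exactly.
#'
#' @param trace a [glucose_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(trace, path) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- ifelse(trace$missing, "NaN",
              format(trace$glucose, digits = 15, trim = TRUE,
                     scientific = FALSE))
  df <- data.frame(
    timestamp = format(trace$times, "%Y-%m-%d %H:%M:%S"),
    glucose_mg_dl = g
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a sparse blood-sample table
#'
#' Expects columns `animal_id`, `time` (ISO-8601), `plasma_glucose`
#' (mg/dL) and `hematocrit` (fraction). One animal per file; the series
#' comes back with `medium = "plasma"`.
#'
#' @param path CSV file path.
#' @param tz timezone for timestamps (default `"UTC"`).
#' @return a [blood_samples()] series.
#' @export
read_blood_samples <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time", "plasma_glucose", "hematocrit")
  if (!all(need %in% names(df))) {
    stop(sprintf("blood-sample CSV needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty blood-sample file", call. = FALSE)
  times <- parse_iso_times(df$time, tz)
  if (anyNA(times)) {
    stop(sprintf("unparseable time at row %d", which(is.na(times))[1]),
         call. = FALSE)
  }
  hct <- unique(df$hematocrit)
  if (length(hct) > 1) stop("hematocrit must be constant within one animal's file",
                            call. = FALSE)
  if (!is.finite(hct) || hct <= 0 || hct >= 1) {
    stop(sprintf("hematocrit %.3g outside (0, 1)", hct), call. = FALSE)
  }
  if (any(df$plasma_glucose <= 0)) {
    stop("plasma_glucose must be > 0", call. = FALSE)
  }
  o <- order(times)
  blood_samples(times[o], df$plasma_glucose[o], hematocrit = hct,
                animal_id = df$animal_id[1], medium = "plasma")
}

#' Write a blood-sample series to CSV
#' @param samples a [blood_samples()] series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blood_samples <- function(samples, path) {
  stopifnot(inherits(samples, "blood_samples"))
  df <- data.frame(
    animal_id = samples$animal_id,
    time = format(samples$times, "%Y-%m-%d %H:%M:%S"),
    plasma_glucose = format(samples$plasma_glucose, digits = 15, trim = TRUE,
                            scientific = FALSE),
    hematocrit = samples$hematocrit
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study design: analysis windows, meals, diets, euglycemic range
#'
#' Defaults follow the study protocol this package models: lights-off
#' night from 21:00 to 06:55, diurnal period 07:00 to 20:55, postprandial
#' window 08:45 (first blood draw, 15 min before the test meal at 09:00)
#' to 13:00, meals at 08:30 and 16:00, a 5-day high-starch to high-fat
#' crossover, and the 70-180 mg/dL euglycemic range.
#'
#' @param night_window,day_window,postprandial_window length-2 character
#'   vectors of clock times `"HH:MM"`. The night window wraps midnight.
#' @param meal_times clock times of daily meals.
#' @param test_meal_time clock time of the calibrated test meal on meal
#'   test days.
#' @param diet_sequence data.frame with columns `day`, `diet`,
#'   `hs_fraction` (fraction of the high-starch formula in the mix).
#' @param meal_test_days integer days of the trial on which a test meal +
#'   serial blood sampling happen.
#' @param euglycemic_range `c(lo, hi)` mg/dL.
#' @return an object of class `study_design`.
#' @export
study_design <- function(night_window = c("21:00", "06:55"),
                         day_window = c("07:00", "20:55"),
                         postprandial_window = c("08:45", "13:00"),
                         meal_times = c("08:30", "16:00"),
                         test_meal_time = "09:00",
                         diet_sequence = default_diet_sequence(),
                         meal_test_days = c(2L, 5L),
                         euglycemic_range = c(70, 180)) {
  stopifnot(length(night_window) == 2, length(day_window) == 2,
            length(postprandial_window) == 2)
  if (euglycemic_range[1] >= euglycemic_range[2]) {
    stop("euglycemic_range must satisfy lo < hi", call. = FALSE)
  }
  # day and night must not overlap within the 24-h cycle
  dw <- clock_minutes(day_window); nw <- clock_minutes(night_window)
  in_day <- function(m) m >= dw[1] & m <= dw[2]
  if (in_day(nw[1]) || in_day(nw[2])) {
    stop("night and day windows overlap", call. = FALSE)
  }
  structure(
    list(night_window = night_window,
         day_window = day_window,
         postprandial_window = postprandial_window,
         meal_times = meal_times,
         test_meal_time = test_meal_time,
         diet_sequence = diet_sequence,
         meal_test_days = as.integer(meal_test_days),
         euglycemic_range = as.numeric(euglycemic_range)),
    class = "study_design"
  )
}

#' Default 5-day high-starch to high-fat diet sequence
#'
#' Day 1-2 pure high starch (HS), then 75/25, 50/50 mixes, day 5 pure
#' high fat (HF). `hs_fraction` is the proportion of the HS formula.
#' @return data.frame with columns `day`, `diet`, `hs_fraction`.
#' @export
default_diet_sequence <- function() {
  data.frame(
    day = 1:5,
    diet = c("HS", "HS", "MIX75", "MIX50", "HF"),
    hs_fraction = c(1, 1, 0.75, 0.5, 0)
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  night %s-%s | day %s-%s | postprandial %s-%s\n",
              x$night_window[1], x$night_window[2],
              x$day_window[1], x$day_window[2],
              x$postprandial_window[1], x$postprandial_window[2]))
  cat(sprintf("  meals at %s | test meal %s on days %s\n",
              paste(x$meal_times, collapse = ", "), x$test_meal_time,
              paste(x$meal_test_days, collapse = ",")))
  cat(sprintf("  euglycemic range %g-%g mg/dL\n",
              x$euglycemic_range[1], x$euglycemic_range[2]))
  invisible(x)
}

#' Read a study design from a YAML (or JSON) config file
#'
#' Recognized keys mirror the arguments of [study_design()]; absent keys
#' fall back to the defaults. `diet_sequence` may be given as a list of
#' `{day, diet, hs_fraction}` records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [study_design()].
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (key in c("night_window", "day_window", "postprandial_window",
                "meal_times", "test_meal_time", "meal_test_days",
                "euglycemic_range")) {
    if (!is.null(cfg[[key]])) args[[key]] <- unlist(cfg[[key]])
  }
  if (!is.null(cfg$diet_sequence)) {
    ds <- cfg$diet_sequence
    if (!is.data.frame(ds)) ds <- do.call(rbind, lapply(ds, as.data.frame))
    args$diet_sequence <- ds
  }
  do.call(study_design, args)
}

# internal: lenient ISO-8601 parser returning NA (not an error) on
# unparseable entries so callers can name the offending row
parse_iso_times <- function(x, tz = "UTC") {
  raw <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(raw, "%Y-%m-%d %H:%M:%OS", tz = tz))
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(strptime(raw[retry], "%Y-%m-%d %H:%M", tz = tz))
  }
  out
}

# internal: "HH:MM" -> minutes after midnight
clock_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]),
         numeric(1))
}
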