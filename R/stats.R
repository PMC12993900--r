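#' Repeated-measures correlation
#'
#' Association between two variables measured repeatedly on the same
#' subjects, with between-subject offsets removed: both variables are
#' centered within subject, the centered values are pooled, and the
#' pooled Pearson correlation is reported with `df = n_obs - n_subjects -
#' 1` and a two-sided p-value from the t distribution. Subjects with
#' fewer than 2 complete pairs are dropped with a warning.
#'
#' @param x,y numeric vectors of paired observations.
#' @param subject subject label per observation.
#' @return list with `r`, `df`, `p`, `n_obs`, `n_subjects`.
#' @export
rm_correlation <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject)) {
    stop("`x`, `y`, `subject` must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; subject <- as.character(subject)[keep]
  counts <- table(subject)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("dropping %d subject(s) with < 2 observations: %s",
                    length(small), paste(small, collapse = ", ")))
    keep <- !(subject %in% small)
    x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  }
  subj <- unique(subject)
  if (length(subj) < 1 || length(x) < 3) {
    stop("need at least one subject with >= 2 observations and >= 3 observations total",
         call. = FALSE)
  }
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0) {
    stop("no within-subject variation in x or y", call. = FALSE)
  }
  r <- stats::cor(xc, yc)
  df <- length(x) - length(subj) - 1L
  if (df < 1) stop("non-positive degrees of freedom", call. = FALSE)
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r = r, df = df, p = min(p, 1), n_obs = length(x),
       n_subjects = length(subj))
}

#' Spearman screen: night metrics vs postprandial metrics
#'
#' Rank-correlates every night metric against every postprandial metric
#' across matched animals and flags each pair as `significant`
#' (p <= 0.05), `trend` (0.05 < p <= 0.10) or `ns`. This is a raw,
#' uncorrected screen (the convention of the exploratory analysis it
#' mirrors); set `adjust = "BH"` for Benjamini-Hochberg adjusted flags.
#'
#' @param night,post data.frames with an `animal_id` column plus numeric
#'   metric columns; rows are matched on `animal_id`.
#' @param metrics optional character vector restricting which metric
#'   columns are screened (default: all shared numeric columns).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `night_metric`, `post_metric`, `rho`,
#'   `p`, `flag`, sorted by p.
#' @export
spearman_screen <- function(night, post, metrics = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!"animal_id" %in% names(night) || !"animal_id" %in% names(post)) {
    stop("both tables need an `animal_id` column", call. = FALSE)
  }
  ids <- intersect(night$animal_id, post$animal_id)
  if (length(ids) < 4) stop("need >= 4 matched animals", call. = FALSE)
  night <- night[match(ids, night$animal_id), , drop = FALSE]
  post <- post[match(ids, post$animal_id), , drop = FALSE]
  numcols <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
  ncols <- setdiff(numcols(night), "day")
  pcols <- setdiff(numcols(post), "day")
  if (!is.null(metrics)) {
    ncols <- intersect(ncols, metrics)
    pcols <- intersect(pcols, metrics)
  }
  rows <- list()
  for (nm in ncols) {
    xv <- night[[nm]]
    if (all(!is.finite(xv)) || stats::sd(xv, na.rm = TRUE) == 0 ||
        is.na(stats::sd(xv, na.rm = TRUE))) {
      warning(sprintf("night metric '%s' constant or all-NA; skipped", nm))
      next
    }
    for (pm in pcols) {
      yv <- post[[pm]]
      ok <- is.finite(xv) & is.finite(yv)
      if (sum(ok) < 4) next
      if (stats::sd(yv[ok]) == 0) {
        warning(sprintf("postprandial metric '%s' constant; skipped", pm))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(xv[ok], yv[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        night_metric = nm, post_metric = pm,
        rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (!length(rows)) {
    return(data.frame(night_metric = character(), post_metric = character(),
                      rho = numeric(), p = numeric(), flag = character()))
  }
  out <- do.call(rbind, rows)
  pflag <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$flag <- ifelse(pflag <= 0.05, "significant",
                     ifelse(pflag <= 0.10, "trend", "ns"))
  out[order(out$p), , drop = FALSE]
}

#' One-way fixed-effects ANOVA
#'
#' Tests the effect of a single factor (e.g. diet composition, or period
#' night-vs-day) on a metric.
#'
#' @param values numeric response.
#' @param groups factor/labels, >= 2 levels with >= 2 observations each.
#' @return list with `F`, `df1`, `df2`, `p`, `group_means`.
#' @export
diet_anova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  tab <- table(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop(sprintf("every group needs n >= 2 (got: %s)",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")),
         call. = FALSE)
  }
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(tab * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ssw == 0) {
    # degenerate: no within-group variance
    Fstat <- if (ssb == 0) 0 else Inf
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
  }
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       group_means = gm)
}

#' Two-sided F-test comparing two variances
#'
#' `F = var(a) / var(b)` (sample variances) against the F distribution
#' with `(n_a - 1, n_b - 1)` degrees of freedom; used to compare the
#' inter-individual variability of a CGM metric between periods.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
variance_f_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in both samples",
                                           call. = FALSE)
  vb <- stats::var(b)
  if (vb == 0) stop("zero variance in `b`: F undefined", call. = FALSE)
  Fstat <- stats::var(a) / vb
  df1 <- length(a) - 1L; df2 <- length(b) - 1L
  pl <- stats::pf(Fstat, df1, df2)
  p <- 2 * min(pl, 1 - pl)
  list(F = Fstat, df1 = df1, df2 = df2, p = min(p, 1))
}

#' PCA overview of a metric table
#'
#' Columns are standardized to zero mean and unit sample standard
#' deviation, then decomposed by SVD (no rotation). Gives the global view
#' of the correlation structure between night and day excursion metrics.
#'
#' @param table data.frame or matrix; non-numeric columns are dropped,
#'   rows with missing cells are an error.
#' @return list with `scores`, `loadings`, `explained` (variance
#'   fractions, summing to 1), `sdev`.
#' @export
pca_metrics <- function(table) {
  df <- as.data.frame(table)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (nrow(num) < 3 || ncol(num) < 2) {
    stop("need >= 3 rows and >= 2 numeric metric columns", call. = FALSE)
  }
  if (anyNA(num)) stop("metric table has missing cells", call. = FALSE)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop(sprintf("constant column(s): %s",
                 paste(names(num)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  pc <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained = expl,
       sdev = pc$sdev)
}
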