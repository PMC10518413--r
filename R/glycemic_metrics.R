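#' Time in, above and below range
#'
#' Fractions of readings in the target range \[lo, hi\] (inclusive), strictly
#' above hi, and strictly below lo. The three fractions partition the sample
#' and sum to 1 exactly. Defaults are the consensus 70--180 mg/dL target.
#'
#' @param values Numeric glucose values (mg/dL).
#' @param lo,hi Range limits in mg/dL.
#' @return Named numeric vector `c(tir, tar, tbr)`.
#' @export
range_fractions <- function(values, lo = 70, hi = 180) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no valid glucose values", call. = FALSE)
  n_above <- sum(values > hi)
  n_below <- sum(values < lo)
  tar <- n_above / n
  # derive the last component so tir + tar + tbr sums to 1 exactly in
  # floating point (left-to-right); each value stays within 1 ulp of its
  # count ratio
  if (n_below == 0) {
    tbr <- 0
    tir <- 1 - tar
  } else {
    tir <- (n - n_above - n_below) / n
    tbr <- 1 - (tir + tar)
  }
  c(tir = tir, tar = tar, tbr = tbr)
}

#' Per-subject summary glycemic metrics
#'
#' Mean, SD, coefficient of variation (SD/mean) and range fractions over each
#' subject's valid readings.
#'
#' @param data A `cgm_df` tibble.
#' @param lo,hi Target-range limits in mg/dL.
#' @return Tibble with columns `subject_id`, `mean_glucose`, `sd_glucose`,
#'   `cv`, `tir`, `tar`, `tbr`, `n_valid`.
#' @export
summary_metrics <- function(data, lo = 70, hi = 180) {
  stopifnot_cgm(data)
  v <- only_valid(data)
  per <- split(v$glucose, v$subject_id)
  rows <- lapply(names(per), function(id) {
    g <- per[[id]]
    if (length(g) < 2) {
      stop("subject ", id, " has fewer than 2 valid records; SD undefined",
           call. = FALSE)
    }
    rf <- range_fractions(g, lo, hi)
    tibble::tibble(subject_id = id,
                   mean_glucose = mean(g), sd_glucose = sd(g),
                   cv = sd(g) / mean(g),
                   tir = rf[["tir"]], tar = rf[["tar"]], tbr = rf[["tbr"]],
                   n_valid = length(g))
  })
  dplyr::bind_rows(rows)
}

#' Daily time-in-range series
#'
#' One TIR value per UTC calendar day with at least one valid reading;
#' days without valid readings are omitted. `study_day` indexes days from
#' each subject's first observation day (day 0).
#'
#' @param data A `cgm_df` tibble.
#' @param lo,hi Target-range limits in mg/dL.
#' @return Tibble with columns `subject_id`, `study_day`, `date`, `tir`,
#'   `n_valid`.
#' @export
daily_tir_series <- function(data, lo = 70, hi = 180) {
  stopifnot_cgm(data)
  v <- only_valid(data)
  v$date <- utc_date(v$time)
  first_day <- dplyr::summarise(dplyr::group_by(v, .data$subject_id),
                                day0 = min(.data$date), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(v, .data$subject_id, .data$date),
    tir = range_fractions(.data$glucose, lo, hi)[["tir"]],
    n_valid = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::left_join(out, first_day, by = "subject_id")
  out$study_day <- as.integer(out$date - out$day0)
  out$day0 <- NULL
  dplyr::arrange(out[, c("subject_id", "study_day", "date", "tir", "n_valid")],
                 .data$subject_id, .data$study_day)
}

#' Ambulatory glucose profile of one subject
#'
#' Folds a subject's valid readings onto time of day and fits a smoothed mean
#' curve (local regression) with a pointwise standard-error band. The 24-h
#' seam is handled circularly by replicating the folded data shifted by
#' +/- 24 h and fitting on the padded window. Falls back to binned hourly
#' means (with a warning) when there are too few points for the smoother.
#'
#' @param data A `cgm_df` tibble containing exactly one subject.
#' @param n_grid Number of equally spaced time-of-day grid points in \[0, 24).
#' @param span Local-regression span (fraction of the padded data).
#' @return An object of class `agp_profile`: list with `subject_id`, `grid`
#'   (hours), `mean` (smoothed mg/dL), `se` (pointwise SE), and `raw`
#'   (tibble date/tod/glucose of the folded readings).
#' @export
agp_profile <- function(data, n_grid = 96, span = 0.3) {
  stopifnot_cgm(data)
  v <- only_valid(data)
  id <- unique(v$subject_id)
  if (length(id) != 1) {
    stop("agp_profile expects a single subject; got ", length(id), call. = FALSE)
  }
  tod <- time_of_day_hours(v$time)
  raw <- tibble::tibble(date = utc_date(v$time), tod = tod, glucose = v$glucose)
  grid <- seq(0, 24 - 24 / n_grid, length.out = n_grid)
  # circular padding: +/- 6 h around the midnight seam
  pad_lo <- tod >= 18
  pad_hi <- tod < 6
  x <- c(tod[pad_lo] - 24, tod, tod[pad_hi] + 24)
  y <- c(v$glucose[pad_lo], v$glucose, v$glucose[pad_hi])
  fit <- tryCatch(suppressWarnings(
    loess(y ~ x, span = span, degree = 2,
          control = stats::loess.control(surface = "interpolate"))),
    error = function(e) NULL)
  if (is.null(fit) || length(unique(x)) < 10) {
    warning("too few points for local regression; using binned hourly means",
            call. = FALSE)
    hour_means <- tapply(v$glucose, floor(tod), mean)
    mu <- approx(as.numeric(names(hour_means)) + 0.5, hour_means,
                 xout = grid, rule = 2)$y
    se <- rep(NA_real_, n_grid)
  } else {
    pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
    mu <- as.numeric(pr$fit)
    se <- as.numeric(pr$se.fit)
  }
  structure(list(subject_id = id, grid = grid, mean = mu, se = se, raw = raw),
            class = "agp_profile")
}

#' @export
print.agp_profile <- function(x, ...) {
  cat("<agp_profile>", x$subject_id, "-", nrow(x$raw), "readings,",
      length(x$grid), "grid points\n")
  invisible(x)
}

#' Subjects-by-hour mean glucose matrix
#'
#' Entry (i, h) is subject i's mean valid glucose over readings whose UTC
#' time of day falls in \[h, h+1). Hours without data are `NA`, never zero.
#' This is the matrix rendered by the lasagna plot.
#'
#' @param data A `cgm_df` tibble.
#' @return Numeric matrix, subjects in rows (rownames = subject IDs),
#'   24 hourly columns `"0"`..`"23"`.
#' @export
hourly_mean_matrix <- function(data) {
  stopifnot_cgm(data)
  v <- only_valid(data)
  v$hour <- floor(time_of_day_hours(v$time))
  ids <- unique(data$subject_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = 24,
              dimnames = list(ids, as.character(0:23)))
  agg <- dplyr::summarise(dplyr::group_by(v, .data$subject_id, .data$hour),
                          mg = mean(.data$glucose), .groups = "drop")
  m[cbind(match(agg$subject_id, ids), agg$hour + 1L)] <- agg$mg
  m
}
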