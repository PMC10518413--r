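#' Read raw CGM records from CSV
#'
#' Reads timestamped continuous glucose monitoring records in the common
#' long-format dialect: one row per reading with a subject identifier, a UTC
#' timestamp and a glucose value in mg/dL, plus an optional validity flag.
#' Rows are sorted by subject and time; duplicated (subject, timestamp) rows
#' are collapsed keep-first with a warning; rows with non-numeric glucose are
#' kept but flagged invalid.
#'
#' @param path CSV file with a header row, UTF-8.
#' @param column_map Named character vector mapping the canonical column
#'   names `subject_id`, `time`, `glucose` (and optionally `valid`) to the
#'   column names used in the file.
#' @return A tibble of class `cgm_df` with columns `subject_id` (character),
#'   `time` (POSIXct, UTC), `glucose` (double, mg/dL) and `valid` (logical).
#' @export
read_cgm_csv <- function(path,
                         column_map = c(subject_id = "subject_id",
                                        time = "time",
                                        glucose = "glucose_mg_dl",
                                        valid = "valid")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("subject_id", "time", "glucose")) {
    src <- unname(column_map[[col]])
    if (is.null(src) || !src %in% names(raw)) {
      stop("required column '", col, "' (file column '", src %||% col,
           "') not found in ", path, call. = FALSE)
    }
  }
  if (nrow(raw) == 0) {
    return(new_cgm_df(tibble::tibble(subject_id = character(),
                                     time = as.POSIXct(character(), tz = "UTC"),
                                     glucose = double(),
                                     valid = logical())))
  }
  time_chr <- raw[[column_map[["time"]]]]
  # Accept ISO 8601 with or without trailing " UTC" / "Z".
  time <- as.POSIXct(sub("\\s*(UTC|Z)\\s*$", "", time_chr),
                     tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  alt <- is.na(time)
  if (any(alt)) {
    time[alt] <- as.POSIXct(sub("\\s*(UTC|Z)\\s*$", "", time_chr[alt]),
                            tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    stop("unparseable timestamp at data row ", bad, ": '", time_chr[bad], "'",
         call. = FALSE)
  }
  glucose <- suppressWarnings(as.numeric(raw[[column_map[["glucose"]]]]))
  nonnum <- is.na(glucose) | !is.finite(glucose)
  if (any(nonnum)) {
    warning(sum(nonnum), " row(s) with non-numeric glucose flagged invalid",
            call. = FALSE)
  }
  valid <- rep(TRUE, nrow(raw))
  vcol <- column_map["valid"]
  if (!is.na(vcol) && vcol %in% names(raw)) {
    valid <- toupper(trimws(raw[[vcol]])) %in% c("TRUE", "T", "1", "YES")
  }
  out <- tibble::tibble(
    subject_id = as.character(raw[[column_map[["subject_id"]]]]),
    time = time,
    glucose = glucose,
    valid = valid & !nonnum
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$time)
  dup <- duplicated(out[, c("subject_id", "time")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (subject, timestamp) row(s) dropped (keep-first)",
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  new_cgm_df(out)
}

new_cgm_df <- function(data) {
  if (!inherits(data, "cgm_df")) class(data) <- c("cgm_df", class(data))
  data
}

#' Write CGM records back to CSV
#'
#' Inverse of [read_cgm_csv()]: writes the Table-1-style long format with
#' columns `subject_id`, `time` (ISO 8601 UTC) and `glucose_mg_dl`, plus the
#' `valid` flag.
#'
#' @param data A `cgm_df` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(data, path) {
  stopifnot_cgm(data)
  out <- tibble::tibble(
    subject_id = data$subject_id,
    time = format(data$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    glucose_mg_dl = data$glucose,
    valid = data$valid
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Flag sensor-implausible glucose values
#'
#' Marks records invalid when glucose falls outside the sensor-plausible
#' range. The default range 39--401 mg/dL corresponds to the reporting limits
#' of common CGM devices; device-error codes typically surface as values
#' outside it. Records already flagged invalid stay invalid.
#'
#' @param data A `cgm_df` tibble.
#' @param lo_plausible,hi_plausible Plausibility bounds in mg/dL.
#' @return The input with an updated `valid` column; the fraction of records
#'   flagged (by this call or before) is attached as attribute
#'   `flagged_fraction` and reported via `message()`.
#' @export
flag_invalid <- function(data, lo_plausible = 39, hi_plausible = 401) {
  stopifnot_cgm(data)
  if (!(lo_plausible < hi_plausible)) {
    stop("lo_plausible must be < hi_plausible", call. = FALSE)
  }
  out_of_range <- !is.finite(data$glucose) |
    data$glucose < lo_plausible | data$glucose > hi_plausible
  data$valid <- data$valid & !out_of_range
  frac <- if (nrow(data) > 0) mean(!data$valid) else 0
  attr(data, "flagged_fraction") <- frac
  message(sprintf("flagged %d of %d records (%.2f%%) as invalid",
                  sum(!data$valid), nrow(data), 100 * frac))
  data
}

#' Infer the sampling interval of each subject's series
#'
#' Returns the modal positive difference between consecutive timestamps,
#' per subject. Robust to occasional gaps: one long gap does not move the
#' mode of a regular 5-minute series.
#'
#' @param data A `cgm_df` tibble.
#' @return Tibble with columns `subject_id` and `interval_s` (seconds).
#' @export
infer_sampling_interval <- function(data) {
  stopifnot_cgm(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$subject_id),
    interval_s = modal_interval(.data$time),
    .groups = "drop"
  )
}

modal_interval <- function(time) {
  if (length(time) < 2) {
    stop("need at least 2 records to infer a sampling interval", call. = FALSE)
  }
  d <- diff(as.numeric(sort(time)))
  d <- d[d > 0]
  if (length(d) == 0) stop("no positive time differences", call. = FALSE)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])
}

#' Days with adequate CGM coverage
#'
#' Counts, per subject, the UTC calendar days whose number of valid readings
#' reaches `fraction` of the expected daily count implied by the subject's
#' inferred sampling interval (288 readings/day at 5 minutes). This follows
#' the consensus standard that roughly 70% of possible readings in a day are
#' needed to describe a daily profile.
#'
#' @param data A `cgm_df` tibble.
#' @param fraction Required fraction of expected daily readings, in (0, 1].
#' @return Tibble with columns `subject_id` and `coverage_days` (integer).
#' @export
coverage_days <- function(data, fraction = 0.7) {
  stopifnot_cgm(data)
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  ids <- unique(data$subject_id)
  res <- vapply(ids, function(id) {
    sub <- data[data$subject_id == id, , drop = FALSE]
    v <- sub[sub$valid & is.finite(sub$glucose), , drop = FALSE]
    if (nrow(v) == 0) return(0L)
    interval <- modal_interval(sub$time)
    expected <- 86400 / interval
    per_day <- table(utc_date(v$time))
    sum(per_day >= fraction * expected)
  }, integer(1))
  tibble::tibble(subject_id = ids, coverage_days = unname(res))
}

#' Observation span in days
#'
#' Time from each subject's first to last observation (valid or not),
#' in days; 0 for a single record.
#'
#' @param data A `cgm_df` tibble.
#' @return Tibble with columns `subject_id` and `span_days` (double).
#' @export
observation_span <- function(data) {
  stopifnot_cgm(data)
  if (nrow(data) == 0) stop("empty series", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(data, .data$subject_id),
    span_days = as.numeric(max(.data$time) - min(.data$time), units = "days"),
    .groups = "drop"
  )
}

#' Per-subject cohort summary
#'
#' One row per subject: observation span, coverage days at the given
#' fraction, and counts of valid and flagged records.
#'
#' @param data A `cgm_df` tibble.
#' @param fraction Coverage fraction passed to [coverage_days()].
#' @return Tibble with columns `subject_id`, `span_days`, `coverage_days`,
#'   `n_valid`, `n_flagged`.
#' @export
cohort_summary <- function(data, fraction = 0.7) {
  stopifnot_cgm(data)
  counts <- dplyr::summarise(
    dplyr::group_by(data, .data$subject_id),
    n_valid = sum(.data$valid & is.finite(.data$glucose)),
    n_flagged = dplyr::n() - .data$n_valid,
    .groups = "drop"
  )
  out <- dplyr::left_join(observation_span(data), counts, by = "subject_id")
  dplyr::left_join(out, coverage_days(data, fraction), by = "subject_id")[,
    c("subject_id", "span_days", "coverage_days", "n_valid", "n_flagged")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
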