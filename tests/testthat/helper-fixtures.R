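# Shared fixtures built in code.

# Six-row example file in the standard CGM CSV dialect: two subjects,
# three 5-minute readings each.
example_cgm_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "subject_id,time,glucose_mg_dl",
    "Subject 00000001,2022-01-01 10:55:00 UTC,155",
    "Subject 00000001,2022-01-01 11:00:00 UTC,147",
    "Subject 00000001,2022-01-01 11:05:00 UTC,138",
    "Subject 00000002,2022-05-01 15:55:00 UTC,89",
    "Subject 00000002,2022-05-01 16:00:00 UTC,97",
    "Subject 00000002,2022-05-01 16:05:00 UTC,98"
  ), path)
  path
}

# Build a cgm_df directly from vectors (defaults: one subject, 5-min grid).
make_series <- function(glucose, subject_id = "S1",
                        start = as.POSIXct("2022-01-01 00:00:00", tz = "UTC"),
                        interval_s = 300, valid = TRUE) {
  n <- length(glucose)
  glucodens:::new_cgm_df(tibble::tibble(
    subject_id = subject_id,
    time = start + seq(0, by = interval_s, length.out = n),
    glucose = glucose,
    valid = rep_len(valid, n)
  ))
}

# Small fast cohort for structural tests.
small_cohort_config <- function(seed = 1, n_subjects = 9,
                                followup_days = c(3, 6), ...) {
  cohort_config(n_subjects = n_subjects,
                class_probs = c(green = 1, blue = 1, red = 1) / 3,
                followup_days = followup_days, seed = seed, ...)
}

quiet_flag <- function(...) suppressMessages(flag_invalid(...))
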