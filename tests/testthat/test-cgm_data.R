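test_that("reading the six-row example file yields two ordered subjects", {
  data <- read_cgm_csv(example_cgm_csv())
  expect_s3_class(data, "cgm_df")
  expect_equal(unname(table(data$subject_id)),
               c(3L, 3L), ignore_attr = TRUE)
  expect_equal(data$glucose[data$subject_id == "Subject 00000001"],
               c(155, 147, 138))
  gaps <- diff(as.numeric(data$time[data$subject_id == "Subject 00000002"]))
  expect_true(all(gaps == 300))
  expect_true(all(data$valid))
})

test_that("a header-only file gives an empty cohort without error", {
  path <- tempfile(fileext = ".csv")
  writeLines("subject_id,time,glucose_mg_dl", path)
  data <- read_cgm_csv(path)
  expect_equal(nrow(data), 0)
  expect_s3_class(data, "cgm_df")
})

test_that("duplicate timestamps collapse keep-first with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,glucose_mg_dl",
               "A,2022-01-01 10:00:00,100",
               "A,2022-01-01 10:00:00,200",
               "A,2022-01-01 10:05:00,110"), path)
  expect_warning(data <- read_cgm_csv(path), "duplicate")
  expect_equal(nrow(data), 2)
  expect_equal(data$glucose, c(100, 110))  # keep-first
})

test_that("bad inputs are reported usefully", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,glucose_mg_dl",
               "A,not-a-time,100"), path)
  expect_error(read_cgm_csv(path), "unparseable timestamp at data row 1")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,glucose_mg_dl",
               "A,2022-01-01 10:00:00,oops",
               "A,2022-01-01 10:05:00,110"), path2)
  expect_warning(data <- read_cgm_csv(path2), "non-numeric glucose")
  expect_equal(data$valid, c(FALSE, TRUE))

  expect_error(read_cgm_csv(tempfile()), "not found")
})

test_that("plausibility flagging respects the configured bounds", {
  s <- make_series(c(155, 147, 138))
  expect_message(out <- flag_invalid(s, 39, 401), "flagged 0 of 3")
  expect_true(all(out$valid))

  s2 <- make_series(c(20, 150, 450))
  out2 <- quiet_flag(s2, 39, 401)
  expect_equal(out2$valid, c(FALSE, TRUE, FALSE))
  expect_equal(attr(out2, "flagged_fraction"), 2 / 3)

  expect_error(flag_invalid(s, 401, 39), "lo_plausible")

  all_bad <- quiet_flag(make_series(c(10, 20)), 39, 401)
  expect_error(summary_metrics(all_bad), "no valid data")
})

test_that("sampling interval is the modal consecutive difference", {
  expect_equal(infer_sampling_interval(make_series(c(1, 2, 3) + 100))$interval_s,
               300)
  # 60 s spacing with one 3600 s gap keeps the 60 s mode
  t0 <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC")
  times <- c(t0 + seq(0, 540, 60), t0 + 600 + 3600 + seq(0, 540, 60))
  s <- glucodens:::new_cgm_df(tibble::tibble(
    subject_id = "A", time = times, glucose = 100, valid = TRUE))
  expect_equal(infer_sampling_interval(s)$interval_s, 60)
  expect_equal(infer_sampling_interval(make_series(c(100, 110)))$interval_s, 300)
  expect_error(infer_sampling_interval(make_series(100)), "at least 2")
})

test_that("coverage counts days meeting the 70% standard", {
  expect_equal(coverage_days(make_series(rep(100, 288)))$coverage_days, 1L)
  expect_equal(coverage_days(make_series(rep(100, 200)))$coverage_days, 0L)
  expect_equal(coverage_days(make_series(rep(100, 202)))$coverage_days, 1L)
  expect_error(coverage_days(make_series(rep(100, 10)), fraction = 0),
               "fraction")
  expect_error(coverage_days(make_series(rep(100, 10)), fraction = 1.2),
               "fraction")
  # all records invalid -> zero days
  s <- make_series(rep(100, 288), valid = FALSE)
  expect_equal(coverage_days(s)$coverage_days, 0L)
})

test_that("coverage is monotone in valid records and in the fraction", {
  base <- make_series(rep(100, 3 * 288))
  for (n_bad in c(0, 100, 300, 500)) {
    v1 <- base; if (n_bad > 0) v1$valid[seq_len(n_bad)] <- FALSE
    v2 <- base; if (n_bad > 0) v2$valid[seq_len(min(n_bad + 100, 864))] <- FALSE
    expect_gte(coverage_days(v1)$coverage_days,
               coverage_days(v2)$coverage_days)
  }
  for (f in c(0.3, 0.5, 0.7, 0.9, 1)) {
    expect_gte(coverage_days(base, 0.2)$coverage_days,
               coverage_days(base, f)$coverage_days)
  }
})

test_that("observation span is last minus first in days", {
  s48 <- make_series(rep(100, 2), interval_s = 48 * 3600)
  expect_equal(observation_span(s48)$span_days, 2)
  expect_equal(observation_span(make_series(100))$span_days, 0)
  t1 <- read_cgm_csv(example_cgm_csv())
  expect_equal(observation_span(t1)$span_days, rep(10 / 1440, 2))
})

test_that("write/read round-trips valid rows bit-identically", {
  data <- read_cgm_csv(example_cgm_csv())
  path <- tempfile(fileext = ".csv")
  write_cgm_csv(data, path)
  back <- read_cgm_csv(path, column_map = c(subject_id = "subject_id",
                                            time = "time",
                                            glucose = "glucose_mg_dl",
                                            valid = "valid"))
  expect_identical(back$subject_id, data$subject_id)
  expect_identical(back$time, data$time)
  expect_identical(back$glucose, data$glucose)
  expect_identical(back$valid, data$valid)
})

test_that("cohort summary partitions records into valid and flagged", {
  coh <- simulate_cohort(small_cohort_config(seed = 3))
  rec <- quiet_flag(coh$records)
  smry <- cohort_summary(rec)
  expect_equal(nrow(smry), 9)
  expect_equal(smry$n_valid + smry$n_flagged,
               as.integer(table(rec$subject_id)[smry$subject_id]),
               ignore_attr = TRUE)
  expect_true(all(smry$coverage_days <= ceiling(smry$span_days) + 1))
})
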