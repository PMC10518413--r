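#' Parameters of one latent glycemic phenotype class
#'
#' A class bundles the generator settings for one glycemic phenotype:
#' baseline glucose, circadian swing, postprandial excursions, sensor-scale
#' noise with short-range autocorrelation, and the class-linked baseline
#' C-peptide distribution (lognormal, nmol/L).
#'
#' @param name Class label.
#' @param baseline Baseline (pre-circadian, pre-meal) mean glucose, mg/dL.
#' @param amplitude Circadian sine amplitude, mg/dL.
#' @param meal_peak Mean peak height of a meal excursion, mg/dL.
#' @param meal_halflife_min Exponential decay half-life of an excursion, min.
#' @param noise_sd Marginal SD of the AR(1) sensor/physiology noise, mg/dL.
#' @param ar1 AR(1) coefficient of the noise, in \[0, 1).
#' @param cpep_meanlog,cpep_sdlog Lognormal parameters of baseline C-peptide.
#' @return Object of class `class_params` (a validated list).
#' @export
class_params <- function(name, baseline, amplitude = 0, meal_peak = 0,
                         meal_halflife_min = 60, noise_sd = 0, ar1 = 0,
                         cpep_meanlog = log(0.6), cpep_sdlog = 0.35) {
  stopifnot(baseline > 0, amplitude >= 0, meal_peak >= 0,
            meal_halflife_min > 0, noise_sd >= 0, ar1 >= 0, ar1 < 1,
            cpep_sdlog >= 0)
  structure(list(name = name, baseline = baseline, amplitude = amplitude,
                 meal_peak = meal_peak, meal_halflife_min = meal_halflife_min,
                 noise_sd = noise_sd, ar1 = ar1,
                 cpep_meanlog = cpep_meanlog, cpep_sdlog = cpep_sdlog),
            class = "class_params")
}

#' Default three-phenotype configuration
#'
#' Mirrors the qualitative structure of a recent-onset type 1 diabetes
#' cohort: a well-controlled class (lowest, least variable glucose, highest
#' residual C-peptide), an intermediate class, and a poorly controlled class
#' (highest, most variable glucose, lowest C-peptide). Class means are
#' 110/150/200 mg/dL with overall within-subject SDs of roughly 25/35/50.
#'
#' @return Named list of three `class_params` (`green`, `blue`, `red`).
#' @export
default_classes <- function() {
  list(
    green = class_params("green", baseline = 110, amplitude = 15,
                         meal_peak = 35, meal_halflife_min = 45,
                         noise_sd = 20, ar1 = 0.8,
                         cpep_meanlog = log(0.90), cpep_sdlog = 0.35),
    blue = class_params("blue", baseline = 150, amplitude = 20,
                        meal_peak = 60, meal_halflife_min = 60,
                        noise_sd = 28, ar1 = 0.8,
                        cpep_meanlog = log(0.55), cpep_sdlog = 0.35),
    red = class_params("red", baseline = 200, amplitude = 28,
                       meal_peak = 90, meal_halflife_min = 60,
                       noise_sd = 40, ar1 = 0.8,
                       cpep_meanlog = log(0.30), cpep_sdlog = 0.40)
  )
}

#' Cohort-level generator configuration
#'
#' @param n_subjects Number of subjects.
#' @param class_probs Class membership proportions (named like `classes`,
#'   summing to 1). Class counts are the largest-remainder rounding of
#'   `n_subjects * class_probs`, so every class is represented.
#' @param classes Named list of `class_params`.
#' @param interval_s Sampling interval in seconds (300 = 5 minutes).
#' @param followup_days Integer range `c(min, max)` of per-subject follow-up.
#' @param gap_prob Per-day probability of a contiguous wear gap.
#' @param gap_hours Range `c(min, max)` of gap length in hours.
#' @param day_drop_prob Per-day probability the whole day is missing.
#' @param error_rate Per-record probability of an injected device-error
#'   value (implausible reading, flagged invalid); at most 0.05.
#' @param subject_sd Between-subject SD of the baseline within a class,
#'   mg/dL.
#' @param seed Root seed; all cohort randomness derives from it.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 30,
                          class_probs = c(green = 13, blue = 11, red = 6) / 30,
                          classes = default_classes(),
                          interval_s = 300,
                          followup_days = c(7, 28),
                          gap_prob = 0.15,
                          gap_hours = c(2, 12),
                          day_drop_prob = 0.05,
                          error_rate = 0.03,
                          subject_sd = 8,
                          seed = 1) {
  stopifnot(n_subjects >= 1, interval_s > 0,
            abs(sum(class_probs) - 1) < 1e-12,
            length(class_probs) == length(classes),
            all(names(class_probs) %in% names(classes)),
            followup_days[1] >= 1, followup_days[2] >= followup_days[1],
            gap_prob >= 0, gap_prob <= 1,
            error_rate >= 0, error_rate <= 0.05,
            subject_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 class_probs = class_probs, classes = classes,
                 interval_s = interval_s, followup_days = followup_days,
                 gap_prob = gap_prob, gap_hours = gap_hours,
                 day_drop_prob = day_drop_prob, error_rate = error_rate,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one subject's CGM series
#'
#' Glucose at time t is
#' `baseline + amplitude * sin(2*pi*(hour - 8)/24)` plus meal excursions
#' (three daily meals near 07:30, 12:30 and 18:30, jittered by +/- 45 min,
#' lognormal peak heights, exponential decay) plus AR(1) Gaussian noise with
#' the stated marginal SD. Values are clipped to the sensor range
#' \[40, 400\] mg/dL. Deterministic given `seed`.
#'
#' @param params A `class_params` object.
#' @param days Number of wear days (>= 1).
#' @param interval_s Sampling interval, seconds.
#' @param seed Integer seed.
#' @param subject_id Subject label for the output tibble.
#' @param start Wear start (POSIXct, UTC midnight by default).
#' @param baseline_shift Additive subject-level baseline offset, mg/dL.
#' @param meals Set to `FALSE` to suppress meal excursions.
#' @return A `cgm_df` tibble (all records valid).
#' @export
simulate_subject <- function(params, days, interval_s = 300, seed = 1,
                             subject_id = "S1",
                             start = as.POSIXct("2022-01-01 00:00:00",
                                                tz = "UTC"),
                             baseline_shift = 0, meals = TRUE) {
  stopifnot(inherits(params, "class_params"), days >= 1, interval_s > 0)
  n <- as.integer(days * 86400 / interval_s)
  tsec <- seq(0, by = interval_s, length.out = n)
  time <- start + tsec
  hour <- time_of_day_hours(time)
  g <- params$baseline + baseline_shift +
    params$amplitude * sin(2 * pi * (hour - 8) / 24)
  with_seed(seed, {
    if (meals && params$meal_peak > 0) {
      meal_hours <- c(7.5, 12.5, 18.5)
      for (d in seq_len(ceiling(days))) {
        for (mh in meal_hours) {
          tm <- ((d - 1) * 24 + mh + runif(1, -0.75, 0.75)) * 3600
          peak <- rlnorm(1, meanlog = log(params$meal_peak) - 0.5 * 0.25^2,
                         sdlog = 0.25)
          after <- tsec >= tm
          g[after] <- g[after] +
            peak * 2^(-(tsec[after] - tm) / 60 / params$meal_halflife_min)
        }
      }
    }
    if (params$noise_sd > 0) {
      innov_sd <- params$noise_sd * sqrt(1 - params$ar1^2)
      e <- rnorm(n, 0, innov_sd)
      # stationary start so the marginal SD is noise_sd from the first sample
      noise <- as.numeric(stats::filter(e, params$ar1, method = "recursive",
                                        init = rnorm(1, 0, params$noise_sd)))
      g <- g + noise
    }
  })
  g <- pmin(pmax(g, 40), 400)
  new_cgm_df(tibble::tibble(subject_id = subject_id, time = time,
                            glucose = g, valid = TRUE))
}

#' Draw class-linked baseline C-peptide covariates
#'
#' @param class_names Character vector of class labels, one per subject.
#' @param classes Named list of `class_params`.
#' @param seed Integer seed.
#' @param subject_ids Subject labels.
#' @return Tibble with columns `subject_id`, `c_peptide` (nmol/L), `arm`
#'   (0/1, randomized 2:1 active:placebo).
#' @export
simulate_covariates <- function(class_names, classes, seed = 1,
                                subject_ids = paste0("S",
                                                     seq_along(class_names))) {
  with_seed(seed, {
    cpep <- vapply(class_names, function(cn) {
      p <- classes[[cn]]
      rlnorm(1, p$cpep_meanlog, p$cpep_sdlog)
    }, numeric(1))
    arm <- rbinom(length(class_names), 1, 2 / 3)
  })
  tibble::tibble(subject_id = subject_ids, c_peptide = unname(cpep), arm = arm)
}

#' Simulate a full CGM cohort with ground truth
#'
#' Draws class memberships, simulates each subject's series, injects wear
#' gaps, whole missing days and device-error records, and returns the
#' records together with a covariate table (class-linked C-peptide,
#' randomized arm) and a truth table for validation. Fully deterministic
#' given `config$seed`.
#'
#' Device errors are injected as implausible readings (below 39 or above
#' 401 mg/dL) carrying `valid = FALSE`, so they are caught both by the flag
#' column and by [flag_invalid()].
#'
#' @param config A `cohort_config`.
#' @return List with elements `records` (a `cgm_df`), `covariates` (tibble:
#'   `subject_id`, `c_peptide`, `arm`), and `truth` (tibble: `subject_id`,
#'   `class`, `true_mean`, `c_peptide`, `coverage_days` ground truth at the
#'   70% standard).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  counts <- largest_remainder(config$class_probs, n)
  seeds <- derive_seeds(config$seed, n + 2L)
  class_names <- with_seed(seeds[n + 1L],
                           sample(rep(names(counts), counts)))
  covars <- simulate_covariates(class_names, config$classes,
                                seed = seeds[n + 2L], subject_ids = ids)
  expected_per_day <- 86400 / config$interval_s
  rec_list <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- config$classes[[class_names[i]]]
    sub_seeds <- derive_seeds(seeds[i], 3L)
    aux <- with_seed(sub_seeds[1], list(
      days = sample(seq(config$followup_days[1], config$followup_days[2]), 1),
      bshift = rnorm(1, 0, config$subject_sd),
      start = as.POSIXct("2022-01-01 00:00:00", tz = "UTC") +
        sample(0:364, 1) * 86400
    ))
    ser <- simulate_subject(p, aux$days, config$interval_s,
                            seed = sub_seeds[2], subject_id = ids[i],
                            start = aux$start, baseline_shift = aux$bshift)
    ser <- with_seed(sub_seeds[3], inject_missingness(ser, config))
    per_day <- table(utc_date(ser$time[ser$valid]))
    truth_rows[[i]] <- tibble::tibble(
      subject_id = ids[i], class = class_names[i],
      true_mean = p$baseline + aux$bshift,
      c_peptide = covars$c_peptide[i],
      coverage_days = sum(per_day >= 0.7 * expected_per_day)
    )
    rec_list[[i]] <- ser
  }
  records <- new_cgm_df(dplyr::bind_rows(rec_list))
  list(records = records, covariates = covars,
       truth = dplyr::bind_rows(truth_rows))
}

largest_remainder <- function(probs, n) {
  raw <- probs * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    add <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[add] <- counts[add] + 1
  }
  stats::setNames(as.integer(counts), names(probs))
}

# wear gaps, whole missing days, and implausible device-error readings
inject_missingness <- function(ser, config) {
  days <- unique(utc_date(ser$time))
  drop <- rep(FALSE, nrow(ser))
  day_idx <- match(utc_date(ser$time), days)
  for (d in seq_along(days)) {
    if (runif(1) < config$day_drop_prob) {
      drop[day_idx == d] <- TRUE
    } else if (runif(1) < config$gap_prob) {
      len_h <- runif(1, config$gap_hours[1], config$gap_hours[2])
      start_h <- runif(1, 0, 24 - len_h)
      tod <- time_of_day_hours(ser$time)
      drop[day_idx == d & tod >= start_h & tod < start_h + len_h] <- TRUE
    }
  }
  ser <- ser[!drop, , drop = FALSE]
  if (config$error_rate > 0 && nrow(ser) > 0) {
    err <- runif(nrow(ser)) < config$error_rate
    if (any(err)) {
      low <- runif(sum(err)) < 0.5
      ser$glucose[err] <- ifelse(low, runif(sum(err), 5, 35),
                                 runif(sum(err), 420, 500))
      ser$valid[err] <- FALSE
    }
  }
  ser
}

#' Write a simulated cohort to CSV files
#'
#' Emits `cgm.csv` (Table-1 long dialect read back by [read_cgm_csv()]),
#' `covariates.csv` and `truth.csv` into `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cgm = file.path(dir, "cgm.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.csv"))
  write_cgm_csv(cohort$records, paths["cgm"])
  readr::write_csv(cohort$covariates, paths["covariates"], progress = FALSE)
  readr::write_csv(cohort$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
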