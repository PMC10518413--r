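#' @importFrom rlang .data
#' @importFrom stats approx loess lm median p.adjust pchisq pnorm predict
#'   quantile rnorm runif rlnorm rbinom sd t.test var wilcox.test kruskal.test
#'   coef complete.cases
#' @importFrom utils head modifyList
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds below 2^31, derived from one root seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_cgm <- function(data) {
  need <- c("subject_id", "time", "glucose", "valid")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("not a CGM cohort table; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

only_valid <- function(data) {
  out <- data[data$valid & is.finite(data$glucose), , drop = FALSE]
  if (nrow(out) == 0) stop("no valid data", call. = FALSE)
  out
}

utc_date <- function(time) as.Date(time, tz = "UTC")

# UTC clock time in decimal hours; epoch midnights are UTC midnights.
time_of_day_hours <- function(time) {
  (as.numeric(time) %% 86400) / 3600
}
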