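#' Silverman rule-of-thumb bandwidth
#'
#' `h = 0.9 * min(sd, IQR/1.34) * m^(-1/5)` in mg/dL. Errors when all values
#' are identical (both spread measures vanish); supply an explicit bandwidth
#' in that case.
#'
#' @param values Numeric glucose values (mg/dL), at least 2 distinct.
#' @return Positive bandwidth in mg/dL.
#' @export
silverman_bandwidth <- function(values) {
  values <- values[is.finite(values)]
  m <- length(values)
  if (m < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 7)))
  spread <- min(s, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) {
    stop("all values identical; supply an explicit bandwidth", call. = FALSE)
  }
  0.9 * spread * m^(-1 / 5)
}

#' Default glucose evaluation grid
#'
#' Uniform grid of `n_grid` points covering at least 40--400 mg/dL, extended
#' beyond the observed data range by `extend * h` on each side so the
#' Gaussian kernel mass is captured and the density integrates to 1.
#'
#' @param values Observed glucose values.
#' @param h Bandwidth (mg/dL).
#' @param n_grid Number of grid points.
#' @param extend Half-width of the extension in bandwidths.
#' @return Sorted uniform numeric grid.
#' @export
default_glucose_grid <- function(values, h, n_grid = 512, extend = 6) {
  lo <- min(40, min(values) - extend * h)
  hi <- max(400, max(values) + extend * h)
  seq(lo, hi, length.out = n_grid)
}

#' Estimate a glucodensity by kernel density estimation
#'
#' The glucodensity of a wear period is the probability density of the
#' glucose values observed during it. It is estimated with a Gaussian kernel:
#' `f_hat(s) = (1/m) * sum_i K_h(s - y_i)`, with
#' `K_h(u) = exp(-u^2 / (2 h^2)) / (h * sqrt(2 * pi))`,
#' evaluated on a uniform grid. No renormalization is applied; on the default
#' grid the trapezoid integral is 1 to within numerical tolerance.
#'
#' @param values Numeric glucose values (mg/dL).
#' @param h Bandwidth in mg/dL; default [silverman_bandwidth()].
#' @param grid Evaluation grid; default [default_glucose_grid()].
#' @return Object of class `glucodensity`: list with `grid`, `density`,
#'   `bandwidth`, `n`.
#' @export
estimate_glucodensity <- function(values, h = NULL, grid = NULL) {
  values <- values[is.finite(values)]
  m <- length(values)
  if (m == 0) stop("no values to estimate a density from", call. = FALSE)
  if (is.null(h)) h <- silverman_bandwidth(values)
  if (!(is.numeric(h) && h > 0)) stop("bandwidth must be positive", call. = FALSE)
  if (is.null(grid)) grid <- default_glucose_grid(values, h)
  dens <- numeric(length(grid))
  # chunk the kernel sum to bound memory on long wear periods
  idx <- split(seq_len(m), ceiling(seq_len(m) / 5000))
  for (ii in idx) {
    z <- outer(grid, values[ii], "-") / h
    dens <- dens + rowSums(exp(-0.5 * z * z))
  }
  dens <- dens / (m * h * sqrt(2 * pi))
  structure(list(grid = grid, density = dens, bandwidth = h, n = m),
            class = "glucodensity")
}

#' @export
print.glucodensity <- function(x, ...) {
  cat("<glucodensity> m =", x$n, " h =", signif(x$bandwidth, 4),
      "mg/dL, grid", length(x$grid), "points on [",
      round(min(x$grid)), ",", round(max(x$grid)), "]\n")
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Cumulative distribution function of a glucodensity
#'
#' Cumulative trapezoid integration of the density over its grid, clipped to
#' \[0, 1\] and normalized so the terminal value is exactly 1.
#'
#' @param gd A `glucodensity` object.
#' @return Object of class `gluco_cdf`: list with `grid` and `cdf`.
#' @export
density_to_cdf <- function(gd) {
  stopifnot(inherits(gd, "glucodensity"))
  x <- gd$grid
  y <- gd$density
  cdf <- c(0, cumsum(diff(x) * (head(y, -1) + y[-1]) / 2))
  if (cdf[length(cdf)] > 0) cdf <- cdf / cdf[length(cdf)]
  cdf <- pmin(pmax(cdf, 0), 1)
  structure(list(grid = x, cdf = cumnondec(cdf)), class = "gluco_cdf")
}

cumnondec <- function(x) cummax(x)

#' Default shared probability grid
#'
#' Uniform probabilities on which the whole cohort's quantile functions are
#' evaluated and on which Wasserstein distances are integrated.
#'
#' @param n Number of grid points.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
default_p_grid <- function(n = 999) seq(1, n, by = 1) / (n + 1)

#' Quantile function of a glucose sample or glucodensity
#'
#' Evaluates glucose quantiles on a shared probability grid, either directly
#' from the sample (`mode = "empirical"`, type-7 interpolation) or by
#' numerically inverting the KDE-based CDF (`mode = "kde"`). The quantile
#' function is the representation on which 2-Wasserstein distances between
#' glucodensities are computed.
#'
#' @param x Numeric glucose values, or a `glucodensity` (forces
#'   `mode = "kde"`).
#' @param p_grid Shared probability grid, uniform in (0, 1).
#' @param mode `"empirical"` or `"kde"`.
#' @param h Bandwidth used when `mode = "kde"` and `x` is a numeric sample.
#' @return Object of class `quantile_function`: list with `p` and `q`
#'   (nondecreasing, mg/dL).
#' @export
quantile_function <- function(x, p_grid = default_p_grid(),
                              mode = c("empirical", "kde"), h = NULL) {
  if (inherits(x, "glucodensity")) {
    mode <- "kde"
  } else {
    mode <- match.arg(mode)
    x <- x[is.finite(x)]
    if (length(x) == 0) stop("no values", call. = FALSE)
  }
  if (mode == "empirical") {
    q <- unname(quantile(x, probs = p_grid, type = 7))
  } else {
    gd <- if (inherits(x, "glucodensity")) x else estimate_glucodensity(x, h = h)
    cf <- density_to_cdf(gd)
    keep <- c(TRUE, diff(cf$cdf) > 0)
    q <- approx(cf$cdf[keep], cf$grid[keep], xout = p_grid,
                rule = 2, ties = "ordered")$y
  }
  structure(list(p = p_grid, q = cummax(q)), class = "quantile_function")
}

#' @export
print.quantile_function <- function(x, ...) {
  cat("<quantile_function>", length(x$p), "probabilities, q in [",
      round(min(x$q), 1), ",", round(max(x$q), 1), "] mg/dL\n")
  invisible(x)
}

#' Glucodensities for every subject in a cohort
#'
#' @param data A `cgm_df` tibble.
#' @param h Bandwidth; `NULL` selects per subject by [silverman_bandwidth()].
#' @param grid Common grid; `NULL` selects per subject.
#' @return Named list of `glucodensity` objects, one per subject.
#' @export
cohort_glucodensities <- function(data, h = NULL, grid = NULL) {
  stopifnot_cgm(data)
  v <- only_valid(data)
  per <- split(v$glucose, v$subject_id)
  lapply(per, estimate_glucodensity, h = h, grid = grid)
}

#' Quantile functions for every subject in a cohort
#'
#' @param data A `cgm_df` tibble.
#' @param p_grid Shared probability grid.
#' @param mode `"empirical"` (default) or `"kde"`.
#' @return Named list of `quantile_function` objects, one per subject.
#' @export
cohort_quantiles <- function(data, p_grid = default_p_grid(),
                             mode = c("empirical", "kde")) {
  stopifnot_cgm(data)
  mode <- match.arg(mode)
  v <- only_valid(data)
  per <- split(v$glucose, v$subject_id)
  lapply(per, quantile_function, p_grid = p_grid, mode = mode)
}
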