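test_that("silverman bandwidth follows the plug-in rule", {
  v <- c(89, 97, 98)
  # 0.9 * min(sd, IQR/1.34) * 3^(-1/5), frozen from the formula by hand
  expect_equal(silverman_bandwidth(v), 2.426197, tolerance = 1e-6)
  expect_gt(silverman_bandwidth(v), 0)
  expect_equal(silverman_bandwidth(2 * v), 2 * silverman_bandwidth(v))
  expect_error(silverman_bandwidth(rep(5, 10)), "explicit bandwidth")
  expect_error(silverman_bandwidth(42), "at least 2")
})

test_that("KDE matches single-kernel and three-term closed forms", {
  # grids chosen so the evaluation point is itself a grid point
  gd <- estimate_glucodensity(100, h = 10, grid = seq(40, 160, by = 0.5))
  expect_equal(gd$density[gd$grid == 100], 1 / (10 * sqrt(2 * pi)),
               tolerance = 1e-9)

  gd3 <- estimate_glucodensity(c(89, 97, 98), h = 5,
                               grid = seq(59, 128, by = 0.5))
  # brute-force three-term kernel sum: mean(dnorm(97, y_i, 5))
  expect_equal(gd3$density[gd3$grid == 97], 0.06006039, tolerance = 1e-6)

  expect_error(estimate_glucodensity(numeric(0)), "no values")
  expect_error(estimate_glucodensity(c(1, 2), h = -1), "positive")
})

test_that("every estimated density integrates to 1 on the default grid", {
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(sample(50:2000, 1), runif(1, 100, 200), runif(1, 15, 50))
    gd <- estimate_glucodensity(v)
    expect_lt(abs(glucodens:::trapz(gd$grid, gd$density) - 1), 1e-6)
    expect_true(all(gd$density >= 0))
  }
})

test_that("KDE agrees with the standard density estimator on a shared grid", {
  set.seed(21)
  v <- rnorm(500, 150, 30)
  h <- silverman_bandwidth(v)
  grid <- seq(0, 320, length.out = 512)
  gd <- estimate_glucodensity(v, h = h, grid = grid)
  ref <- density(v, bw = h, from = 0, to = 320, n = 512)
  expect_equal(gd$density, ref$y, tolerance = 1e-3)
})

test_that("CDF integration matches symmetry and the Gaussian closed form", {
  set.seed(4)
  v <- c(120 + rnorm(2000, 0, 15))
  cf <- density_to_cdf(estimate_glucodensity(v, h = 8))
  at_center <- approx(cf$grid, cf$cdf, xout = mean(v))$y
  expect_equal(at_center, 0.5, tolerance = 0.02)
  expect_lte(cf$cdf[1], 1e-6)
  expect_equal(cf$cdf[length(cf$cdf)], 1)
  expect_true(all(diff(cf$cdf) >= 0))

  # single-value KDE is an exact Gaussian; fine grid keeps the cumulative
  # trapezoid error below the comparison tolerance
  cf1 <- density_to_cdf(estimate_glucodensity(
    100, h = 10, grid = seq(30, 170, length.out = 4097)))
  expect_lt(max(abs(cf1$cdf - pnorm(cf1$grid, 100, 10))), 1e-6)
})

test_that("quantile functions behave in both modes", {
  qc <- quantile_function(rep(100, 5))
  expect_true(all(qc$q == 100))

  qe <- quantile_function(0:100, p_grid = 0.5)
  expect_equal(qe$q, 50)

  set.seed(9)
  v <- rnorm(50000, 150, 30)
  qk <- quantile_function(v, mode = "kde")
  inner <- qk$p >= 0.01 & qk$p <= 0.99  # tails reflect kernel widening
  truth <- qnorm(qk$p, 150, 30)
  expect_lt(max(abs(qk$q - truth)[inner] / abs(truth)[inner]), 0.02)
  expect_true(all(diff(qk$q) >= 0))

  expect_error(quantile_function(numeric(0)), "no values")
})

test_that("CDF -> quantile -> CDF is the identity on the p grid", {
  set.seed(12)
  v <- rnorm(3000, 160, 40)
  gd <- estimate_glucodensity(v)
  cf <- density_to_cdf(gd)
  qf <- quantile_function(gd)
  back <- approx(cf$grid, cf$cdf, xout = qf$q, rule = 2)$y
  expect_lt(max(abs(back - qf$p)), 1e-3)
})

test_that("quantile functions are location equivariant", {
  set.seed(13)
  v <- rnorm(800, 140, 25)
  p <- default_p_grid(199)
  q0 <- quantile_function(v, p)
  q1 <- quantile_function(v + 30, p)
  expect_equal(q1$q, q0$q + 30)  # empirical: exact

  h <- silverman_bandwidth(v)
  k0 <- quantile_function(estimate_glucodensity(v, h = h), p)
  k1 <- quantile_function(estimate_glucodensity(v + 30, h = h), p)
  grid_step <- diff(default_glucose_grid(v, h))[1]
  expect_lt(max(abs(k1$q - (k0$q + 30))), 2 * grid_step)
})

test_that("kde and empirical quantiles converge together as m grows", {
  p <- default_p_grid(99)
  p_in <- p[p >= 0.05 & p <= 0.95]
  gaps <- vapply(c(100, 1000, 10000), function(m) {
    d <- vapply(1:5, function(s) {
      v <- glucodens:::with_seed(s * 100 + m, rnorm(m, 150, 30))
      qe <- quantile_function(v, p)
      qk <- quantile_function(v, p, mode = "kde")
      max(abs(qe$q[p %in% p_in] - qk$q[p %in% p_in]))
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("cohort helpers produce one object per subject", {
  coh <- simulate_cohort(small_cohort_config(seed = 6))
  rec <- quiet_flag(coh$records)
  gds <- cohort_glucodensities(rec)
  qfs <- cohort_quantiles(rec)
  expect_setequal(names(gds), unique(rec$subject_id))
  expect_setequal(names(qfs), unique(rec$subject_id))
  expect_s3_class(gds[[1]], "glucodensity")
  expect_s3_class(qfs[[1]], "quantile_function")
})
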