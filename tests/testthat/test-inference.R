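test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("degenerate groups give H = 0, p = 1", {
  kw <- kruskal_wallis(list(rep(2, 4), rep(2, 3)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "2 non-empty")
})

test_that("Kruskal-Wallis is invariant to monotone transformations", {
  set.seed(55)
  g <- list(rnorm(8, 0), rnorm(6, 1), rnorm(7, 0.5))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) x^3))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) 5 * x - 2))$H, h0)
})

test_that("permutation p agrees with the chi-square approximation at n = 30", {
  set.seed(77)
  g <- split(rnorm(30), rep(1:3, c(13, 11, 6)))
  chisq_p <- kruskal_wallis(g)$p
  perm_p <- kruskal_wallis(g, p_method = "permutation", n_perm = 20000)$p
  expect_lt(abs(chisq_p - perm_p), 0.03)
})

test_that("pairwise rank-sum uses exact enumeration for small groups", {
  tab <- pairwise_ranksum(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(tab$p, 0.1)  # 2 extreme tables of choose(6, 3) = 20

  same <- pairwise_ranksum(list(a = 1:4, b = 1:4))
  expect_equal(same$p, 1)

  warns <- testthat::capture_warnings(
    out <- pairwise_ranksum(list(a = 1:3, b = numeric(0), c = 4:6)))
  expect_true(all(grepl("empty group", warns)))
  expect_equal(nrow(out), 1)
})

test_that("BH adjustment is the step-up arithmetic and order-preserving", {
  tab <- pairwise_ranksum(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(tab$p_adj, p.adjust(tab$p, "BH"))
  expect_true(all(tab$p_adj >= tab$p))
  expect_equal(order(tab$p_adj), order(tab$p))
  # frozen example of the step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("cluster comparisons handle constants, missing data, empty cluster", {
  ids <- sprintf("S%02d", 1:9)
  a <- glucodens:::new_cluster_assignment(
    stats::setNames(rep(1:3, each = 3L), ids), 3L, ids[c(1, 4, 7)], 0)
  covs <- tibble::tibble(subject_id = ids,
                         c_peptide = c(5, 5, 5, 5, 5, 5, 5, 5, 5),
                         tir = c(0.9, 0.8, 0.85, 0.5, 0.55, 0.6, 0.2, 0.25, 0.3))
  res <- compare_clusters_by_variable(a, covs, c("c_peptide", "tir"))
  expect_equal(res$c_peptide$H, 0)
  expect_equal(res$c_peptide$p, 1)
  expect_lt(res$tir$p, 0.05)
  expect_equal(nrow(res$tir$pairwise), 3)

  covs$tir[1] <- NA
  expect_message(compare_clusters_by_variable(a, covs, "tir"), "1 subject")
  covs$tir[1:3] <- NA
  expect_error(compare_clusters_by_variable(a, covs, "tir"), "cluster empty")
  expect_error(compare_clusters_by_variable(a, covs, "nope"), "not found")
})

test_that("cluster comparison detects a planted covariate shift", {
  hits <- vapply(1:50, function(s) {
    vals <- glucodens:::with_seed(s, {
      lab <- sample(rep(1:3, c(13, 11, 6)))
      x <- rnorm(30)
      x[lab == 3] <- x[lab == 3] + 2
      list(lab = lab, x = x)
    })
    kruskal_wallis(split(vals$x, vals$lab))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("ANCOVA recovers exact noise-free structure", {
  tir0 <- c(0.3, 0.5, 0.6, 0.8, 0.4, 0.7)
  trt <- c(1, 0, 1, 0, 1, 0)
  # noise-free fits are intentionally perfect; silence summary.lm's note
  fit <- suppressWarnings(ancova_tir(tir0, tir0, trt))
  expect_equal(fit$mu, 0, tolerance = 1e-10)
  expect_equal(fit$alpha, 0, tolerance = 1e-10)
  expect_equal(fit$beta, 1, tolerance = 1e-10)

  fit2 <- suppressWarnings(ancova_tir(tir0, 0.5 + 0.1 * trt, trt))
  expect_equal(fit2$alpha, 0.1, tolerance = 1e-10)
  expect_equal(fit2$beta, 0, tolerance = 1e-10)

  expect_error(ancova_tir(rep(0.5, 6), tir0, trt), "rank deficient")
  expect_error(ancova_tir(tir0[1:3], tir0[1:3], trt[1:3]), "n >= 4")
  expect_error(ancova_tir(tir0, tir0, c(1, 2, 1, 0, 1, 0)), "0/1")
})

test_that("all-control ANCOVA equals simple regression of tir1 on tir0", {
  set.seed(88)
  tir0 <- runif(20, 0.2, 0.9)
  tir1 <- 0.1 + 0.8 * tir0 + rnorm(20, 0, 0.05)
  fit <- ancova_tir(tir0, tir1, rep(0, 20))
  direct <- lm(tir1 ~ tir0)
  expect_equal(fit$mu, unname(coef(direct)[1]), tolerance = 1e-10)
  expect_equal(fit$beta, unname(coef(direct)[2]), tolerance = 1e-10)
  expect_true(is.na(fit$alpha) || abs(fit$alpha) < 1e-10)
})

test_that("change-from-baseline tests match closed forms", {
  tir0 <- rep(0, 5)
  out <- change_from_baseline_tests(tir0, 1:5, rep(1, 5))
  expect_equal(out$t, 3 * sqrt(5) / sqrt(2.5))
  expect_equal(out$df, 4)

  alt <- change_from_baseline_tests(rep(0, 4), c(1, -1, 1, -1), rep(0, 4))
  expect_equal(alt$t, 0)
  expect_equal(alt$p, 1)

  both <- change_from_baseline_tests(rep(0, 8), rep(c(1, 2, 3, 4), 2),
                                     rep(c(0, 1), each = 4))
  welch <- both[both$test == "welch", ]
  expect_equal(welch$t, 0)
  expect_equal(welch$estimate, 0)

  expect_error(change_from_baseline_tests(rep(0, 4), rep(1, 4), rep(1, 4)),
               "arm 1")
})
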