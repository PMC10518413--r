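#' Kruskal-Wallis rank test across clusters
#'
#' Rank-based nonparametric one-way ANOVA with tie correction, p-value from
#' the chi-square approximation with k - 1 degrees of freedom (the default in
#' standard software at any sample size), or from a Monte-Carlo permutation
#' null for small samples.
#'
#' @param groups List of numeric vectors, one per cluster (>= 2 groups, each
#'   non-empty).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List with `H` (test statistic), `p`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000, seed = 1) {
  p_method <- match.arg(p_method)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  if (length(unique(pooled)) == 1) {
    return(list(H = 0, p = 1, df = k - 1L, method = "degenerate"))
  }
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  if (p_method == "chisq") {
    return(list(H = H, p = unname(kt$p.value), df = k - 1L, method = "chisq"))
  }
  sizes <- lengths(groups)
  stat_of <- function(x) {
    unname(kruskal.test(split(x, rep(seq_len(k), sizes)))$statistic)
  }
  null_H <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_of(sample(pooled)) }, numeric(1)))
  p <- (1 + sum(null_H >= H - 1e-12)) / (n_perm + 1)
  list(H = H, p = p, df = k - 1L, method = "permutation")
}

#' Pairwise Wilcoxon rank-sum tests between clusters
#'
#' Two-sided rank-sum test for every cluster pair: exact enumeration when
#' both groups have at most 8 observations and no ties, otherwise the normal
#' approximation with tie and continuity correction. Raw p-values are primary
#' (the pairwise comparisons are exploratory); Benjamini-Hochberg-adjusted
#' values are reported alongside.
#'
#' @param groups Named list of numeric vectors, one per cluster.
#' @return Tibble with columns `group1`, `group2`, `p`, `p_adj` (BH),
#'   one row per unordered pair.
#' @export
pairwise_ranksum <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    g1 <- groups[[i1]]; g2 <- groups[[i2]]
    if (length(g1) == 0 || length(g2) == 0) {
      warning("empty group in pair ", nm[i1], " vs ", nm[i2], "; skipped",
              call. = FALSE)
      return(NULL)
    }
    if (identical(sort(g1), sort(g2))) {
      p <- 1
    } else {
      exact <- length(g1) <= 8 && length(g2) <= 8 &&
        !any(duplicated(c(g1, g2)))
      p <- suppressWarnings(
        wilcox.test(g1, g2, exact = exact, correct = TRUE)$p.value)
    }
    tibble::tibble(group1 = nm[i1], group2 = nm[i2], p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Compare clusters on covariates and glycemic metrics
#'
#' For each requested variable, splits the per-subject values by cluster and
#' reports the Kruskal-Wallis omnibus test plus the pairwise rank-sum table.
#' Subjects with a missing value are excluded (count messaged); an entire
#' cluster lost to missingness is an error.
#'
#' @param assignment A `cluster_assignment`.
#' @param covariate_table Tibble keyed by `subject_id` holding the variables
#'   (e.g. `c_peptide`, `tir`, `tar`, `tbr`).
#' @param variables Character vector of column names to compare.
#' @return Named list of `comparison_result` objects (fields `variable`,
#'   `groups`, `H`, `p`, `pairwise`).
#' @export
compare_clusters_by_variable <- function(assignment, covariate_table,
                                         variables = c("c_peptide", "tir",
                                                       "tar", "tbr")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$cluster)
  tab <- covariate_table[match(ids, covariate_table$subject_id), , drop = FALSE]
  out <- lapply(variables, function(v) {
    if (!v %in% names(tab)) stop("variable not found: ", v, call. = FALSE)
    x <- tab[[v]]
    keep <- is.finite(x)
    if (any(!keep)) {
      message(sum(!keep), " subject(s) missing '", v, "' excluded")
    }
    cl <- assignment$cluster[keep]
    groups <- split(x[keep], cl)
    if (length(groups) < assignment$k || any(lengths(groups) == 0)) {
      stop("cluster empty after missing-data exclusion for '", v, "'",
           call. = FALSE)
    }
    kw <- kruskal_wallis(groups)
    structure(list(variable = v, groups = groups, H = kw$H, p = kw$p,
                   pairwise = pairwise_ranksum(groups)),
              class = "comparison_result")
  })
  stats::setNames(out, variables)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$variable, ": Kruskal-Wallis H =",
      signif(x$H, 4), ", p =", signif(x$p, 3), "\n")
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' ANCOVA for post-treatment time in range
#'
#' Ordinary least squares for the change-from-baseline model
#' `TIR1 = mu + alpha * treatment + beta * TIR0 + error`, with the t-test of
#' the treatment effect `alpha = 0` as the primary contrast.
#'
#' @param tir0 Baseline TIR per subject.
#' @param tir1 Post-treatment TIR per subject.
#' @param treatment_indicator 0/1 vector (1 = active arm).
#' @return Object of class `ancova_fit`: list with `mu`, `alpha`, `beta`,
#'   `se` (named), `t_alpha`, `p_alpha`, `sigma`, `n`, and the underlying
#'   `lm` fit.
#' @export
ancova_tir <- function(tir0, tir1, treatment_indicator) {
  n <- length(tir1)
  if (length(tir0) != n || length(treatment_indicator) != n) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (!all(treatment_indicator %in% c(0, 1))) {
    stop("treatment_indicator must be 0/1", call. = FALSE)
  }
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (var(tir0) == 0) {
    stop("baseline TIR is constant; design matrix is rank deficient",
         call. = FALSE)
  }
  delta <- as.numeric(treatment_indicator)
  if (length(unique(delta)) == 1) {
    # single-arm data: the model reduces to simple regression on baseline
    fit <- lm(tir1 ~ tir0)
    sm <- summary(fit)
    cf <- sm$coefficients
    return(structure(list(
      mu = unname(cf["(Intercept)", "Estimate"]),
      alpha = NA_real_,
      beta = unname(cf["tir0", "Estimate"]),
      se = c(mu = cf["(Intercept)", "Std. Error"], alpha = NA_real_,
             beta = cf["tir0", "Std. Error"]),
      t_alpha = NA_real_, p_alpha = NA_real_,
      sigma = sm$sigma, n = n, fit = fit
    ), class = "ancova_fit"))
  }
  fit <- lm(tir1 ~ delta + tir0)
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(list(
    mu = unname(cf["(Intercept)", "Estimate"]),
    alpha = unname(cf["delta", "Estimate"]),
    beta = unname(cf["tir0", "Estimate"]),
    se = c(mu = cf["(Intercept)", "Std. Error"],
           alpha = cf["delta", "Std. Error"],
           beta = cf["tir0", "Std. Error"]),
    t_alpha = unname(cf["delta", "t value"]),
    p_alpha = unname(cf["delta", "Pr(>|t|)"]),
    sigma = sm$sigma, n = n, fit = fit
  ), class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("<ancova_fit> n =", x$n, "\n")
  cat(sprintf("  mu = %.4f  alpha = %.4f (t = %.3f, p = %.4g)  beta = %.4f\n",
              x$mu, x$alpha, x$t_alpha, x$p_alpha, x$beta))
  invisible(x)
}

#' Paired and two-sample t-tests on TIR change from baseline
#'
#' Per arm, the paired t-test of the within-subject change `TIR1 - TIR0`
#' against zero; between arms, Welch's two-sample t-test on the changes.
#'
#' @param tir0,tir1 Baseline and post-treatment TIR per subject.
#' @param treatment_indicator 0/1 vector (1 = active arm).
#' @return Tibble with columns `test`, `arm`, `estimate` (mean change or
#'   difference in mean change), `t`, `df`, `p`.
#' @export
change_from_baseline_tests <- function(tir0, tir1, treatment_indicator) {
  delta <- tir1 - tir0
  arms <- sort(unique(treatment_indicator))
  rows <- lapply(arms, function(a) {
    d <- delta[treatment_indicator == a]
    if (length(d) < 2 || var(d) == 0) {
      stop("zero change-from-baseline variance in arm ", a, call. = FALSE)
    }
    tt <- t.test(d)
    tibble::tibble(test = "paired", arm = as.character(a),
                   estimate = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (length(arms) == 2) {
    d1 <- delta[treatment_indicator == arms[2]]
    d0 <- delta[treatment_indicator == arms[1]]
    tt <- t.test(d1, d0)
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = "welch", arm = paste(arms[2], "vs", arms[1]),
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value))
  }
  out
}
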