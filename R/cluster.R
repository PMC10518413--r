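#' Cluster subjects by k-medoids on a Wasserstein distance matrix
#'
#' Partitioning-around-medoids on the precomputed 2-Wasserstein distance
#' matrix. The first restart is deterministic: the most central subject
#' (minimum total distance) seeds the medoid set and subsequent medoids are
#' added by max-min separation; further restarts draw random initial medoid
#' sets from the seeded RNG. Each start is refined by steepest-descent swaps
#' to a local optimum; ties in cost are broken toward the lowest subject
#' index. The best restart by total within-cluster distance wins.
#' Deterministic given `seed`.
#'
#' @param D Symmetric distance matrix with subject IDs as dimnames.
#' @param k Number of clusters, `2 <= k <= nrow(D)` (`k = 1` returns the
#'   trivial single cluster).
#' @param n_restarts Number of starts (first is deterministic).
#' @param seed Integer seed for the random restarts.
#' @return Object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector of labels 1..k), `k`, `medoids` (subject IDs, label
#'   order), `cost` (total within-cluster distance).
#' @param method `"pam"` (default) or `"average"` for agglomerative
#'   average-linkage cutting the tree at `k`.
#' @export
cluster_glucodensities <- function(D, k, n_restarts = 20, seed = 1,
                                   method = c("pam", "average")) {
  method <- match.arg(method)
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k > n) stop("k exceeds the number of subjects", call. = FALSE)
  if (k == 1) {
    cl <- stats::setNames(rep(1L, n), ids)
    med <- ids[which.min(colSums(D))]
    return(new_cluster_assignment(cl, 1L, med, sum(D[, med])))
  }
  if (method == "average") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    lab <- stats::cutree(hc, k = k)
    meds <- vapply(seq_len(k), function(g) {
      members <- which(lab == g)
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    cost <- sum(vapply(seq_len(k), function(g) {
      sum(D[lab == g, meds[g]])
    }, numeric(1)))
    return(new_cluster_assignment(stats::setNames(as.integer(lab), ids), k,
                                  ids[meds], cost))
  }
  starts <- vector("list", n_restarts)
  starts[[1]] <- maxmin_seed(D, k)
  if (n_restarts > 1) {
    rand <- with_seed(seed, lapply(seq_len(n_restarts - 1),
                                   function(i) sort(sample.int(n, k))))
    starts[seq_len(n_restarts - 1) + 1] <- rand
  }
  best <- NULL
  for (st in starts) {
    res <- pam_swap(D, st)
    if (is.null(best) || res$cost < best$cost - 1e-12 ||
        (abs(res$cost - best$cost) <= 1e-12 &&
         !identical(res$medoids, best$medoids) &&
         paste(res$medoids, collapse = ",") < paste(best$medoids, collapse = ","))) {
      best <- res
    }
  }
  meds <- sort(best$medoids)
  lab <- apply(D[, meds, drop = FALSE], 1, which.min)
  new_cluster_assignment(stats::setNames(as.integer(lab), ids), as.integer(k),
                         ids[meds], best$cost)
}

# first medoid: most central point; then max-min separation seeding
maxmin_seed <- function(D, k) {
  meds <- which.min(colSums(D))
  while (length(meds) < k) {
    dmin <- apply(D[, meds, drop = FALSE], 1, min)
    dmin[meds] <- -Inf
    meds <- c(meds, which.max(dmin))
  }
  sort(meds)
}

# steepest-descent swap phase; lowest-index tie-break via strict improvement
pam_swap <- function(D, medoids) {
  n <- nrow(D)
  cost <- function(m) sum(apply(D[, m, drop = FALSE], 1, min))
  cur <- cost(medoids)
  repeat {
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (h in seq_len(n)) {
        if (h %in% medoids) next
        cand <- medoids
        cand[mi] <- h
        delta <- cost(cand) - cur
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- cand
        }
      }
    }
    if (is.null(best_swap)) break
    medoids <- sort(best_swap)
    cur <- cur + best_delta
  }
  list(medoids = medoids, cost = cur)
}

new_cluster_assignment <- function(cluster, k, medoids, cost) {
  structure(list(cluster = cluster, k = k, medoids = medoids, cost = cost),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", x$k, " sizes:",
      paste(table(x$cluster), collapse = "/"),
      " cost =", signif(x$cost, 5), "\n")
  cat(" medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of clusters by mean silhouette
#'
#' Runs [cluster_glucodensities()] for each candidate `k` and returns the
#' `k` maximizing the mean silhouette width computed from the distance
#' matrix; ties go to the smallest `k`.
#'
#' @param D Symmetric distance matrix.
#' @param k_min,k_max Candidate range; `k_max` is capped at `n - 1`.
#' @param n_restarts,seed Passed to [cluster_glucodensities()].
#' @return Integer `k`, with the silhouette profile attached as attribute
#'   `silhouette` (named numeric vector).
#' @export
select_k <- function(D, k_min = 2, k_max = 6, n_restarts = 20, seed = 1) {
  n <- nrow(D)
  if (all(D == 0)) stop("degenerate distance matrix (all zeros)", call. = FALSE)
  k_max <- min(k_max, n - 1)
  if (k_min > k_max) stop("empty candidate range for k", call. = FALSE)
  ks <- k_min:k_max
  sil <- vapply(ks, function(k) {
    a <- cluster_glucodensities(D, k, n_restarts = n_restarts, seed = seed)
    mean(cluster::silhouette(as.integer(a$cluster), dmatrix = D)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  k <- ks[which.max(sil)]  # which.max takes the first (smallest k) on ties
  structure(as.integer(k), silhouette = sil)
}

#' Adjusted Rand index between a truth table and a clustering
#'
#' Chance-corrected agreement between the generator's true class partition
#' and a recovered cluster assignment: 1 for identical partitions up to
#' relabeling, about 0 for random labels.
#'
#' @param truth Tibble with columns `subject_id` and `class` (the generator's
#'   truth table).
#' @param assignment A `cluster_assignment`.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
cohort_truth_ari <- function(truth, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$cluster)
  if (!setequal(ids, truth$subject_id)) {
    stop("subject sets differ between truth and assignment", call. = FALSE)
  }
  true_lab <- truth$class[match(ids, truth$subject_id)]
  mclust::adjustedRandIndex(true_lab, assignment$cluster)
}
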