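#' Configuration for a full pipeline run
#'
#' @param out_dir Output directory for all artifacts.
#' @param input_csv,covariates_csv Paths to CGM records and covariates in
#'   the standard CSV dialects; when `NULL`, a synthetic cohort is simulated
#'   from `cohort` and written alongside the other artifacts.
#' @param cohort A `cohort_config` used when no input files are given.
#' @param lo_plausible,hi_plausible Sensor-plausibility bounds, mg/dL.
#' @param range_lo,range_hi Target-range limits, mg/dL.
#' @param coverage_fraction Fraction for [coverage_days()].
#' @param p_grid_n Size of the shared probability grid.
#' @param quantile_mode `"empirical"` or `"kde"` for the distance
#'   representation.
#' @param k Number of clusters, or `"auto"` for silhouette selection.
#' @param n_restarts Clustering restarts.
#' @param variables Covariate/metric names compared across clusters.
#' @param seed Root seed for every stochastic stage.
#' @param make_figures Set `FALSE` to skip image rendering.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       input_csv = NULL, covariates_csv = NULL,
                       cohort = cohort_config(),
                       lo_plausible = 39, hi_plausible = 401,
                       range_lo = 70, range_hi = 180,
                       coverage_fraction = 0.7,
                       p_grid_n = 999,
                       quantile_mode = "empirical",
                       k = "auto", n_restarts = 20,
                       variables = c("c_peptide", "tir", "tar", "tbr"),
                       seed = 1, make_figures = TRUE) {
  structure(list(out_dir = out_dir, input_csv = input_csv,
                 covariates_csv = covariates_csv, cohort = cohort,
                 lo_plausible = lo_plausible, hi_plausible = hi_plausible,
                 range_lo = range_lo, range_hi = range_hi,
                 coverage_fraction = coverage_fraction,
                 p_grid_n = p_grid_n, quantile_mode = quantile_mode,
                 k = k, n_restarts = n_restarts, variables = variables,
                 seed = as.integer(seed), make_figures = make_figures),
            class = "run_config")
}

#' Run the full glucodensity analysis pipeline
#'
#' Executes validate, metrics, density, distance, cluster, compare and plot
#' stages in order, writing every artifact (CSV tables, figures with
#' `.data.csv` sidecars) plus a `manifest.json` into `config$out_dir`.
#' Rerunning with an identical config and seed reproduces identical numeric
#' artifacts.
#'
#' @param config A `run_config`.
#' @return (Invisibly) list with the manifest and the main in-memory
#'   results (`summary`, `metrics`, `distances`, `assignment`,
#'   `comparisons`, `truth_ari` when ground truth is available).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- list(stage = name,
                            seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  truth <- NULL
  if (is.null(config$input_csv)) {
    cohort <- simulate_cohort(config$cohort)
    write_cohort(cohort, out)
    records <- cohort$records
    covars <- cohort$covariates
    truth <- cohort$truth
    input_files <- file.path(out, c("cgm.csv", "covariates.csv"))
  } else {
    records <- read_cgm_csv(config$input_csv)
    covars <- readr::read_csv(config$covariates_csv, show_col_types = FALSE)
    input_files <- c(config$input_csv, config$covariates_csv)
  }

  records <- t_stage("validate", {
    r <- suppressMessages(flag_invalid(records, config$lo_plausible,
                                       config$hi_plausible))
    smry <- cohort_summary(r, config$coverage_fraction)
    readr::write_csv(smry, file.path(out, "cohort_summary.csv"),
                     progress = FALSE)
    attr(r, "summary") <- smry
    r
  })
  smry <- attr(records, "summary")

  metrics <- t_stage("metrics", {
    m <- summary_metrics(records, config$range_lo, config$range_hi)
    readr::write_csv(m, file.path(out, "metrics.csv"), progress = FALSE)
    d <- daily_tir_series(records, config$range_lo, config$range_hi)
    readr::write_csv(d, file.path(out, "daily_tir.csv"), progress = FALSE)
    list(metrics = m, daily = d)
  })

  densities <- t_stage("density", {
    gd <- cohort_glucodensities(records)
    long <- dplyr::bind_rows(lapply(names(gd), function(id) {
      tibble::tibble(subject_id = id, grid_mg_dl = gd[[id]]$grid,
                     density = gd[[id]]$density)
    }))
    readr::write_csv(long, file.path(out, "glucodensities.csv"),
                     progress = FALSE)
    gd
  })

  quantiles <- t_stage("distance", {
    qf <- cohort_quantiles(records, default_p_grid(config$p_grid_n),
                           mode = config$quantile_mode)
    qlong <- dplyr::bind_rows(lapply(names(qf), function(id) {
      tibble::tibble(subject_id = id, p = qf[[id]]$p, q_mg_dl = qf[[id]]$q)
    }))
    readr::write_csv(qlong, file.path(out, "quantiles.csv"), progress = FALSE)
    D <- pairwise_distance_matrix(qf)
    dd <- as.data.frame(D)
    dd <- cbind(subject_id = rownames(D), dd)
    readr::write_csv(tibble::as_tibble(dd), file.path(out, "distances.csv"),
                     progress = FALSE)
    list(qf = qf, D = D)
  })
  D <- quantiles$D

  assignment <- t_stage("cluster", {
    k <- if (identical(config$k, "auto")) {
      select_k(D, n_restarts = config$n_restarts, seed = config$seed)
    } else as.integer(config$k)
    a <- cluster_glucodensities(D, k, n_restarts = config$n_restarts,
                                seed = config$seed)
    readr::write_csv(tibble::tibble(
      subject_id = names(a$cluster),
      cluster = unname(a$cluster),
      is_medoid = names(a$cluster) %in% a$medoids
    ), file.path(out, "clusters.csv"), progress = FALSE)
    a
  })

  comparisons <- t_stage("compare", {
    covtab <- dplyr::left_join(covars, metrics$metrics, by = "subject_id")
    res <- compare_clusters_by_variable(assignment, covtab,
                                        config$variables)
    flat <- dplyr::bind_rows(lapply(res, function(cr) {
      tibble::tibble(variable = cr$variable, H = cr$H, p = cr$p,
                     pair = paste(cr$pairwise$group1, cr$pairwise$group2,
                                  sep = "-"),
                     p_pair = cr$pairwise$p, p_pair_bh = cr$pairwise$p_adj)
    }))
    readr::write_csv(flat, file.path(out, "comparisons.csv"), progress = FALSE)
    nested <- lapply(res, function(cr) {
      list(H = cr$H, p = cr$p,
           pairwise = lapply(seq_len(nrow(cr$pairwise)), function(i) {
             as.list(cr$pairwise[i, ])
           }))
    })
    jsonlite::write_json(nested, file.path(out, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  t_stage("plot", {
    if (isTRUE(config$make_figures)) {
      hm <- hourly_mean_matrix(records)
      lasagna_plot(hm, file.path(out, "fig_lasagna.png"),
                   config$range_lo, config$range_hi)
      profiles <- lapply(split(records, records$subject_id), function(s) {
        suppressWarnings(agp_profile(new_cgm_df(s)))
      })
      agp_panel_plot(profiles, file.path(out, "fig_agp.png"))
      suppressWarnings(dynamic_tir_plot(metrics$daily,
                                        file.path(out, "fig_dynamic_tir.png")))
      glucodensity_cluster_plot(densities, assignment,
                                out = file.path(out,
                                                "fig_density_clusters.png"))
      cluster_boxplots(comparisons, file.path(out,
                                              "fig_cluster_boxplots.png"))
    }
    NULL
  })

  truth_ari <- if (!is.null(truth) && assignment$k == length(unique(truth$class))) {
    cohort_truth_ari(truth, assignment)
  } else NA_real_

  manifest <- list(
    stages = unname(stages),
    seed = config$seed,
    n_subjects = length(unique(records$subject_id)),
    n_records = nrow(records),
    n_valid = sum(records$valid),
    flagged_fraction = mean(!records$valid),
    k = assignment$k,
    cluster_sizes = as.list(table(assignment$cluster)),
    truth_ari = truth_ari,
    input_hashes = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    package_version = as.character(utils::packageVersion("glucodens"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, summary = smry,
                 metrics = metrics$metrics, daily = metrics$daily,
                 densities = densities, quantiles = quantiles$qf,
                 distances = D, assignment = assignment,
                 comparisons = comparisons, truth = truth,
                 truth_ari = truth_ari))
}
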