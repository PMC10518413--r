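#' @import ggplot2
NULL

save_figure <- function(plot, out, data, width = 10, height = 7) {
  if (is.null(out)) return(NULL)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ggsave(out, plot, width = width, height = height, dpi = 120)
  sidecar <- paste0(tools::file_path_sans_ext(out), ".data.csv")
  readr::write_csv(data, sidecar, progress = FALSE)
  c(figure = out, data = sidecar)
}

#' Lasagna plot of hourly mean glucose
#'
#' Heatmap with one row per subject and one column per hour of day; cell
#' color is the subject's mean glucose at that hour, on a diverging scale
#' anchored at the 70 and 180 mg/dL target limits (red low, green in range,
#' yellow/orange high). Hours without data are drawn in grey.
#'
#' @param hourly_matrix Matrix from [hourly_mean_matrix()].
#' @param out Output image path (`.png`, `.pdf` or `.svg`); `NULL` skips
#'   writing. A `<name>.data.csv` sidecar with the rendered numbers
#'   accompanies every image.
#' @param lo,hi Target-range anchors, mg/dL.
#' @return (Invisibly) list with `matrix` (exactly what was rendered),
#'   `data` (long tibble), `plot`, and `files`.
#' @export
lasagna_plot <- function(hourly_matrix, out = NULL, lo = 70, hi = 180) {
  if (is.null(dim(hourly_matrix)) || nrow(hourly_matrix) == 0) {
    stop("empty matrix", call. = FALSE)
  }
  ids <- rownames(hourly_matrix) %||% as.character(seq_len(nrow(hourly_matrix)))
  long <- tibble::tibble(
    subject_id = rep(ids, times = ncol(hourly_matrix)),
    hour = rep(as.integer(colnames(hourly_matrix)), each = nrow(hourly_matrix)),
    mean_glucose = as.vector(hourly_matrix)
  )
  p <- ggplot(long, aes(x = .data$hour,
                        y = factor(.data$subject_id, levels = rev(ids)),
                        fill = .data$mean_glucose)) +
    geom_tile() +
    scale_fill_gradientn(
      colours = c("#d73027", "#1a9850", "#a6d96a", "#fee08b", "#f46d43"),
      values = scales_rescale(c(40, lo, (lo + hi) / 2, hi, 300), c(40, 300)),
      limits = c(40, 300), oob = squish_oob, na.value = "grey85",
      name = "mg/dL") +
    labs(x = "Hour of day", y = NULL,
         title = "Average glucose by time of day") +
    theme_minimal(base_size = 10)
  files <- save_figure(p, out, long)
  invisible(list(matrix = hourly_matrix, data = long, plot = p, files = files))
}

# minimal stand-ins for scales:: helpers so the hard dependency is ggplot2 only
scales_rescale <- function(x, range) (x - range[1]) / (range[2] - range[1])
squish_oob <- function(x, range = c(0, 1), ...) pmin(pmax(x, range[1]), range[2])

#' Ambulatory glucose profile panels
#'
#' One panel per subject: raw per-day traces over the 24-h clock (blue),
#' the smoothed mean profile (red), and dashed target-range lines at 70 and
#' 180 mg/dL.
#'
#' @param profiles List of `agp_profile` objects ([agp_profile()]).
#' @param out Output image path, or `NULL`.
#' @param max_raw_days Per subject, at most this many distinct days of raw
#'   trace are drawn (the smooth always uses all data).
#' @return (Invisibly) list with `data` (smoothed curves, long tibble),
#'   `raw`, `plot`, `files`.
#' @export
agp_panel_plot <- function(profiles, out = NULL, max_raw_days = 14) {
  if (length(profiles) == 0) stop("no profiles", call. = FALSE)
  smooth <- dplyr::bind_rows(lapply(profiles, function(pr) {
    tibble::tibble(subject_id = pr$subject_id, tod = pr$grid,
                   mean_agp = pr$mean, se = pr$se)
  }))
  raw <- dplyr::bind_rows(lapply(profiles, function(pr) {
    days <- unique(pr$raw$date)
    keep <- pr$raw$date %in% days[seq_len(min(length(days), max_raw_days))]
    tibble::tibble(subject_id = pr$subject_id, date = pr$raw$date[keep],
                   tod = pr$raw$tod[keep], glucose = pr$raw$glucose[keep])
  }))
  p <- ggplot() +
    geom_line(data = raw,
              aes(x = .data$tod, y = .data$glucose,
                  group = interaction(.data$date)),
              colour = "steelblue", linewidth = 0.2, alpha = 0.5) +
    geom_line(data = smooth, aes(x = .data$tod, y = .data$mean_agp),
              colour = "red", linewidth = 0.7) +
    geom_hline(yintercept = c(70, 180), linetype = "dashed") +
    facet_wrap(~subject_id) +
    scale_x_continuous(limits = c(0, 24), breaks = c(0, 6, 12, 18, 24)) +
    labs(x = "Hour of day", y = "Glucose (mg/dL)",
         title = "Ambulatory glucose profiles") +
    theme_minimal(base_size = 9)
  files <- save_figure(p, out, smooth, width = 12, height = 9)
  invisible(list(data = smooth, raw = raw, plot = p, files = files))
}

#' Dynamic time-in-range panels
#'
#' One panel per subject: daily TIR against study day (blue), a smoothed
#' mean profile (red) with a pointwise uncertainty band (grey). Axis ranges
#' are subject-specific; single-day subjects are drawn as a point with a
#' warning.
#'
#' @param daily Long tibble from [daily_tir_series()].
#' @param out Output image path, or `NULL`.
#' @param span Local-regression span for the smoothed mean.
#' @return (Invisibly) list with `data` (daily values plus smooth and band
#'   where defined), `plot`, `files`.
#' @export
dynamic_tir_plot <- function(daily, out = NULL, span = 0.75) {
  if (nrow(daily) == 0) stop("no daily TIR data", call. = FALSE)
  smoothed <- dplyr::bind_rows(lapply(split(daily, daily$subject_id),
                                      function(d) {
    d <- d[order(d$study_day), ]
    if (nrow(d) < 2) {
      warning("subject ", d$subject_id[1],
              " has a single day; no smooth drawn", call. = FALSE)
      d$smooth <- NA_real_; d$smooth_se <- NA_real_
      return(d)
    }
    fit <- tryCatch(loess(tir ~ study_day, data = d,
                          span = max(span, 4 / nrow(d)), degree = 1),
                    error = function(e) NULL)
    if (is.null(fit)) {
      d$smooth <- mean(d$tir); d$smooth_se <- NA_real_
    } else {
      pr <- predict(fit, newdata = d, se = TRUE)
      d$smooth <- as.numeric(pr$fit)
      d$smooth_se <- as.numeric(pr$se.fit)
    }
    d
  }))
  smoothed$smooth_se[!is.finite(smoothed$smooth_se)] <- NA_real_
  band <- smoothed[!is.na(smoothed$smooth_se), , drop = FALSE]
  p <- ggplot(smoothed, aes(x = .data$study_day)) +
    geom_ribbon(data = band,
                aes(ymin = .data$smooth - 1.96 * .data$smooth_se,
                    ymax = .data$smooth + 1.96 * .data$smooth_se),
                fill = "grey70", alpha = 0.6, na.rm = TRUE) +
    geom_line(aes(y = .data$tir), colour = "steelblue", linewidth = 0.4) +
    geom_point(aes(y = .data$tir), colour = "steelblue", size = 0.5) +
    geom_line(aes(y = .data$smooth), colour = "red", linewidth = 0.7,
              na.rm = TRUE) +
    facet_wrap(~subject_id, scales = "free") +
    labs(x = "Study day", y = "Time in range (proportion)",
         title = "Daily time in range over the study") +
    theme_minimal(base_size = 9)
  files <- save_figure(p, out, smoothed, width = 12, height = 9)
  invisible(list(data = smoothed, plot = p, files = files))
}

#' Clustered glucodensity and CDF panels
#'
#' One density panel and one CDF panel per cluster; each curve is one
#' subject, colored by cluster.
#'
#' @param densities Named list of `glucodensity` objects.
#' @param cdfs Named list of `gluco_cdf` objects (defaults to integrating
#'   `densities`).
#' @param assignment A `cluster_assignment` covering every subject.
#' @param out Output image path, or `NULL`.
#' @return (Invisibly) list with `data` (long tibble of rendered curves),
#'   `plot`, `files`.
#' @export
glucodensity_cluster_plot <- function(densities, assignment,
                                      cdfs = lapply(densities, density_to_cdf),
                                      out = NULL) {
  ids <- names(densities)
  missing <- setdiff(ids, names(assignment$cluster))
  if (length(missing) > 0) {
    stop("subject(s) missing from assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long <- dplyr::bind_rows(lapply(ids, function(id) {
    cl <- assignment$cluster[[id]]
    dplyr::bind_rows(
      tibble::tibble(subject_id = id, cluster = cl, kind = "density",
                     glucose = densities[[id]]$grid,
                     value = densities[[id]]$density),
      tibble::tibble(subject_id = id, cluster = cl, kind = "cdf",
                     glucose = cdfs[[id]]$grid, value = cdfs[[id]]$cdf)
    )
  }))
  long$kind <- factor(long$kind, levels = c("density", "cdf"))
  p <- ggplot(long, aes(x = .data$glucose, y = .data$value,
                        group = .data$subject_id,
                        colour = factor(.data$cluster))) +
    geom_line(linewidth = 0.4) +
    facet_grid(cluster ~ kind, scales = "free_y") +
    scale_colour_brewer(palette = "Set1", name = "Cluster") +
    labs(x = "Glucose (mg/dL)", y = NULL,
         title = "Clustered glucodensities and CDFs") +
    theme_minimal(base_size = 10)
  files <- save_figure(p, out, long, width = 10, height = 8)
  invisible(list(data = long, plot = p, files = files))
}

#' Cluster comparison boxplots
#'
#' Per-cluster boxplots of each compared variable, annotated with the
#' Kruskal-Wallis omnibus p-value and the pairwise rank-sum p-values.
#'
#' @param comparison_results Named list of `comparison_result` objects
#'   ([compare_clusters_by_variable()]).
#' @param out Output image path, or `NULL`.
#' @return (Invisibly) list with `data` (long tibble of individual values),
#'   `annotations` (p-value strings per panel), `plot`, `files`.
#' @export
cluster_boxplots <- function(comparison_results, out = NULL) {
  if (length(comparison_results) == 0) stop("no comparison results",
                                            call. = FALSE)
  long <- dplyr::bind_rows(lapply(comparison_results, function(cr) {
    dplyr::bind_rows(lapply(names(cr$groups), function(g) {
      tibble::tibble(variable = cr$variable, cluster = g,
                     value = cr$groups[[g]])
    }))
  }))
  ann <- dplyr::bind_rows(lapply(comparison_results, function(cr) {
    pw <- paste(sprintf("%s-%s: %.3g", cr$pairwise$group1,
                        cr$pairwise$group2, cr$pairwise$p), collapse = "  ")
    tibble::tibble(variable = cr$variable, overall_p = cr$p,
                   label = sprintf("KW p = %.3g\n%s", cr$p, pw))
  }))
  p <- ggplot(long, aes(x = .data$cluster, y = .data$value,
                        fill = .data$cluster)) +
    geom_boxplot(outlier.size = 0.7) +
    geom_text(data = ann, aes(x = -Inf, y = Inf, label = .data$label),
              inherit.aes = FALSE, hjust = -0.05, vjust = 1.2, size = 2.8) +
    facet_wrap(~variable, scales = "free_y", ncol = 2) +
    scale_fill_brewer(palette = "Set1", guide = "none") +
    labs(x = "Cluster", y = NULL,
         title = "Cluster comparisons: nonparametric ANOVA") +
    theme_minimal(base_size = 10)
  files <- save_figure(p, out, long, width = 9, height = 7)
  invisible(list(data = long, annotations = ann, plot = p, files = files))
}
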