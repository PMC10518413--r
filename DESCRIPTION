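Package: glucodens
Title: Glucodensity Analysis of Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distributional analysis of continuous glucose monitoring (CGM)
    data. Represents each subject's glucose readings as a kernel-density
    "glucodensity", compares subjects with the 2-Wasserstein distance between
    their quantile functions, clusters subjects by k-medoids on the resulting
    distance matrix, and relates clusters to baseline C-peptide and
    time-in-range metrics with nonparametric tests. Includes conventional
    glycemic metrics (time in/above/below range, mean, CV), ambulatory glucose
    profile and lasagna-plot visualizations, an ANCOVA-based treatment-effect
    analysis on time in range, and a synthetic CGM cohort generator with
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    cluster,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
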