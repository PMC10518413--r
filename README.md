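# glucodens

Distributional ("glucodensity") analysis of continuous glucose monitoring
(CGM) data in R, for biostatisticians and clinical researchers working with
wearable glucose sensors — for example in trials of new-onset type 1
diabetes, where residual beta-cell function (baseline C-peptide) is the
biomarker of interest.

## What it does

A CGM device records interstitial glucose Y(t) every few minutes, for days
to months per subject, with gaps and device errors. Instead of reducing a
wear period to a handful of scalars, `glucodens` represents each subject by
the **glucodensity** — the probability density f(s) of their glucose values,
estimated by a Gaussian kernel density estimator

    f̂(s) = (1/m) Σᵢ K_h(s − yᵢ),   K_h(u) = exp(−u²/2h²) / (h√(2π)),

with Silverman's rule for the bandwidth h by default. Subjects are compared
in the 2-Wasserstein geometry: for distributions on the line,

    d_W2(f₁, f₂)² = ∫₀¹ (F₁⁻¹(p) − F₂⁻¹(p))² dp,

the L² distance between quantile functions (units: mg/dL). The package then

- validates raw CGM records (plausibility flagging, modal sampling
  interval, the 70%-of-expected-readings daily *coverage* metric);
- computes conventional glycemic metrics — time in range (TIR, 70–180
  mg/dL inclusive), time above/below range, mean, SD, CV — overall and per
  study day;
- builds per-subject glucodensities, CDFs and quantile functions on shared
  grids, and the pairwise 2-Wasserstein distance matrix;
- clusters subjects by k-medoids (PAM) on that matrix, with silhouette-based
  selection of k and an average-linkage alternative;
- compares clusters on C-peptide and TIR/TAR/TBR with Kruskal–Wallis and
  pairwise Wilcoxon rank-sum tests (raw and Benjamini–Hochberg-adjusted p);
- supports treatment-effect analysis on TIR: paired and Welch t-tests on
  change from baseline, the ANCOVA `TIR₁ = μ + α·δ + β·TIR₀ + ε`, and
  per-subject paired pre/post Wasserstein distances;
- renders the standard displays (lasagna plot, ambulatory glucose profile
  panels, dynamic daily-TIR panels, clustered density/CDF panels, annotated
  cluster boxplots), each with a `.data.csv` sidecar of the exact numbers
  drawn;
- ships a synthetic CGM cohort generator with latent glycemic phenotype
  classes, circadian and meal dynamics, AR(1) sensor noise, wear gaps,
  device errors and class-linked C-peptide — plus ground truth, so the whole
  pipeline is testable end to end.

## Worked example

```r
library(glucodens)

coh <- simulate_cohort(cohort_config(seed = 7))   # 30 subjects, 3 classes
rec <- flag_invalid(coh$records)
#> flagged 4172 of 140746 records (2.96%) as invalid

head(cohort_summary(rec), 4)
#>   subject_id span_days coverage_days n_valid n_flagged
#> 1 S001            13.0            12    3541       104
#> 2 S002            27.0            22    6692       204
#> 3 S003            21.0            18    5096       160
#> 4 S004            18.0            17    4842       141

D <- pairwise_distance_matrix(cohort_quantiles(rec))
k <- select_k(D, seed = 7)                        # silhouette choice: 3
a <- cluster_glucodensities(D, k, seed = 7)
#> <cluster_assignment> k = 3  sizes: 13/6/11  cost = 202.52
#>  medoids: S013, S021, S027
cohort_truth_ari(coh$truth, a)
#> [1] 1

covtab <- merge(coh$covariates, summary_metrics(rec), by = "subject_id")
compare_clusters_by_variable(a, covtab)$c_peptide
#> <comparison_result> c_peptide : Kruskal-Wallis H = 17.15 , p = 0.000189
#>   group1 group2            p       p_adj
#> 1      1      2 0.0007336812 0.002201044
#> 2      1      3 0.0107967877 0.010796788
#> 3      2      3 0.0041785576 0.006267836
```

The summary table reports each subject's wear span, days meeting the 70%
coverage standard, and valid/flagged record counts. The clustering recovers
the three planted glycemic phenotypes exactly (adjusted Rand index 1), and
the clusters differ clearly in baseline C-peptide — the qualitative pattern
this kind of analysis is designed to expose. `run_pipeline(run_config(...))`
(or `inst/scripts/glucodens-run.R`) executes the same chain as one call and
writes every table, figure and a `manifest.json` into an output directory.

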