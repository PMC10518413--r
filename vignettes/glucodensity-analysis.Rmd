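---
title: "Glucodensity analysis of CGM data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucodensity analysis of CGM data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucodens)
```

## The statistical object

A CGM wear period gives a dense, irregular sample y₁, …, y_m of a subject's
glucose process Y(t). The *glucodensity* view treats the occupation measure
of that process — the distribution of glucose values over the wear period —
as the unit of analysis: F(s) is the fraction of wear time spent at or below
s mg/dL, and f(s) = F′(s) is its density. This deliberately discards the
temporal ordering of readings in exchange for an object that is comparable
across subjects with very different wear durations, and that retains the
full shape of glycemic exposure (location, spread, asymmetry, tails) rather
than a few scalar summaries.

`estimate_glucodensity()` estimates f with a Gaussian-kernel KDE,
f̂(s) = (1/m) Σ K_h(s − yᵢ). The readings are serially dependent (5-minute
sampling, strong autocorrelation), which affects the *efficiency* of the KDE
but not its target; we treat the sample as identically distributed draws
from the occupation distribution, the standard working assumption for this
representation. The kernel is Gaussian because closed-form oracles
(single-kernel values, Gaussian CDFs and quantiles) then exist for testing,
and because the estimate is infinitely smooth, which the quadrature below
exploits.

Distances between subjects use the 2-Wasserstein metric. On the real line
it reduces to the L² distance between quantile functions,
d²(f₁, f₂) = ∫₀¹ (F₁⁻¹(p) − F₂⁻¹(p))² dp, so no transport problem is ever
solved numerically: `wasserstein2()` integrates the squared difference of
two quantile functions over a shared probability grid. The metric is in
glucose units (mg/dL) and satisfies the translation identity — shifting a
subject's readings by c mg/dL moves them exactly c away from their old
representation — which is both clinically interpretable and a sharp unit
test.

## Which representation feeds the distances

Two quantile representations are available. `mode = "empirical"` uses
type-7 sample quantiles: exact, smoothing-free, and the default for
distance computations, because the Wasserstein distance between raw
samples needs no bandwidth choice and is reproducible without tuning.
`mode = "kde"` inverts the KDE-based CDF by monotone interpolation; it is
used for the density/CDF figures and offered for distances when smoothed
representations are preferred. For the large m typical of CGM (thousands of
readings) the two converge; the test suite checks that their sup-norm gap
on p ∈ [0.05, 0.95] shrinks as m grows.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| plausibility range | [39, 401] | mg/dL | reporting limits of common sensors; readings outside are device errors |
| target range | [70, 180] | mg/dL | consensus glycemic target; TIR inclusive, TAR/TBR strict |
| coverage fraction | 0.7 | — | consensus minimum fraction of expected daily readings for a usable day |
| bandwidth h | Silverman | mg/dL | 0.9·min(sd, IQR/1.34)·m^(−1/5); exposed as a first-class argument since any rule is defensible |
| density grid | 512 pts on ≥[40, 400] | mg/dL | spans the sensor range; auto-extended 6h beyond the data so kernel mass is captured |
| probability grid | 999 pts, 0.001–0.999 | — | shared across the cohort; 2‰ resolution keeps quadrature error far below sampling noise |
| k (clusters) | silhouette over 2–6 | — | selection rule made explicit; `k = 3` reproduces the three-phenotype structure directly |
| restarts | 20 | — | PAM local optima are cheap to escape at n ≈ 30 |

TIR uses inclusive bounds ([70, 180]) while TAR/TBR are strict, so the
three fractions partition every sample; the third fraction is derived from
the other two with a grouping that makes `tir + tar + tbr == 1` hold
*exactly* in floating point (each value stays within 1 ulp of its count
ratio). Days are UTC calendar days throughout; the inputs are UTC
timestamps and no day boundary is otherwise defined. Duplicate
(subject, timestamp) rows keep the first occurrence with a warning.
Expected readings per day derive from each subject's modal inter-reading
gap, not a global constant, so mixed 1–15-minute devices coexist in one
cohort.

## Clustering

`cluster_glucodensities()` is partitioning-around-medoids on the distance
matrix: medoids are actual subjects (interpretable as "prototypical
glucodensities"), only the matrix is needed, and the algorithm is
deterministic given its seed. The first start is deterministic
(most-central subject, then max-min separation seeding); remaining starts
are random; each start runs steepest-descent swaps to a local optimum with
ties broken toward the lowest subject index. An average-linkage
agglomerative alternative (`method = "average"`) is provided for
sensitivity analysis. A reference PAM implementation serves as an
independent cross-check in the test suite, never as the implementation.

## Inference across clusters

Cluster comparisons are rank-based: Kruskal–Wallis omnibus test (chi-square
reference distribution by default, matching standard software at any n; a
Monte-Carlo permutation p is available and agrees with the chi-square
approximation to within a few hundredths at n ≈ 30) and pairwise two-sided
Wilcoxon rank-sum tests, exact when both groups have ≤ 8 observations and
no ties. The pairwise test choice is a design decision — rank-sum tests
keep the pairwise and omnibus procedures in the same family. These
analyses are exploratory, so raw pairwise p-values are primary and
Benjamini–Hochberg-adjusted values are always reported alongside.

For treatment effects on TIR, `ancova_tir()` fits
TIR₁ = μ + α·δ + β·TIR₀ + ε by OLS and tests H₀: α = 0; with a single arm
present it degenerates gracefully to simple regression on baseline
(α undefined). `change_from_baseline_tests()` gives the per-arm paired
t-tests and the Welch two-sample t-test on deltas.
`paired_wasserstein()` quantifies each subject's pre/post distributional
change in mg/dL; it is the same integral as the cohort distance, reported
per subject.

## The synthetic cohort generator

The study conditions the generator emulates: ~30 subjects at 5-minute
sampling; three latent glycemic phenotypes with class means 110/150/200
mg/dL and overall within-subject SDs of roughly 25/35/50, mixed in
proportions 13/11/6 at n = 30 (largest-remainder counts, so every class is
present); class-linked lognormal baseline C-peptide with medians ordered
0.90/0.55/0.30 nmol/L (best-controlled class highest — about a 3-SD
log-scale gap between extremes); ~3% device-error readings (injected as
implausible values carrying the invalid flag); day-level wear gaps
(15%/day chance of a 2–12 h gap, 5%/day chance of a fully missing day);
and per-subject follow-up drawn uniformly from 7–28 days. Follow-up,
noise, separation and missingness are all configurable, but these defaults
*are* the reference conditions and the tests run against them.

Within a subject, glucose is baseline (plus a N(0, 8²) between-subject
offset) + a circadian sine (trough near 02:00) + three daily meal
excursions (times jittered ±45 min, lognormal peaks, exponential decay) +
AR(1) noise with stationary marginal SD as configured (φ = 0.8 at 5-minute
sampling), clipped to the sensor range [40, 400]. All randomness flows
from one root seed through deterministically derived child seeds, so a
cohort reproduces byte-identically.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: informative (glucose-dependent)
missingness, sensor drift and calibration error, insulin dosing and
exercise dynamics, day-to-day regime changes (illness, disease
progression), and follow-up heterogeneity beyond a uniform range (real
cohorts can span 4–500+ days). Missingness is missing-completely-at-random
by default because assessing missingness bias is explicitly out of scope.

## Numerical choices

- **Quadrature.** Densities are evaluated on a uniform grid and integrated
  by the trapezoid rule. Because the integrand is a Gaussian mixture whose
  derivatives vanish at the (extended) grid ends, the total-mass error is
  far below 1e-6 at 512 points; the *cumulative* CDF error is larger at
  interior points, so tests that compare against closed-form CDFs at 1e-6
  use finer grids.
- **Normalization.** `estimate_glucodensity()` never renormalizes — unit
  mass is a checked property, not an enforced one. `density_to_cdf()` does
  renormalize its terminal value to 1 (and enforces monotonicity) because
  downstream inversion requires an exact CDF.
- **Inversion.** KDE-mode quantiles come from monotone linear
  interpolation of the strictly increasing part of the CDF, with flat
  extrapolation beyond it.
- **Wasserstein integral.** The trapezoid integral over the probability
  grid is normalized by the grid's probability span, so a pure location
  shift of c yields exactly c despite the grid stopping at 0.001 and
  0.999.
- **Degenerate inputs.** All-identical samples: Silverman's rule errors
  (an explicit bandwidth is required); Kruskal–Wallis returns H = 0,
  p = 1; constant baseline TIR is a rank-deficiency error in the ANCOVA.
  Cohorts where every record is flagged invalid raise "no valid data"
  rather than returning empty summaries.
- **Determinism.** Clustering restarts, the permutation test and the
  generator all consume explicitly derived seeds; reruns with the same
  configuration hash-match their artifacts.

## Problem sizes in the test suite

The suite exercises the defaults at the scale the methods are meant for:
full 30-subject cohorts (7–28 days each) for clustering recovery (20
replicate cohorts), metric-axiom checks over all 4,060 subject triples,
1,000-replicate calibration of the omnibus test, 200-replicate power
checks of the C-peptide comparison, and 500-replicate ANCOVA recovery at
n = 60. Structural tests use smaller 9–12-subject cohorts with 3–6-day
follow-up, which is ample for contract checks. These sizes are the
package's own validation design choices.

## Known limitations

- No boundary correction at the physiological limits: kernel mass can leak
  below 40 mg/dL for subjects with substantial hypoglycemia; the
  plausibility bounds plus grid extension keep the effect small but it is
  not corrected.
- The bandwidth rule matters near the tails; results that depend on tail
  quantiles (p < 0.01) should prefer empirical mode or report sensitivity
  to h.
- The occupation-measure view discards temporal structure by design;
  dynamics must come from the daily-TIR and AGP displays, not from the
  densities.
- Fréchet means of glucodensities, distribution-level two-sample tests and
  Wasserstein–Fréchet regression are out of scope; the package stops at
  per-subject distances, clustering and rank-based cluster inference.
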