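---
title: "Methods: weighted connectome topology, inference and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome topology, inference and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunable parameters with their defaults and the reasons
behind them, what the synthetic-cohort generator emulates (and what it does
not, hence what a green test does and does not establish), the numerical
choices, and known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The data model

One subject's structural connectome is a symmetric, non-negative,
zero-diagonal `n × n` matrix of streamline counts over an ordered
parcellation (bundled default: 68 Desikan–Killiany cortical regions +
14 subcortical structures, `n = 82`). At the I/O boundary the loader
enforces symmetry to within `1e-9` (averaging below that, erroring above:
tractography emits symmetric counts, and silently symmetrizing truly
asymmetric data would mask upstream bugs), zeroes the diagonal, and rejects
negative or non-finite entries. Matrices are delimited text (comma or tab,
auto-detected), with an optional header whose order must match the atlas.

The cortical-to-network lookup (Yeo-7 systems + a subcortical class) ships
as a static table. The projection of a vertex-wise functional parcellation
onto anatomical regions has no single canonical answer; a fixed, documented
modal assignment makes every network census in this package reproducible.

## 2. Topology metrics and the sparsity sweep

All metrics operate on *weighted* graphs; thresholding selects edges but
never binarizes them.

* **Normalization.** Weights are divided by the matrix maximum before
  metric computation (`normalize = "max"`, the default; `"none"`
  available). The Onnela clustering coefficient assumes weights in
  `[0, 1]`, and with this scaling global/local efficiency and clustering
  are all bounded by 1. Whether raw streamline counts "should" be
  normalized further (e.g. by region volume) is an open question in the
  field; the loader accepts raw counts and leaves normalization explicit.
* **Proportional threshold.** At sparsity `S` the strongest
  `floor(S·n(n−1)/2)` edges are retained. Ties at the cut weight break by
  ascending (row, column) upper-triangle index — an arbitrary but
  deterministic rule, chosen for bit-reproducibility across platforms.
* **Distances.** Edge length is `1/w` (the standard toolbox convention:
  stronger connections are shorter). Unreachable pairs are `+Inf`.
* **Characteristic path length** averages finite `d_ij` only and reports
  the count of excluded infinite pairs. At sparse thresholds graphs can
  disconnect; exclusion keeps the statistic finite while the count
  preserves auditability. The verbal definition "mean number of
  connections on the shortest path" reads as a binary hop count, yet the
  analysis is weighted; both are implemented
  (`path_length = "weighted"` default, `"hops"` optional).
* **Global efficiency** uses the Latora–Marchiori form with `1/∞ = 0`, so
  disconnection reduces efficiency rather than being dropped.
* **Clustering** is the Onnela geometric-mean form; `C_i = 0` for degree
  `< 2`.
* **Local efficiency** of node `i` is the global efficiency of the
  subgraph induced by `i`'s neighbours with their retained original
  weights (node `i` removed). This matches the verbal definition directly;
  the alternative that reweights paths by the index node's own edge
  weights is not implemented.
* **Sweep and AUC.** The default grid is `S = 0.05 … 0.30` in steps of
  0.01, read inclusively (26 levels; the strict open-interval reading with
  24 levels is available via `default_thresholds(inclusive = FALSE)`).
  Each metric curve is collapsed by the trapezoid rule on the raw
  threshold axis (grid width 0.25). Non-finite path-length values
  propagate as gaps and the AUC integrates finite segments only, with the
  gap count recorded.

The sweep is computed by a single C++ pass that sorts edges once and adds
them incrementally across the ascending grid; the test suite asserts its
equality with the composition of the R-level operations, and shortest
paths are verified against an independent Floyd–Warshall oracle (and
igraph) on random graphs.

## 3. Univariate inference

Group contrasts use the pooled-variance (Student) t test — not Welch —
because the reference df arithmetic (`df = 61` for 37 + 26) implies pooled
variances; ANCOVA is OLS with treatment-coded categorical covariates.
Treatment-response regressions use signed percent change
(`100·(w6 − w0)/w0`; negative = improvement), so beneficial predictors
get negative slopes. Responders are defined by a *strict* `> 25%`
reduction: a change of exactly −25% is a non-responder.

FDR control is Benjamini–Hochberg step-up,
`q_(i) = min_{j≥i} p_(j)·m/j`, applied within each research question. The
family size `m` defaults to the number of tests in the family and may be
declared larger (never smaller — a family smaller than the tests it
contains is incoherent, which is why the superficially attractive choice
`m = 63`/`m = 37` from the sample-size sentence of the motivating analysis
is not the default).

Classifier accuracy statistics mirror the standard reporting set: exact
Clopper–Pearson 95% CI (beta-quantile form), no-information rate
`100·max(counts)/sum(counts)`, one-sided exact binomial tail against the
NIR, and sensitivity/specificity/PPV/NPV from the 2×2 table.

## 4. Multivariate models

No SVM implementation ships with the supported runtime, so the package
implements the linear models itself: L1-hinge-loss soft-margin
classification and ε-insensitive regression (`ε = 0.1`), solved in the
dual by cyclic coordinate descent (liblinear-style) to tolerance `1e-6`,
with the bias as an augmented constant feature. The solver is
deterministic (no randomized sweeps) and is verified in tests against
margin geometry (`|w| = 1` for unit-separated points) and slope recovery
inside the ε-tube. Only linear kernels are implemented; an RBF `sigma`
request raises an explicit not-implemented error.

Evaluation is leave-one-out cross-validation. Standardization (z-scoring)
happens *inside each training fold only* and is applied to the held-out
subject with training statistics — necessary because streamline-derived
features span orders of magnitude, and leaving it outside the fold would
leak. Cost tuning shares the single LOOCV loop (the apparent procedure of
the reference analysis): every candidate `C` gets a full LOOCV, the best
held-out score wins (accuracy for classification, RMSE for regression;
`tuning_metric = "rmse"` applies RMSE on a ±1 coding to classification
too, the literal reading of the reference text), ties break toward the
smallest `C`. The default grid is `2^-10 … 2^5` plus 0.218 and 10.9 so the
reference models' selected costs are always reachable. Internally the
ascending grid is solved with warm starts (the dual solution at one cost
seeds the next), making the whole grid barely more expensive than one fit.

Significance uses permutation testing: the outcome is permuted `B` times
(default 1000; the pipeline default is 200 and scaled test configurations
use 99), the *entire* tuning + LOOCV pipeline reruns per permutation, and
`p = (1 + #[perm ≥ obs]) / (B + 1)`.

Variable importance is model-agnostic: per-feature ROC AUC
(`max(AUC, 1−AUC)` with direction retained; equal to the normalized
Mann–Whitney U, tie-aware) for classification, and a loess smoother
(span 0.75, degree 2) `1 − RSS/RSS₀` score floored at 0 for regression.
Constant features score 0 and are flagged.

## 5. The synthetic cohort: what it emulates, and what it does not

The motivating study's MRI data are not public, so validation rests on a
generator whose stated world is: 37 ADHD + 26 TDC subjects, 82×82
matrices, a *planted* reduction of subcortical connectivity in ADHD, and a
treatment response linearly linked to baseline global efficiency.

Generator structure (all parameters are declared assumptions, exposed in
`simulation_config()`; none is claimed from the motivating paper except
where noted):

* **Geometry and backbone.** Regions get latent 3-D positions; connection
  probability decays exponentially with distance, scaled to a base density
  of 0.35. Which connections exist is decided *once per cohort* (a shared
  anatomical backbone); each subject rewires only 5% of it. Early
  development versions drew each subject's topology independently, which
  made cohort difficulty swing wildly between seeds — independent
  re-drawing of tract existence is not how anatomy works, and the shared
  backbone is both more realistic and statistically stabler.
* **Weights.** Log-normal streamline counts (meanlog 3, sdlog 0.8) around
  a shared cohort template with subject-level jitter (sd 0.4 in log
  space), heavy-tailed like real count matrices. One deterministic
  "anchor" edge between two unaffected homotopic-like regions is fixed at
  6 template SDs above the mean: the strongest homotopic tracts are the
  most reproducible feature of real count matrices, and pinning the
  maximum keeps max-normalization from injecting pure scale noise into
  every between-subject comparison.
* **Planted diagnostic effect.** For ADHD subjects, every edge incident to
  the affected set (bilateral pallidum, putamen, thalamus, caudate — the
  subcortical contributors highlighted by the motivating analysis) is
  multiplied by 0.7 (× small subject-level log-normal jitter). The effect
  is planted on *edges*, so reduced local efficiency must emerge through
  thresholding and the metric code — the generator never touches a metric.
  A side effect worth knowing: because proportional thresholding keeps a
  fixed edge count, attenuated subcortical edges that drop below the cut
  are replaced by extra cortical edges, so ADHD subjects also show
  slightly *higher* efficiency in unaffected regions. This is a real
  consequence of proportional thresholding, not a bug.
* **Phenotypes.** ADHD-RS-IV scores are generated at item level (18 items,
  each 0–3; inattention = items 1–9) and summed, so the 0–54/0–27 bounds
  hold by construction. Baselines: discretized normal (mean 38, sd 7,
  clamped to [20, 54]) for ADHD; [0, 12] for TDC. Percent change for ADHD
  is `−30 + β·(gE_AUC − mean) + N(0, 15)`, discretized through integer
  week-6 scores. The default `β = −68000` per AUC unit was calibrated
  once, before the acceptance tests were frozen, by measuring the
  generator's gE-AUC spread (SD ≈ 1.1e−4) and matching the standardized
  effect implied by the reference regression (`t(34) = −2.76`, i.e.
  `r ≈ 0.43` against the 15-point residual SD ⇒ ≈ 7.5 percentage points
  per SD). Covariates (age 8–17, gender 70/30, dose 0.3–1.2 mg/kg, two
  ADHD subtypes, prior stimulant use 30%) are independent of outcome.
* **Reproducibility.** Each subject has an RNG stream derived from the
  master seed, so enlarging a cohort never perturbs existing subjects.

What the generator does **not** emulate: spatial autocorrelation of
regional effects, site/scanner variation, symptom–topology coupling at
baseline (deliberately null, matching the reference finding), motion or
tractography artefacts, and the actual effect *magnitudes* of the
motivating study (its headline numbers depend on its non-public cohort).
A green end-to-end test therefore establishes that the pipeline can
recover planted effects of plausible size through the full metric → SVM
chain and stays calibrated under the null — not that it reproduces the
study's point estimates.

## 6. Numerical and degenerate-input choices

* Symmetry tolerance `1e-9`; serialization at 15 significant digits so a
  write/load round trip stays within `1e-9` absolutely even for
  counts in the thousands.
* All-zero matrices cannot be normalized (error); thresholding an
  all-zero matrix yields an empty graph; `C_i = 0` and local efficiency 0
  below degree 2; constant features score 0 importance; degenerate
  (constant) metric columns in small cohorts yield NA inference rows
  rather than aborting a family, and FDR runs over the non-NA family.
* Inattention/hyperactivity percent change guards a zero baseline
  subscale with `max(w0, 1)` (totals are ≥ 20 for ADHD by construction,
  but a subscale can be 0 in principle).
* LOOCV ties in cost selection go to the smallest `C` (strongest
  regularization); permutation p uses the `(1 + k)/(B + 1)` estimator so
  it is never 0.

## 7. Known limitations

* The single-loop tuning-plus-evaluation LOOCV reproduces the reference
  procedure but is optimistically biased relative to nested CV; the bias
  is shared by the permutation null (each permutation reruns the same
  tuning), so the permutation p remains honest even though the headline
  accuracy is "tuned".
* The dual coordinate-descent SVM reproduces liblinear-style solutions,
  not kernlab's SMO; solutions agree in `w` (the primal is strictly
  convex) but support-vector sets may differ.
* Loess importance with span 0.75 can be unstable for n near 10 (its
  stated minimum) and for heavily tied features.
* Hop-count path length on weighted graphs ignores the weight structure
  entirely; it exists to document the literal reading, not as a
  recommended analysis.
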