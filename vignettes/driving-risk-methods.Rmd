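---
title: "Driving-risk evaluation from personality traits and event counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driving-risk evaluation from personality traits and event counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverisk)
```

This vignette documents the statistical and numerical choices behind each
stage of the pipeline: what is modeled, which parameters exist, what their
defaults mean, and where deliberate conventions (rounding, boundary
handling, tie-breaking) affect results.

## 1. Questionnaire scoring

The instrument is a 32-item Big Five questionnaire on a 1–5 Likert scale.
The bundled key (`big_five_key()`) partitions the items into extraversion
(6), agreeableness (8), conscientiousness (6), neuroticism (7), and
openness (5); six items (10, 20, 22, 24, 27, 31) are reverse-coded as
`6 - v` before averaging. `score_responses()` accepts a single response
vector or a respondent-by-item data frame and returns dimension means.
Scoring is a plain mean of (recoded) item responses, so a respondent
answering 3 everywhere scores exactly 3 on every dimension — a fixed point
used as a test oracle. The key also carries reference per-item means and
standard deviations from a 40-driver fleet sample; averaging those item
means per dimension reproduces the published dimension means to two
decimals (`dimension_means_from_item_means()`).

## 2. Event counts

Counts of six aberrant behaviors — exceeding the speed limit, abnormal
stay, hard acceleration, driving overtime, excessive engine rotation
speed, hard deceleration (`behavior_names()`, fixed order) — come from one
of two sources.

### 2.1 Rule-based detection from telemetry

`detect_events()` applies explicit threshold rules to a 1 Hz trace with
columns `timestamp`, `speed_kmh`, `rpm`, `x_m`, `y_m`. An *episode* is a
maximal contiguous run of violating samples; each episode counts once.
Defaults (`rule_config()`):

* **Speeding**: speed > 87 km/h sustained for more than 90 samples.
* **Abnormal stay**: speed < 5 km/h for more than 300 s while the maximal
  pairwise planar distance within the episode stays under 50 m. A cheap
  bounding-box pre-check avoids the exact O(n²) distance computation
  except in near-threshold cases.
* **Hard acceleration**: speed gain of more than 30 km/h within a 5 s
  window; overlapping windows are merged into one episode.
* **Hard deceleration**: per-second speed drop exceeding 13 km/h for at
  least 3 consecutive steps.
* **Driving overtime**: a continuous run of nonzero speed longer than
  4 hours.
* **Excessive rotation speed**: speed < 85 km/h with rpm > 1500 for at
  least 3 consecutive samples (low gear at high revs).

A timestamp step different from 1 s marks a session boundary; rules never
span the gap, so detection is exactly compositional over disjoint
sessions. `counts_from_events()` tabulates episodes per driver and
behavior.

### 2.2 Synthetic cohorts

`generate_cohort()` draws traits and counts for `n_drivers` drivers:

* Traits are truncated normals on [1, 5] (rejection sampling) with means
  `c(3.41, 3.57, 3.56, 2.77, 3.35)` and SDs
  `c(0.67, 0.52, 0.45, 0.44, 0.53)` — the reference fleet's dimension
  aggregates.
* Counts are negative binomial with a log link:
  `mu_b = baseline_b * exp(sum_j L[b, j] * (trait_j - mean_j))`, variance
  `mu + dispersion * mu^2`. Baselines default to the reference per-driver
  averages over a 560 h (three-month) window:
  `c(1676, 143, 11, 6, 573, 35)`.
* The default loading matrix is zero (a null generator: counts carry no
  trait signal), and the default `dispersion` of 1 gives heavily
  overdispersed, right-skewed counts. These defaults are the conditions
  under which the no-signal properties in the test suite are stated.

**Calibration.** `calibrate_to_target_correlations()` chooses loadings so
that the cohort's trait–behavior Pearson correlations match a target
matrix (e.g. `reference_trait_behavior_correlations()`). One subtlety
dominates the design: under the log link, the correlation between a trait
and its count is *non-monotone* in the loading — it rises, peaks, and then
falls as the lognormal mixing variance swamps the linear signal. The
attainable peak also depends strongly on the dispersion: at dispersion 1
no single-trait loading can push the correlation much past ~0.5, so
targets like 0.835 are structurally unreachable. The calibrator therefore
(a) computes the attainable ceiling in closed form and fails fast with an
informative error when a target row exceeds it, and (b) inverts the
closed-form correlation on its rising branch for the initial loadings,
followed by a damped empirical refinement. For fleet-like cohorts with
strong planted signal we use `dispersion = rep(0.02, 6)`; counts remain
overdispersed and right-skewed because the trait-driven lognormal mixing
itself supplies extra-Poisson variation.

## 3. Natural-breaks classification

`fit_breaks(values, k)` computes the Jenks natural-breaks partition: among
all contiguous partitions of the sorted values into `k` classes, the one
minimizing the sum of squared deviations from class means (SDCM). Two
solvers are provided:

* `method = "dp"` (default): exact dynamic programming over the distinct
  values with tie multiplicities as weights, O(k·m²) for m distinct
  values. Tied values are never split across classes.
* `method = "greedy"`: the classical iterative exchange heuristic
  (quantile initialization, adjacent boundary moves while SDCM improves),
  kept for transparency; it agrees with the DP on well-separated data but
  is not guaranteed optimal.

Fit quality is the goodness of variance fit, `GVF = 1 - SDCM/SDAM`, with
the identity `SDAM = SDCM + SDBC` (total = within + between) holding to
numerical precision for any contiguous partition (`gvf_of()`). A
degenerate sample with zero total deviation is defined to have GVF 1.

`select_k_elbow()` picks the class count: compute GVF for k in 2..7 and
take the smallest k whose *next* marginal gain falls below `min_gain`
(default 0.01). On the reference risk-index GVF profile
`(0.617, 0.887, 0.947, 0.971, 0.976, 0.987)` this selects k = 5, the 5→6
gain being exactly 0.005. If no gain falls below the threshold, the
largest k is returned with a warning.

## 4. Risk index and levels

`build_scheme(counts, k_behavior = 4, k_risk = 5)` fits per-behavior
breaks, assigns each driver a class 1..k per behavior, sums the six
classes into the risk index (range 6–24 for k = 4), and Jenks-partitions
the indices into `k_risk` risk levels. Conventions, all exercised by
tests:

* Class upper boundaries are **inclusive**: a count exactly on a boundary
  stays in that class.
* Out-of-sample values falling in a gap between adjacent class intervals
  are assigned by **nearest boundary**, splitting the gap at its midpoint;
  values beyond the extremes clamp to classes 1 and k.
* If a count column has fewer distinct values than `k`, the per-column k
  is capped at the distinct-value count; a cohort with identical counts
  everywhere collapses to one class per behavior and index 6 for everyone.
* The index is monotone in every count, and an all-zero driver always
  scores the floor of 6 — the quantity recomputed by
  `scripts/acceptance.R`.

## 5. Neural-network prediction

`train_network()` implements a single-hidden-layer perceptron from
scratch: logistic hidden units with subtractive thresholds, softmax output
with cross-entropy for classification, identity output with mean squared
error for regression. Training is full-batch gradient descent with
momentum 0.9, learning rate 0.05, up to 5000 epochs, stopping when the
loss improvement drops below 1e-6; inputs are standardized by training
mean and SD; initial weights are N(0, 0.3²) under a dedicated seed so fits
are reproducible. Analytic gradients are validated against central finite
differences in the test suite.

`model_spec(id)` defines the eight models: 1–6 classify the six behavior
classes from the five traits, 7 regresses the risk index, 8 classifies the
risk level. Regression predictions are *reported* after half-up rounding
and clamping to the attainable index range [6, 24]; classification argmax
ties break to the lowest class.

`run_experiments()` runs the repeated-experiment protocol: in each of 4
experiments, a stratified split sends ceiling(0.75·n_s) of every stratum
to training (a stratum of size (15, 16, 6, 3) yields training sizes
(12, 12, 5, 3); singleton strata go to training so no class is unseen),
and metrics are computed on the held-out quarter: accuracy for
classification; MAPE and R² (squared Pearson correlation) for regression.
Averages over experiments are kept exact and displayed with half-up
rounding — the convention under which a 72.5 % average prints as 73 %.
MAPE is banded gap-free: [0, 10) highly accurate, [10, 20] good,
(20, 50] reasonable, above 50 inaccurate; 10.2 % is "good".

## 6. Sensitivity and ablation

`sensitivity_ratios()` implements mean substitution: each input in turn is
fixed at its training mean (zero on the standardized scale), the training
loss is re-evaluated, and the ratio of substituted to original loss ranks
the inputs (rank 1 = largest ratio = most influential). A disconnected
input has ratio exactly 1; in the linearized small-weight limit the
ordering reduces to |weight| × input SD. `sensitivity_table()` averages
ratios over the repeated experiments and adds the Spearman rank
correlation (with a t-approximation p-value and `**`/`*` flags) between
each trait and the target over the full cohort. `ablation_compare()`
retrains a model with one trait removed, on identical splits and seeds,
and reports the per-experiment and mean accuracy deltas.

## 7. What the generator does and does not emulate

The synthetic cohorts reproduce the *structure* the methods need — Likert
traits with realistic means and spreads, overdispersed right-skewed
counts, a controllable trait→behavior correlation pattern, and exposure
bookkeeping — so that every algorithm can be exercised end to end and
planted signal can be verified as recoverable (on calibrated n = 200
cohorts the dominant planted factor is recovered as sensitivity rank 1 and
the classifier beats the majority baseline in the vast majority of seeds).
They do not emulate route or schedule heterogeneity, weather and traffic
confounders, within-driver temporal dynamics, or measurement error in the
questionnaire beyond item-level noise; headline accuracies on real fleets
cannot be reproduced from synthetic data and are not claimed.

## 8. Reproducibility

All randomness flows from explicit seeds: the cohort seed drives trait and
count draws, each experiment has its own split/initialization seed, and
`run_pipeline()` writes a manifest recording the seed and a configuration
hash alongside the CSV reports. Re-running a pipeline with an identical
configuration reproduces every report byte for byte.
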