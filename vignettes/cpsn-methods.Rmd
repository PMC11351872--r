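---
title: "Methods: building and validating clinical patient similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating clinical patient similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, every tunable parameter with its default and rationale,
what the synthetic-cohort generator does and does not emulate, and the
numerical conventions that make results reproducible across
implementations.

## 1. The model

A cohort is described by a *schema*: an ordered list of $M$ clinical
variables, each continuous, binary, or categorical. Encoding maps every
patient to a binary vector with one block per variable:

* A **categorical/binary** variable with $N_i$ declared states contributes
  $N_i$ indicator features. When the variable may be unobserved, the
  literal state `"NA"` is one of those states — missingness is treated as
  information, never imputed. This is a deliberate modeling stance: in
  routine oncology data the fact that a test was not ordered is itself
  correlated with the clinical situation, and any imputation would
  manufacture agreement between patients whose records are silent.
* A **continuous** variable is discretized into four quartile bins fitted
  on its non-missing values, plus an `"NA"` state when it may be
  unobserved — so it contributes 4 or 5 features. Quartile (rather than
  equal-width) partitioning gives every bin the same occupancy on the
  training cohort, so no bin dominates the distance.

Each block holds exactly one active indicator per patient, hence every row
sums to $M$ and the squared Euclidean distance between two patients is
$2q$, with $q$ the number of variables on which they differ. All variables
therefore contribute equally (each at most 2 to the squared distance);
the package deliberately applies no feature weighting, accepting possible
redundancy between correlated variables as the price of a model that needs
no labels or expert weights. The full symmetric distance matrix *is* the
patient similarity network; at cohort scales of a few thousand patients it
is materialized densely, since clustering and neighbour retrieval both
need the complete metric.

The built-in gastric-cancer schema (`gc_schema()`) has 12 continuous and
25 binary/categorical variables. Its reconciliation with a 143-feature
encoding requires every continuous variable to carry an `"NA"` state
($12 \times 5 + 83 = 143$); the package therefore sets
`allow_missing = TRUE` for all of them, which is also the defensible
clinical reading (laboratory panels are never complete in practice).

## 2. Encoding conventions

Where a convention is arbitrary, it is fixed and documented so another
implementation can reproduce results bit for bit:

* **Quantile definition.** Interior cut points $Q_1, Q_2, Q_3$ are
  linear-interpolation quantiles (R type 7), the most widespread default.
* **Bin sides.** Bins are upper-inclusive: $x \le Q_1$ is `Q1`,
  $Q_1 < x \le Q_2$ is `Q2`, etc. Values outside the training range clamp
  into the outer bins, so a fitted encoder can score any new patient.
* **Missing values** are excluded from quantile fitting and contribute
  only to the `"NA"` state.
* **Ties.** With heavily tied data, cut points may coincide; bins are
  still emitted in order and may be empty. Fitting fails only when a
  continuous variable has fewer than 4 distinct values, where quartile
  binning is meaningless.
* **Unseen states** at transform time are an error by default (the safe
  behaviour for clinical data); an explicit `lenient = TRUE` maps them to
  the variable's `"NA"` feature when it has one.

## 3. Subgrouping and the choice of K

K-means is run directly on the one-hot matrix with ordinary Euclidean
Lloyd updates (centroids are within-cluster state-frequency vectors), by
k-means++ seeding and the best of `n_init = 10` restarts per K; an
emptied cluster is reseeded at the point farthest from its assigned
centroid. Labels are renumbered by descending cluster size (ties by first
patient index), which makes `Cluster_1` always the largest subgroup and
the labeling invariant to restart order. The scanned range defaults to
$K = 2..10$ and is configurable.

Two unsupervised selection rules are provided:

* **Elbow** (`elbow_select()`): the chosen K maximizes the discrete
  second difference $W(K{-}1) - 2W(K) + W(K{+}1)$ of the within-cluster
  sum of squares — a formalization of "the point of maximal curvature"
  that needs no human reading of the curve. A flat or linear curve has no
  elbow; the smallest scanned K is returned with a warning. The Kneedle
  algorithm would be a reasonable alternative formalization; it is not
  the default here.
* **Gap statistic** (`gap_statistic()`):
  $\mathrm{Gap}(K) = \tfrac1B \sum_b \log W^{ref}_b(K) - \log W(K)$ with
  $s_K = \mathrm{sd}_b(\log W^{ref}) \sqrt{1 + 1/B}$, choosing the
  smallest K with $\mathrm{Gap}(K) \ge \mathrm{Gap}(K{+}1) - s_{K+1}$.
  The classical uniform-box reference is meaningless for one-hot blocks
  (it would break the one-indicator-per-block structure), so reference
  datasets resample each variable's state independently from its
  empirical marginal: block structure preserved, between-variable
  association destroyed.

All clustering is performed in the full feature space. The 2-D/3-D map
produced by `embed_psn()` is a principal-coordinates (classical metric
MDS) projection of the distance matrix, used for visualization only —
cluster colours on such maps always come from upstream clustering, never
from the embedding.

## 4. Clinical validation

* **Kaplan–Meier** curves are computed per cluster with the standard
  product-limit estimator; at tied times deaths precede censorings.
  Follow-up time is treated as months throughout.
* The **k-sample log-rank test** accumulates observed-minus-expected
  event counts over the ordered distinct event times with the
  hypergeometric covariance; the statistic is referred to
  $\chi^2_{k-1}$. A network whose clusters separate overall survival at
  $p < 0.05$ is called *clinically valid* (a cPSN). The estimator and
  test are implemented in the package from the standard formulas so the
  repository is self-contained and oracle-testable; the test suite
  cross-checks them against `survival::survfit()`/`survdiff()` and a
  permutation oracle.
* **Chi-square association** between cluster membership and categorical
  markers uses the Pearson statistic without continuity correction,
  significance at $p < 0.01$; expected counts below 5 raise a flag on the
  result rather than an error. Missing marker values form their own
  `"NA"` row by default, consistent with the encoding philosophy, with a
  `drop_na` option since tabulation of NA-heavy markers is genuinely
  ambiguous. No multiple-testing correction is applied — raw p-values at
  fixed thresholds are reported, and the thresholds are part of the
  method definition.
* `quartile_groups()` supports the conventional comparators (e.g. age
  quartiles of the whole cohort) against which the network stratification
  can be benchmarked.

## 5. The synthetic-cohort generator

The generator exists so that every stage is testable without patient
data. `default_gc_config()` plants $k_{true} = 5$ equally likely
subgroups in a cohort whose *cohort-wide* marginals match the published
baseline table of the reference gastric-cancer cohort: categorical state
frequencies equal the printed head counts over 1000, missingness rates
equal the printed NA fractions (e.g. 0.672 for Lauren type, 0.630 for
dMMR), and continuous variables match the printed medians and ranges.

**Cluster tilt.** For each variable, the marginal distribution over its
states (in declared order) is cut into $k_{true}$ equal-probability
slices of its CDF; cluster $c$ draws from
$(1-s)\,p_{marginal} + s\,p_{slice(c)}$, where $s \in [0,1]$ is the
separation. Because the equal-weight mixture of the slices reconstructs
the marginal exactly, calibration holds *exactly in expectation at any
separation* — observed deviations are pure binomial sampling error, which
is what `check_calibration()` tests (±0.05 at $n = 1000$ is about three
standard errors). Slices are cyclically permuted across variables so that
no cluster is systematically the "low" group on every variable; the same
mechanism drives continuous variables through their quantile functions,
which aligns the planted structure with the quartile bins the encoder
will fit. The default separation of 0.6 plants structure strong enough to
be recoverable through the full pipeline while leaving a 40% marginal
admixture of noise within every cluster; at $s = 0$ the generator
produces a structureless cohort used for null checks.

**Distributions.** Serum tumor markers and tumor size (AFP, CA-series,
CEA, max diameter) are log-normal — their printed ranges span 2–3 orders
of magnitude — with `meanlog` at the printed median and `sdlog` set so
the plausible range matches the printed one; age, BMI, blood counts and
expression fractions are normal with the printed median as mean and
(range/6) as SD. Draws are clamped to the printed ranges. Continuous
variables get 5% missingness by default: the reference table prints no
missing counts for them, but complete laboratory panels are unrealistic,
and the schema's 143-feature reconciliation presumes they can be missing.

**Missingness** is independent of cluster (MCAR) by default. This is the
conservative choice: because `"NA"` is an encoded state, cluster-linked
missingness would itself be recoverable signal, and the default should
not manufacture it. Informative missingness can be emulated by editing
per-variable rates per cluster configuration.

**Survival.** Death times are exponential with per-cluster hazards
(per month) of 0.020, 0.010, 0.025, 0.030, 0.040 — cluster 2 has the
best and cluster 5 the worst prognosis, a 4-fold hazard ratio between
extremes. An independent exponential censoring time is applied, with its
rate solved numerically (by `uniroot` on the mixture censoring
probability) to hit the configured 30% censored fraction. Neither the
follow-up scale nor a censoring fraction is published for the reference
cohort; months and 30% are declared defaults, not inferences.

**Seeding.** A single master seed spawns one sub-seed per variable plus
one each for labels and survival, so adding a variable leaves the other
columns' draws untouched.

**What passing tests do and do not show.** The generator reproduces
marginals, missingness, block structure, planted co-occurrence, and
cluster-linked hazards. It does *not* reproduce clinical dependence rules
(pT/pN/AJCC consistency, stage–marker correlations beyond cluster
membership) or informative censoring. Pipeline results on synthetic data
therefore demonstrate *parameter recovery under the model's own
assumptions* — e.g. that the elbow rule finds the planted five subgroups
at $n = 1000$ and that their survival separates at $p < 10^{-4}$ — not
that five subgroups exist in any particular real cohort.

## 6. Numerical choices and degenerate inputs

* Squared-distance computations clamp small negative values from
  floating-point cancellation to 0.
* `gap_statistic()` guards $\log W = \log 0$ (perfectly replicated
  groups) with an epsilon and a warning.
* The log-rank covariance of $k-1$ groups is inverted via an SVD
  pseudo-inverse, which tolerates the singular matrices tiny fixtures can
  produce; the test is an error when no event was observed at all.
* KNN ties at equal distance resolve by reference-table order (stable).
* Empty cohorts: encoders refuse to fit; `save_cohort()` writes a
  header-only file that round-trips.

## 7. Problem sizes in the test suite

The suite exercises the full default study once (n = 1000 patients, 143
features, K scanned 2–10) and otherwise uses cohorts of 40–600 patients,
which keeps the complete run under half a minute while covering every
operation, including the permutation and Monte-Carlo oracles (10^4 label
shuffles, 100–200 replicates). These sizes are the package's own choices
for routine verification; all of them scale up by changing `n` and
`k_values` only.

## 8. Known limitations

* Equal, unweighted variable contributions mean correlated variables are
  double-counted (the Mahalanobis-weighted variant is out of scope).
* Quartile binning discards within-bin ordering, and bin edges refit on a
  new cohort will differ — comparisons across cohorts must reuse the
  fitted encoder.
* The elbow's second-difference rule inspects only adjacent K; very flat
  inertia curves legitimately end in a no-elbow warning.
* The chi-square test treats the `"NA"` category like any other, which
  conflates "missing" with a clinical state whenever missingness is
  informative; use `drop_na = TRUE` to probe sensitivity.
* `run_pipeline()` regenerates all artifacts on rerun rather than
  resuming; determinism under a fixed seed makes the two equivalent.
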