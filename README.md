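# cpsn — clinical patient similarity networks from mixed-type clinical data

`cpsn` builds and validates **clinical patient similarity networks
(cPSNs)** from the kind of heterogeneous baseline data a tumor cohort
actually has: continuous laboratory values, binary and categorical
histopathology and staging descriptors, molecular marker status — and a
lot of missingness. It is written for clinical investigators and
biostatisticians who want unsupervised, label-free patient stratification
whose clinical meaning is then *tested*, not assumed.

## The method

All variables are brought into one representation by uniform one-hot
encoding. For a cohort with $M$ variables $X_1,\dots,X_M$, where $X_i$
takes $N_i$ states after encoding, each patient becomes a binary vector of
$\sum_{i=1}^{M} N_i$ indicator features:

* **continuous** variables are discretized into four quartile bins
  (type-7 quantiles fitted on the non-missing values; upper-inclusive
  bins), so clinically similar value ranges share a state;
* **binary/categorical** variables contribute one feature per state;
* a **missing value is its own state** (`variable=NA`): nothing is ever
  imputed, and incomplete records remain fully comparable.

Every row of the resulting feature embedding matrix sums to exactly $M$,
and the Euclidean distance between two patients is $\sqrt{2q}$ where $q$
is the number of variables on which they differ — the distance matrix *is*
the patient similarity network. On top of it the package provides:

* **Subgrouping** — K-means (k-means++/Lloyd, best of `n_init` restarts)
  over $K = 2..10$, with the cluster number chosen by the elbow rule
  (maximal second difference of the within-cluster sum of squares) or the
  gap statistic against marginal-resampled reference data.
* **Clinical validation** — per-cluster Kaplan–Meier curves and the
  k-sample log-rank test on overall survival (a network whose clusters
  separate survival at p < 0.05 is called a *clinical* PSN), chi-square
  association between clusters and molecular markers (significance at
  p < 0.01), and per-cluster state-frequency profiles.
* **Case retrieval** — K-nearest-neighbour lookup of the patients most
  similar to a new index patient, encoded with the already-fitted model.
* A built-in 37-variable **gastric-cancer schema** (12 continuous, 25
  binary/categorical → 143 one-hot features) and a **synthetic-cohort
  generator** calibrated to its published marginal distributions, with
  planted subgroups and cluster-linked censored survival, so the whole
  pipeline is testable without access to patient-level data.

## Worked example

```r
library(cpsn)

schema <- gc_schema()
n_states(schema)
#> [1] 143

# a 1000-patient synthetic cohort with 5 planted subgroups
sim <- simulate_cohort(default_gc_config(), seed = 1)
enc <- fit_encoder(sim$cohort, schema)
X   <- encode_cohort(enc, sim$cohort)

scan <- kmeans_scan(X, k_values = 2:10, seed = 1)
sel  <- elbow_select(scan)
sel$chosen_k
#> [1] 5

a  <- scan_assignments(scan, sel$chosen_k)
rep <- validate_clustering(sim$cohort, schema, a, sim$survival,
                           markers = c("dMMR", "ERBB2-IHC"), encoder = enc)
rep
#> <cpsn_validation>
#>   log-rank: statistic = 127.74 , p = < 2.2e-16
#>   clinically valid network (p < 0.05 ): yes (cPSN)
#>   marker associations (chi-square):
#>     dMMR         p = 1.92e-11 *
#>     ERBB2-IHC    p = <2e-16 *
```

The log-rank p-value far below 0.05 marks the clustering as clinically
meaningful: the five recovered subgroups have genuinely different overall
survival (here by construction — the generator links cluster membership to
exponential hazards spanning a 4-fold ratio). Case retrieval for a new
patient:

```r
knn_query(enc, X, as.data.frame(sim$cohort)[17, ], k = 5)
#>   patient_id distance
#> 1      P0017 0.000000
#> 2      P0794 4.690416
#> 3      P0454 4.898979
#> 4      P0103 5.099020
#> 5      P0274 5.099020
```

A one-command version of the whole analysis (simulate or load → encode →
distances → cluster → validate → embed, with a checksummed manifest) is
`run_pipeline()`; `inst/scripts/cpsn-run.R` wraps it for the shell.

## Scope and caveats

The generator emulates marginal distributions, missingness rates, planted
cluster structure, and cluster-linked survival — not the full dependence
structure of real clinical data (e.g. staging-consistency rules between
pT/pN/AJCC are not enforced). See the methods vignette
(`vignettes/cpsn-methods.Rmd`) for the model, every tunable parameter, and
the package's design decisions.
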