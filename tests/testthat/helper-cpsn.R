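# fixture builders and independent oracles shared across test files

toy_schema <- function() {
  cohort_schema(list(
    variable_spec("marker", "continuous"),
    variable_spec("node", "binary", c("Yes", "No"), allow_missing = FALSE),
    variable_spec("type", "categorical", c("A", "B", "NA"))),
    name = "toy", version = "1")
}

toy_cohort <- function(schema = toy_schema()) {
  cohort_table(data.frame(
    patient_id = paste0("P", 1:8),
    marker = c(1, 2, 3, 4, 5, 6, 7, 8),
    node = rep(c("Yes", "No"), 4),
    type = c("A", "B", NA, "A", "B", "A", NA, "B"),
    stringsAsFactors = FALSE, check.names = FALSE), schema)
}

# random mixed-type schema for property tests
random_schema <- function(seed) {
  set.seed(seed)
  nv <- sample(3:8, 1)
  vars <- lapply(seq_len(nv), function(i) {
    kind <- sample(c("continuous", "binary", "categorical"), 1)
    nm <- paste0("v", i)
    if (kind == "continuous")
      variable_spec(nm, "continuous", allow_missing = sample(c(TRUE, FALSE), 1))
    else if (kind == "binary")
      variable_spec(nm, "binary", c("Yes", "No"),
                    allow_missing = sample(c(TRUE, FALSE), 1))
    else
      variable_spec(nm, "categorical",
                    paste0("s", seq_len(sample(3:5, 1))),
                    allow_missing = sample(c(TRUE, FALSE), 1))
  })
  cohort_schema(vars, name = paste0("rand", seed))
}

# random conforming cohort; missing values only where the variable allows
random_cohort <- function(schema, n, seed) {
  set.seed(seed)
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (nm in schema_variables(schema)) {
    v <- schema$variables[[nm]]
    if (v$kind == "continuous") {
      x <- stats::rnorm(n)
      if (v$allow_missing) x[stats::runif(n) < 0.15] <- NA
      df[[nm]] <- x
    } else {
      st <- setdiff(v$states, "NA")
      x <- sample(st, n, replace = TRUE)
      if (v$allow_missing) x[stats::runif(n) < 0.15] <- NA
      df[[nm]] <- x
    }
  }
  cohort_table(df, schema)
}

# brute-force per-variable feature recount, independent of the encoder
recount_features <- function(schema, table) {
  sum(vapply(schema_variables(schema), function(nm) {
    v <- schema$variables[[nm]]
    if (v$kind == "continuous")
      4L + as.integer(v$allow_missing || anyNA(table[[nm]]))
    else
      length(v$states) +
        as.integer(!"NA" %in% v$states && anyNA(table[[nm]]))
  }, integer(1)))
}

# naive double-loop Euclidean distance oracle
naive_distances <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

# fast vectorized 2-group log-rank statistic used as the permutation
# oracle: g is a 0/1 group indicator; time/event fixed
logrank2_stat_factory <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  R <- outer(ut, time, function(t, x) as.numeric(x >= t))   # at risk
  Dm <- outer(ut, time, function(t, x) as.numeric(x == t)) *
    rep(event, each = length(ut))                           # events at t
  n_t <- as.numeric(R %*% rep(1, length(time)))
  d_t <- as.numeric(Dm %*% rep(1, length(time)))
  function(G) {   # G: n x m matrix of 0/1 group indicators, one per column
    n1 <- R %*% G
    d1 <- Dm %*% G
    oe <- colSums(d1 - d_t * n1 / n_t)
    w <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
    v <- colSums(w * (n1 / n_t) * (1 - n1 / n_t))
    as.numeric(oe^2 / v)
  }
}

# minimal end-to-end run on a simulated cohort, shared by several tests
small_sim_pipeline <- function(n = 150, seed = 1, k_values = 2:6) {
  cfg <- default_gc_config(n = n)
  sim <- simulate_cohort(cfg, seed = seed)
  enc <- fit_encoder(sim$cohort, cfg$schema)
  X <- encode_cohort(enc, sim$cohort)
  list(cfg = cfg, sim = sim, enc = enc, X = X)
}
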