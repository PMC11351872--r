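test_that("quartile cut points use linear-interpolation quantiles", {
  sch <- cohort_schema(list(variable_spec("x", "continuous")))
  tab <- cohort_table(data.frame(patient_id = paste0("P", 1:8), x = 1:8),
                      sch)
  enc <- fit_encoder(tab, sch)
  # hand-computed type-7 quartiles of 1..8
  expect_equal(enc$edges$x$cuts, c(2.75, 4.5, 6.25))
  expect_identical(n_features(enc), 5L)
  expect_identical(enc$feature_names,
                   paste0("x=", c("Q1", "Q2", "Q3", "Q4", "NA")))
})

test_that("discretize follows the upper-inclusive bin convention", {
  e <- c(2.75, 4.5, 6.25)
  expect_identical(discretize(NA, e), "NA")
  expect_identical(discretize(4.5, e), "Q2")   # boundary goes low
  expect_identical(discretize(7.1, e), "Q4")
  expect_identical(discretize(c(-100, 2.75, 6.26, 1e6), e),
                   c("Q1", "Q1", "Q4", "Q4")) # clamping into outer bins
  expect_error(discretize(Inf, e), "non-finite")
})

test_that("encoder fitting validates its preconditions", {
  sch <- cohort_schema(list(variable_spec("x", "continuous")))
  tab <- cohort_table(data.frame(patient_id = paste0("P", 1:6),
                                 x = c(1, 1, 1, 2, 2, NA)), sch)
  expect_error(fit_encoder(tab, sch), "fewer than 4 distinct")
  expect_error(fit_encoder(toy_cohort()[0, ], toy_schema()), "empty cohort")
})

test_that("single binary variable with no missing yields 2 features", {
  sch <- cohort_schema(list(variable_spec("b", "binary", c("Yes", "No"),
                                          allow_missing = FALSE)))
  tab <- cohort_table(data.frame(patient_id = c("a", "b"),
                                 b = c("Yes", "No")), sch)
  expect_identical(n_features(fit_encoder(tab, sch)), 2L)
})

test_that("transform produces the hand-enumerated one-hot matrix", {
  sch <- cohort_schema(list(
    variable_spec("v1", "binary", c("Yes", "No"), allow_missing = FALSE),
    variable_spec("v2", "categorical", c("A", "B", "NA"))))
  tab <- cohort_table(data.frame(patient_id = c("P1", "P2", "P3"),
                                 v1 = c("Yes", "No", "Yes"),
                                 v2 = c("A", "B", NA)), sch)
  X <- encode_cohort(fit_encoder(tab, sch), tab)
  expected <- matrix(c(1, 0, 1, 0, 0,
                       0, 1, 0, 1, 0,
                       1, 0, 0, 0, 1), 3, 5, byrow = TRUE,
                     dimnames = list(c("P1", "P2", "P3"),
                                     c("v1=Yes", "v1=No",
                                       "v2=A", "v2=B", "v2=NA")))
  expect_equal(unclass(X)[, ], expected, ignore_attr = TRUE)
  expect_identical(colnames(X), colnames(expected))
})

test_that("an all-missing patient activates every NA feature", {
  sch <- cohort_schema(list(
    variable_spec("marker", "continuous", allow_missing = TRUE),
    variable_spec("node", "binary", c("Yes", "No", "NA")),
    variable_spec("type", "categorical", c("A", "B", "NA"))))
  tab <- cohort_table(data.frame(
    patient_id = paste0("P", 1:8), marker = 1:8,
    node = rep(c("Yes", "No"), 4),
    type = c("A", "B", NA, "A", "B", "A", NA, "B")), sch)
  enc <- fit_encoder(tab, sch)
  ghost <- data.frame(patient_id = "ghost", marker = NA_real_,
                      node = NA_character_, type = NA_character_)
  X <- encode_cohort(enc, rbind(as.data.frame(tab), ghost))
  g <- X["ghost", ]
  expect_identical(sum(g), 3L)
  expect_true(all(g[c("marker=NA", "node=NA", "type=NA")] == 1L))
})

test_that("row sums equal the variable count for arbitrary cohorts", {
  for (seed in 1:5) {
    sch <- random_schema(seed)
    tab <- random_cohort(sch, 30, seed + 50)
    X <- encode_cohort(fit_encoder(tab, sch), tab)
    expect_true(all(rowSums(X) == length(sch$variables)),
                info = paste("schema seed", seed))
    # block-partition property: one unit indicator per variable block
    blocks <- split(seq_len(ncol(X)), attr(X, "variable"))
    for (cols in blocks)
      expect_true(all(rowSums(X[, cols, drop = FALSE]) == 1L))
  }
})

test_that("feature count matches an independent recount for any schema", {
  for (seed in 6:10) {
    sch <- random_schema(seed)
    tab <- random_cohort(sch, 25, seed + 70)
    enc <- fit_encoder(tab, sch)
    expect_identical(enc$n_features, recount_features(sch, tab),
                     info = paste("schema seed", seed))
    expect_identical(length(enc$feature_names), enc$n_features)
    expect_false(anyDuplicated(enc$feature_names) > 0)
  }
})

test_that("refitting on the same data reproduces the encoder", {
  sch <- random_schema(11)
  tab <- random_cohort(sch, 40, 81)
  expect_equal(fit_encoder(tab, sch), fit_encoder(tab, sch))
})

test_that("identical patients encode to identical rows", {
  sch <- toy_schema()
  df <- as.data.frame(toy_cohort(sch))
  twin <- df[c(1, 1), ]; twin$patient_id <- c("a", "b")
  X <- encode_cohort(fit_encoder(df, sch), twin)
  expect_identical(X["a", ], X["b", ])
})

test_that("unseen state labels error unless lenient, then map to NA", {
  sch <- cohort_schema(list(
    variable_spec("v", "categorical", c("A", "B", "NA"))))
  fitted <- cohort_table(data.frame(patient_id = c("a", "b"),
                                    v = c("A", "B")), sch)
  enc <- fit_encoder(fitted, sch)
  sch2 <- cohort_schema(list(
    variable_spec("v", "categorical", c("A", "B", "C", "NA"))))
  new <- cohort_table(data.frame(patient_id = "c", v = "C"), sch2)
  enc2 <- enc; enc2$schema <- sch2
  expect_error(encode_cohort(enc2, new), "not part of the fitted model")
  X <- encode_cohort(enc2, new, lenient = TRUE)
  expect_identical(unname(X[1, "v=NA"]), 1L)
})
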