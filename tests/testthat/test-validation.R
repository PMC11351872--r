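test_that("KM curve with no events stays at 1", {
  km <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km$all$surv == 1))
})

test_that("one death among four at risk drops survival to 3/4", {
  km <- km_estimate(c(2, 3, 4, 5), c(1, 0, 0, 0))
  expect_equal(km$all$surv[1], 0.75)
})

test_that("KM matches the hand-computed 10-patient product-limit table", {
  tt <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  ev <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- km_estimate(tt, ev)$all
  # worked by hand over the 9 distinct times (death and censoring share
  # t = 2): 9/10, x8/9, x6/7, (censor), x4/5, x3/4, (censor), x1/2,
  # (censor)
  expect_equal(km$surv,
               c(9 / 10, 4 / 5, 24 / 35, 24 / 35, 96 / 175,
                 72 / 175, 72 / 175, 36 / 175, 36 / 175))
  expect_equal(km$n_risk, c(10L, 9L, 7L, 6L, 5L, 4L, 3L, 2L, 1L))
  expect_true(all(diff(km$surv) <= 0))
  # independent cross-check against the standard survival implementation
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km$surv[km$n_event > 0],
               summary(sf, times = km$time[km$n_event > 0])$surv)
})

test_that("KM equals one minus the empirical CDF when uncensored", {
  set.seed(5)
  tt <- rexp(40); ev <- rep(1, 40)
  km <- km_estimate(tt, ev)$all
  ecdf_surv <- 1 - ecdf(tt)(km$time)
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank is zero with p = 1 on duplicated groups", {
  tt <- c(1, 3, 4, 6, 8); ev <- c(1, 1, 0, 1, 0)
  lr <- logrank_test(rep(tt, 2), rep(ev, 2), rep(c("A", "B"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")),
               "without any observed events")
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("A", 3)),
               "at least 2 groups")
})

test_that("log-rank agrees with the standard implementation", {
  set.seed(9)
  n <- 60
  g <- rep(c("A", "B", "C"), each = 20)
  tt <- rexp(n, rate = c(A = 0.1, B = 0.2, C = 0.35)[g])
  ev <- rbinom(n, 1, 0.8)
  lr <- logrank_test(tt, ev, g)
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-9)
  expect_identical(lr$df, 2L)
})

test_that("log-rank is invariant to time rescaling and label swaps", {
  set.seed(11)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.7); g <- rep(c("A", "B"), 15)
  lr <- logrank_test(tt, ev, g)
  expect_equal(logrank_test(tt * 12, ev, g)$statistic, lr$statistic)
  g2 <- ifelse(g == "A", "B", "A")
  expect_equal(logrank_test(tt, ev, g2)$statistic, lr$statistic)
})

test_that("two-group statistic equals the squared standardized O - E", {
  set.seed(13)
  tt <- rexp(50); ev <- rbinom(50, 1, 0.8); g <- rep(c("A", "B"), 25)
  lr <- logrank_test(tt, ev, g)
  stat2 <- logrank2_stat_factory(tt, ev)(matrix(as.numeric(g == "B")))
  expect_equal(lr$statistic, stat2, tolerance = 1e-9)
})

test_that("log-rank separates groups with a threefold hazard ratio", {
  hits <- vapply(1:100, function(sd_) {
    set.seed(sd_)
    death <- c(rexp(200, 0.05), rexp(200, 0.15))
    cens <- rexp(400, 0.02)
    ev <- as.integer(death <= cens)
    tt <- pmin(death, cens)
    logrank_test(tt, ev, rep(c("lo", "hi"), each = 200))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("chi-square handles frozen tables exactly", {
  # balanced, independent 2x2
  t0 <- chisq_association(rep(c("a", "b"), each = 20),
                          rep(c("x", "y"), 20))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # perfectly associated balanced diagonal: chi-square equals n
  t1 <- chisq_association(rep(c("a", "b"), each = 20),
                          rep(c("x", "y"), each = 20))
  expect_equal(t1$statistic, 40)
  expect_identical(t1$df, 1L)
  expect_equal(t1$p_value, stats::pchisq(40, 1, lower.tail = FALSE))
  expect_true(t1$significant)
  expect_error(chisq_association(rep("a", 10), rep(c("x", "y"), 5)),
               "degenerate")
})

test_that("missing marker values are a category unless dropped", {
  a <- rep(c("c1", "c2"), each = 10)
  b <- c(rep("pos", 8), rep(NA, 2), rep("neg", 8), rep(NA, 2))
  kept <- chisq_association(a, b)
  expect_identical(dim(kept$table), c(2L, 3L))
  dropped <- chisq_association(a, b, drop_na = TRUE)
  expect_identical(dim(dropped$table), c(2L, 2L))
})

test_that("chi-square p-values are uniform under independence", {
  set.seed(21)
  p <- vapply(1:200, function(i) {
    a <- sample(c("u", "v", "w"), 400, replace = TRUE)
    b <- sample(c("x", "y", "z", "t"), 400, replace = TRUE)
    chisq_association(a, b)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster profiles recover generator state probabilities", {
  sp <- small_sim_pipeline(n = 600, seed = 17)
  prof <- cluster_profiles(sp$sim$cohort, sp$cfg$schema,
                           sp$sim$true_labels, encoder = sp$enc)
  # per cluster x variable the frequencies partition the patients
  sums <- aggregate(frequency ~ cluster + variable, prof, sum)
  expect_true(all(abs(sums$frequency - 1) < 1e-9))
  # spot-check a planted categorical signature against its configured
  # per-cluster probability
  v <- sp$cfg$variables$Nerve_invasion
  slices <- cpsn:::.slice_dists(v$p, sp$cfg$k_true)
  s <- sp$cfg$separation
  for (cl in c(1, 4)) {
    target <- (1 - s) * v$p + s * slices[v$slice_perm[cl], ]
    target <- (1 - v$missing) * target
    got <- prof$frequency[prof$cluster == cl &
                            prof$variable == "Nerve_invasion" &
                            prof$state == "Yes"]
    expect_lt(abs(got - target[1]), 0.1)
  }
})

test_that("degenerate profile cases behave as expected", {
  sch <- toy_schema()
  tab <- toy_cohort(sch)
  enc <- fit_encoder(tab, sch)
  # single cluster: profiles equal cohort-wide frequencies
  prof1 <- cluster_profiles(tab, sch, rep(1, 8), encoder = enc)
  X <- encode_cohort(enc, tab)
  expect_equal(prof1$frequency, unname(colMeans(X)))
  # cluster of identical patients: all frequencies 0 or 1
  df <- as.data.frame(tab)[rep(1, 4), ]; df$patient_id <- paste0("c", 1:4)
  prof2 <- cluster_profiles(df, sch, rep(1, 4), encoder = enc)
  expect_true(all(prof2$frequency %in% c(0, 1)))
})

test_that("validate_clustering assembles a coherent report", {
  sp <- small_sim_pipeline(n = 300, seed = 19)
  rep_ <- validate_clustering(sp$sim$cohort, sp$cfg$schema,
                              sp$sim$true_labels, sp$sim$survival,
                              markers = c("dMMR", "ERBB2-IHC"),
                              encoder = sp$enc)
  expect_s3_class(rep_, "cpsn_validation")
  expect_true(rep_$valid)   # hazards are cluster-linked by construction
  expect_identical(rep_$valid, rep_$logrank$p_value < 0.05)
  expect_named(rep_$chisq, c("dMMR", "ERBB2-IHC"))
  expect_length(rep_$km, 5L)
  # shuffling survival across patients destroys the linkage
  set.seed(1)
  sh <- sp$sim$survival
  sh$patient_id <- sample(sh$patient_id)
  flags <- vapply(1:20, function(i) {
    set.seed(100 + i)
    sh$patient_id <- sample(sh$patient_id)
    lr <- logrank_test(sh$time[match(sp$sim$cohort$patient_id,
                                     sh$patient_id)],
                       sh$event[match(sp$sim$cohort$patient_id,
                                      sh$patient_id)],
                       sp$sim$true_labels)
    lr$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("quartile grouping splits a cohort in four", {
  set.seed(23)
  x <- rnorm(200)
  g <- quartile_groups(x)
  expect_identical(sort(unique(g)), c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(unname(table(g)["Q1"]), 50, tolerance = 0.05)
})
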