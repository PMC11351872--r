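#' Kaplan-Meier product-limit survival curves
#'
#' Nonparametric survival curve per group under right censoring. At each
#' distinct event time the curve multiplies by `(n_risk - n_event)/n_risk`;
#' observations censored at an event time are still at risk at that time
#' (deaths precede censorings on ties). With no censoring the estimate
#' reduces to one minus the empirical CDF of the event times.
#'
#' @param time Nonnegative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @param group Optional group labels (one curve per group; a single curve
#'   when omitted).
#' @return A `cpsn_km`: named list of per-group data frames with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (rows at distinct
#'   observed times, survival from 1 downward).
#' @export
km_estimate <- function(time, event, group = NULL) {
  time <- as.numeric(time); event <- as.integer(event)
  stopifnot(length(time) == length(event))
  if (any(is.na(time)) || any(time < 0))
    stop("times must be nonnegative and non-missing", call. = FALSE)
  if (!all(event %in% 0:1)) stop("'event' must be 0/1", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  stopifnot(length(group) == length(time))
  curves <- lapply(split(seq_along(time), group), function(idx) {
    if (!length(idx)) stop("empty survival group", call. = FALSE)
    tt <- time[idx]; ev <- event[idx]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(t) sum(tt >= t), integer(1))
    n_event <- vapply(ut, function(t) sum(tt == t & ev == 1L), integer(1))
    n_censor <- vapply(ut, function(t) sum(tt == t & ev == 0L), integer(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv)
  })
  structure(curves, class = "cpsn_km")
}

#' @export
print.cpsn_km <- function(x, ...) {
  cat("<cpsn_km>", length(x), "survival curve(s):\n")
  for (g in names(x)) {
    d <- x[[g]]
    cat("  ", g, ": ", sum(d$n_event), " events / ",
        d$n_risk[1], " patients, final S = ",
        signif(d$surv[nrow(d)], 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.cpsn_km <- function(x, col = seq_along(x), xlab = "Time (months)",
                         ylab = "Survival probability", ...) {
  xmax <- max(vapply(x, function(d) max(d$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x)) {
    d <- x[[i]]
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), do.points = FALSE,
                    col = col[i])
  }
  graphics::legend("bottomleft", legend = names(x), col = col, lty = 1,
                   bty = "n")
  invisible(x)
}

# Moore-Penrose inverse via SVD; the log-rank covariance matrix of k-1
# groups is occasionally singular on tiny fixtures
.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, tol)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' k-sample log-rank test
#'
#' Compares survival distributions across groups via the
#' observed-minus-expected event counts accumulated over the ordered
#' distinct event times, with the hypergeometric covariance at each time.
#' The statistic is referred to a chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Group labels; at least two nonempty groups.
#' @return A `cpsn_test` with `statistic`, `df`, `p_value`,
#'   `observed`/`expected` per group, and `method`.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time); event <- as.integer(event)
  group <- factor(group)
  stopifnot(length(time) == length(event), length(group) == length(time))
  if (nlevels(group) < 2L)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  if (any(tabulate(group) == 0L)) group <- droplevels(group)
  if (sum(event) == 0L)
    stop("log-rank test is undefined without any observed events",
         call. = FALSE)
  k <- nlevels(group)
  ut <- sort(unique(time[event == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    if (n < 1L) next
    d <- sum(event == 1L & time == t)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dj <- vapply(levels(group), function(g)
      sum(event == 1L & time == t & group == g), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1L) {
      w <- d * (n - d) / (n - 1)
      V <- V + w * (diag(nj / n, k) - tcrossprod(nj / n))
    }
  }
  u <- (O - E)[-k]
  stat <- drop(t(u) %*% .pinv(V[-k, -k, drop = FALSE]) %*% u)
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group)),
                 method = "k-sample log-rank test"),
            class = "cpsn_test")
}

#' @export
print.cpsn_test <- function(x, ...) {
  cat("<cpsn_test> ", x$method, ": statistic = ", signif(x$statistic, 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Chi-square association between two categorical labelings
#'
#' Pearson chi-square test on the R x C contingency table of two aligned
#' label vectors, e.g. cluster membership against a molecular marker.
#' Missing values are kept as their own `"NA"` category by default,
#' consistent with the encoding philosophy; `drop_na = TRUE` removes pairs
#' with a missing entry instead. Association is called significant below
#' the 0.01 level.
#'
#' @param labels_a,labels_b Aligned label vectors.
#' @param drop_na Drop pairs with missing entries instead of tabulating
#'   them as `"NA"`.
#' @param alpha Significance threshold (default 0.01).
#' @return A `cpsn_test` with the statistic, df, p-value, the contingency
#'   table, expected counts, and a `low_expected` flag when any expected
#'   cell count is below 5.
#' @export
chisq_association <- function(labels_a, labels_b, drop_na = FALSE,
                              alpha = 0.01) {
  stopifnot(length(labels_a) == length(labels_b))
  a <- as.character(labels_a); b <- as.character(labels_b)
  if (drop_na) {
    keep <- !is.na(a) & !is.na(b) & a != "NA" & b != "NA"
    a <- a[keep]; b <- b[keep]
  } else {
    a[is.na(a)] <- "NA"; b[is.na(b)] <- "NA"
  }
  tab <- table(a, b, dnn = NULL)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate contingency table (fewer than 2 rows or columns)",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), table = tab,
                 expected = ct$expected,
                 low_expected = any(ct$expected < 5),
                 significant = unname(ct$p.value) < alpha,
                 method = "Pearson chi-square"),
            class = "cpsn_test")
}

#' Per-cluster clinical feature profiles
#'
#' For every cluster, variable, and post-encoding state (quartile bins and
#' `"NA"` for continuous variables), the within-cluster frequency of that
#' state — the numbers behind a cluster-characteristics heat map.
#' Frequencies sum to 1 per variable within each cluster.
#'
#' @param table A `cpsn_cohort`.
#' @param schema The matching `cpsn_schema`.
#' @param assignments Cluster labels aligned with the table rows.
#' @param encoder Optional fitted `cpsn_encoder`; fitted on `table` when
#'   omitted.
#' @return Data frame with `cluster`, `variable`, `state`, `frequency`.
#' @export
cluster_profiles <- function(table, schema, assignments, encoder = NULL) {
  stopifnot(length(assignments) == nrow(table))
  if (is.null(encoder)) encoder <- fit_encoder(table, schema)
  X <- encode_cohort(encoder, table)
  cl <- as.character(assignments)
  out <- lapply(sort(unique(cl)), function(g) {
    f <- colMeans(X[cl == g, , drop = FALSE])
    data.frame(cluster = g, variable = attr(X, "variable"),
               state = sub("^[^=]*=", "", colnames(X)),
               frequency = unname(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Quartile grouping of a continuous variable
#'
#' Splits a numeric vector at its cohort quartiles into `Q1..Q4` (type-7
#' quantiles, upper-inclusive bins), the conventional comparator used to
#' benchmark the network stratification against, e.g., age groups.
#'
#' @param x Numeric vector; missing values give `"NA"`.
#' @return Character vector of bin labels.
#' @export
quartile_groups <- function(x) {
  x <- as.numeric(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                       names = FALSE)
  discretize(x, q)
}

#' Clinical-validity assessment of a clustering
#'
#' Assembles the full validation report for a cohort stratification:
#' per-cluster Kaplan-Meier curves, the k-sample log-rank test on overall
#' survival, the network-validity flag (log-rank p below `alpha_survival`
#' marks the network as clinically meaningful, i.e. a cPSN), chi-square
#' association tests between clusters and each requested categorical
#' marker, and per-cluster feature-frequency profiles.
#'
#' @inheritParams cluster_profiles
#' @param survival Data frame `patient_id`, `time`, `event` covering every
#'   patient of `table`.
#' @param markers Character vector of categorical schema variables to test
#'   against the clustering (default: none).
#' @param alpha_survival Log-rank validity threshold (default 0.05).
#' @param alpha_assoc Chi-square significance threshold (default 0.01).
#' @param drop_na Passed to [chisq_association()].
#' @return A `cpsn_validation`: `km`, `logrank`, `valid`, `chisq` (named
#'   list per marker), `profiles`.
#' @export
validate_clustering <- function(table, schema, assignments, survival,
                                markers = character(),
                                alpha_survival = 0.05, alpha_assoc = 0.01,
                                drop_na = FALSE, encoder = NULL) {
  stopifnot(length(assignments) == nrow(table))
  survival <- validate_survival(survival)
  i <- match(table$patient_id, survival$patient_id)
  if (anyNA(i))
    stop("survival records missing for patient(s): ",
         paste(utils::head(table$patient_id[is.na(i)], 3), collapse = ", "),
         call. = FALSE)
  survival <- survival[i, ]
  cl <- cluster_names(assignments)
  km <- km_estimate(survival$time, survival$event, cl)
  lr <- logrank_test(survival$time, survival$event, cl)
  chi <- lapply(markers, function(m) {
    if (!m %in% names(table))
      stop("marker '", m, "' is not a cohort column", call. = FALSE)
    chisq_association(cl, table[[m]], drop_na = drop_na,
                      alpha = alpha_assoc)
  })
  names(chi) <- markers
  structure(list(km = km, logrank = lr,
                 valid = lr$p_value < alpha_survival,
                 alpha_survival = alpha_survival,
                 chisq = chi,
                 profiles = cluster_profiles(table, schema, assignments,
                                             encoder = encoder)),
            class = "cpsn_validation")
}

#' @export
print.cpsn_validation <- function(x, ...) {
  cat("<cpsn_validation>\n  log-rank: statistic =",
      signif(x$logrank$statistic, 5), ", p =",
      format.pval(x$logrank$p_value, digits = 4), "\n")
  cat("  clinically valid network (p <", x$alpha_survival, "):",
      if (x$valid) "yes (cPSN)" else "no", "\n")
  if (length(x$chisq)) {
    cat("  marker associations (chi-square):\n")
    for (m in names(x$chisq))
      cat(sprintf("    %-12s p = %s%s\n", m,
                  format.pval(x$chisq[[m]]$p_value, digits = 3),
                  if (x$chisq[[m]]$significant) " *" else ""))
  }
  invisible(x)
}
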