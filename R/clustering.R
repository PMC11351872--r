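# squared Euclidean distances between rows of X (n x p) and rows of C (k x p)
.sq_dist <- function(X, C) {
  D <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  D[D < 0] <- 0
  D
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen one
.kmeanspp <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- .sq_dist(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, .sq_dist(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

# Lloyd iterations; an emptied cluster is reseeded at the point farthest
# from its assigned center
.lloyd <- function(X, centers, max_iter = 100L) {
  n <- nrow(X); k <- nrow(centers)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D <- .sq_dist(X, centers)
    assign_new <- max.col(-D, ties.method = "first")
    for (j in which(tabulate(assign_new, k) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), assign_new)])
      assign_new[far] <- j
      D[far, ] <- -Inf  # cannot be picked again this round
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    centers <- rowsum(X, assign_new) / tabulate(assign_new, k)
  }
  D <- .sq_dist(X, centers)
  list(cluster = assign_old,
       centers = centers,
       inertia = sum(D[cbind(seq_len(n), assign_old)]),
       iter = it)
}

# stable labels: 1 = largest cluster, ties broken by first patient index
.relabel_by_size <- function(cluster, k) {
  size <- tabulate(cluster, k)
  first <- vapply(seq_len(k), function(j) {
    w <- which(cluster == j)
    if (length(w)) w[1L] else Inf
  }, numeric(1))
  rank <- order(-size, first)
  match(cluster, rank)
}

.kmeans_once <- function(X, k, n_init, max_iter = 100L) {
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- .lloyd(X, .kmeanspp(X, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best$cluster <- .relabel_by_size(best$cluster, k)
  best
}

#' K-means subgrouping over a range of cluster numbers
#'
#' Runs Lloyd's algorithm with k-means++ initialization on the feature
#' embedding matrix for every candidate cluster number (2 to 10 by
#' default), keeping the best of `n_init` restarts by within-cluster sum
#' of squares. Cluster labels are renumbered by descending cluster size
#' (ties by first patient index), so `1` is always the largest subgroup
#' and labels are stable across restart order.
#'
#' @param X Feature matrix from [encode_cohort()].
#' @param k_values Integer vector of candidate K (default `2:10`).
#' @param seed Integer seed governing all restarts.
#' @param n_init Restarts per K (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `cpsn_kscan`: `k_values`, `inertia` per K, an n x length(K)
#'   `assignments` matrix, the patient ids, and the settings used.
#' @seealso [elbow_select()], [gap_statistic()]
#' @export
kmeans_scan <- function(X, k_values = 2:10, seed = 0L, n_init = 10L,
                        max_iter = 100L) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  if (n == 0L) stop("empty feature matrix", call. = FALSE)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1L)) stop("cluster numbers must be positive",
                               call. = FALSE)
  if (max(k_values) >= n)
    stop("largest K (", max(k_values), ") must be below the patient count (",
         n, ")", call. = FALSE)
  Xn <- matrix(as.numeric(X), n, ncol(X), dimnames = dimnames(X))
  set.seed(as.integer(seed))
  inertia <- numeric(length(k_values))
  assignments <- matrix(NA_integer_, n, length(k_values),
                        dimnames = list(rownames(X), paste0("K", k_values)))
  for (i in seq_along(k_values)) {
    fit <- .kmeans_once(Xn, k_values[i], n_init, max_iter)
    inertia[i] <- fit$inertia
    assignments[, i] <- fit$cluster
  }
  structure(list(k_values = k_values, inertia = inertia,
                 assignments = assignments, patient_ids = rownames(X),
                 seed = as.integer(seed), n_init = as.integer(n_init)),
            class = "cpsn_kscan")
}

#' @export
print.cpsn_kscan <- function(x, ...) {
  cat("<cpsn_kscan> K =", paste(range(x$k_values), collapse = ".."),
      " (n_init =", x$n_init, ", seed =", x$seed, ")\n")
  print(data.frame(k = x$k_values, inertia = signif(x$inertia, 6)),
        row.names = FALSE)
  invisible(x)
}

#' Extract one assignment vector from a scan
#' @param scan A `cpsn_kscan`.
#' @param k A scanned cluster number.
#' @return Integer cluster labels named by patient id.
#' @export
scan_assignments <- function(scan, k) {
  stopifnot(inherits(scan, "cpsn_kscan"))
  i <- match(as.integer(k), scan$k_values)
  if (is.na(i)) stop("K = ", k, " was not scanned", call. = FALSE)
  stats::setNames(scan$assignments[, i], scan$patient_ids)
}

#' Elbow selection of the cluster number
#'
#' Picks the cluster number at the point of maximal curvature of the
#' within-cluster sum-of-squares curve, quantified as the discrete second
#' difference `inertia(K-1) - 2*inertia(K) + inertia(K+1)` over interior
#' scanned K. A flat or strictly linear curve carries no elbow; a warning
#' is issued and the smallest scanned K returned.
#'
#' @param scan A `cpsn_kscan` over at least 3 cluster numbers.
#' @return A `cpsn_selection` with `method = "elbow"`, the chosen K, and a
#'   diagnostics data frame (`k`, `inertia`, `second_diff`).
#' @export
elbow_select <- function(scan) {
  stopifnot(inherits(scan, "cpsn_kscan"))
  k <- scan$k_values; w <- scan$inertia
  if (length(k) < 3L)
    stop("elbow selection needs at least 3 scanned cluster numbers",
         call. = FALSE)
  m <- length(k)
  d2 <- c(NA_real_,
          w[seq_len(m - 2L)] - 2 * w[seq_len(m - 2L) + 1L] + w[seq_len(m - 2L) + 2L],
          NA_real_)
  interior <- d2[-c(1L, m)]
  tol <- 1e-8 * max(abs(w), 1)
  if (all(abs(interior) <= tol) || diff(range(w)) <= tol) {
    warning("inertia curve has no elbow (flat or linear); ",
            "returning the smallest scanned K")
    chosen <- k[1L]
  } else {
    chosen <- k[which.max(d2)]
  }
  structure(list(method = "elbow", chosen_k = chosen,
                 diagnostics = data.frame(k = k, inertia = w,
                                          second_diff = d2)),
            class = "cpsn_selection")
}

#' @export
print.cpsn_selection <- function(x, ...) {
  cat("<cpsn_selection> method =", x$method, "-> K =", x$chosen_k, "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

# reference draw for the gap statistic: within each variable block, resample
# every patient's one-hot state independently from the block's empirical
# marginal -- preserves the one-hot structure, destroys co-occurrence
.marginal_resample <- function(X, block) {
  n <- nrow(X)
  out <- matrix(0L, n, ncol(X), dimnames = dimnames(X))
  for (v in unique(block)) {
    cols <- which(block == v)
    p <- colMeans(X[, cols, drop = FALSE])
    if (sum(p) <= 0) next
    draw <- sample.int(length(cols), n, replace = TRUE, prob = p / sum(p))
    out[cbind(seq_len(n), cols[draw])] <- 1L
  }
  out
}

#' Gap-statistic selection of the cluster number
#'
#' Compares the log within-cluster dispersion of the data with its mean
#' over `B` structureless reference datasets:
#' `Gap(K) = mean_b log(W_ref_b(K)) - log(W(K))`, with standard error
#' `s_K = sd_b(log W_ref) * sqrt(1 + 1/B)`. References are drawn by
#' resampling each variable's one-hot state independently from its
#' empirical marginal, which keeps the block structure of the encoding but
#' removes all between-variable association. The selected K is the
#' smallest scanned value with `Gap(K) >= Gap(K+1) - s_(K+1)`.
#'
#' @inheritParams kmeans_scan
#' @param B Number of reference datasets (default 10).
#' @return A `cpsn_selection` with `method = "gap"` and a diagnostics data
#'   frame (`k`, `inertia`, `gap`, `se`).
#' @export
gap_statistic <- function(X, k_values = 2:10, B = 10L, seed = 0L,
                          n_init = 10L, max_iter = 100L) {
  stopifnot(is.matrix(X))
  block <- attr(X, "variable")
  if (is.null(block))
    stop("gap_statistic() needs the 'variable' block attribute of a ",
         "matrix produced by encode_cohort()", call. = FALSE)
  B <- as.integer(B)
  if (B < 2L) stop("'B' must be at least 2", call. = FALSE)
  k_values <- sort(unique(as.integer(k_values)))
  n <- nrow(X)
  Xn <- matrix(as.numeric(X), n, ncol(X), dimnames = dimnames(X))
  set.seed(as.integer(seed))
  eps <- 1e-12
  logW <- function(M) {
    vapply(k_values, function(k) {
      w <- .kmeans_once(M, k, n_init, max_iter)$inertia
      if (w <= 0) {
        warning("zero within-cluster dispersion at K = ", k,
                "; log guarded with epsilon")
        w <- eps
      }
      log(w)
    }, numeric(1))
  }
  lw_data <- logW(Xn)
  lw_ref <- matrix(0, B, length(k_values))
  for (b in seq_len(B)) {
    ref <- matrix(as.numeric(.marginal_resample(X, block)), n, ncol(X))
    lw_ref[b, ] <- logW(ref)
  }
  gap <- colMeans(lw_ref) - lw_data
  se <- apply(lw_ref, 2L, stats::sd) * sqrt(1 + 1 / B)
  m <- length(k_values)
  chosen <- k_values[m]
  for (i in seq_len(m - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { chosen <- k_values[i]; break }
  }
  structure(list(method = "gap", chosen_k = chosen,
                 diagnostics = data.frame(k = k_values, inertia = exp(lw_data),
                                          gap = gap, se = se)),
            class = "cpsn_selection")
}

#' Name integer cluster labels the reporting way
#' @param assignments Integer cluster labels.
#' @return Character vector `"Cluster_1"`, `"Cluster_2"`, ... (1 = largest
#'   subgroup under the scan's renumbering rule).
#' @export
cluster_names <- function(assignments) paste0("Cluster_", assignments)
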