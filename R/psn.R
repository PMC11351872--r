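#' Pairwise Euclidean patient distances
#'
#' Organizes the feature embedding matrix into the patient similarity
#' network: the symmetric matrix of Euclidean distances between the binary
#' patient vectors. Because each variable block holds exactly one active
#' feature per patient, two patients differing in `q` variables are at
#' distance `sqrt(2q)`, so squared distances are even integers bounded by
#' twice the variable count.
#'
#' @param X A `cpsn_features` matrix from [encode_cohort()] (any numeric
#'   matrix with patient row names is accepted).
#' @return Symmetric n x n distance matrix with zero diagonal, patient ids
#'   as dimnames.
#' @export
psn_distances <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) == 0L) stop("cannot build a PSN from 0 patients", call. = FALSE)
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Retrieve the nearest neighbours of an index patient
#'
#' Encodes a raw index patient with an already-fitted encoder (no refit),
#' computes its Euclidean distance to every reference patient, and returns
#' the `k` closest — the case-retrieval operation of the network. The
#' caller chooses `k` to widen or narrow the pool of similar cases. Ties at
#' equal distance keep reference-table order.
#'
#' @param model The fitted `cpsn_encoder` used for the reference cohort.
#' @param X_ref Reference `cpsn_features` matrix (rows are candidates).
#' @param patient One-row data frame with the raw clinical values of the
#'   index patient (a `patient_id` column is optional).
#' @param k Number of neighbours; values above the reference size are
#'   clamped with a warning.
#' @param lenient Passed to [encode_cohort()] for unseen state labels.
#' @return A data frame (`patient_id`, `distance`), ascending by distance.
#' @export
knn_query <- function(model, X_ref, patient, k = 10L, lenient = FALSE) {
  stopifnot(inherits(model, "cpsn_encoder"), is.matrix(X_ref))
  n <- nrow(X_ref)
  if (n == 0L) stop("empty reference matrix", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n,
            " reference patients; returning all of them")
    k <- n
  }
  patient <- as.data.frame(patient, check.names = FALSE)
  if (nrow(patient) != 1L)
    stop("'patient' must be a single-row record", call. = FALSE)
  if (!"patient_id" %in% names(patient)) patient$patient_id <- "index"
  x <- encode_cohort(model, patient, lenient = lenient)
  d <- sqrt(rowSums(sweep(X_ref, 2L, as.numeric(x[1L, ]))^2))
  ord <- order(d)[seq_len(k)]       # order() is stable: ties keep row order
  data.frame(patient_id = rownames(X_ref)[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}

#' Low-dimensional embedding of the PSN for visualization
#'
#' Projects the network into 2 or 3 coordinates by classical metric
#' multidimensional scaling (principal coordinates) of the Euclidean
#' distance matrix. The embedding is for plotting patient maps only; all
#' clustering and neighbour retrieval operate in the full feature space.
#'
#' @param X A `cpsn_features` matrix or a precomputed distance matrix from
#'   [psn_distances()].
#' @param dims 2 or 3 output dimensions.
#' @return Data frame with `patient_id` and coordinate columns
#'   `dim1..dims`. Deterministic for fixed input.
#' @export
embed_psn <- function(X, dims = 2L) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("'dims' must be 2 or 3", call. = FALSE)
  is_dist <- is.null(attr(X, "variable")) && nrow(X) == ncol(X) &&
    isSymmetric(unname(unclass(X))) && all(diag(X) == 0)
  D <- if (is_dist) X else psn_distances(X)
  if (nrow(D) <= dims)
    stop("need more than ", dims, " patients to embed in ", dims,
         " dimensions", call. = FALSE)
  co <- stats::cmdscale(stats::as.dist(D), k = dims)
  out <- data.frame(patient_id = rownames(D), stringsAsFactors = FALSE)
  for (j in seq_len(dims)) out[[paste0("dim", j)]] <- co[, j]
  out
}
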