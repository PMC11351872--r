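#' Fit the one-hot encoder on a cohort
#'
#' Learns the encoding model that turns a mixed-type cohort into a binary
#' feature embedding matrix. Each continuous variable is partitioned into
#' four quartile bins, with the three interior cut points (Q1, Q2, Q3)
#' estimated on its non-missing training values by linear-interpolation
#' (type 7) quantiles. Binary/categorical variables contribute one feature
#' per declared state. Any variable that may be unobserved — declared
#' `allow_missing` or with missingness seen during fitting — gains an
#' additional `"NA"` feature, so no value is ever imputed.
#'
#' @param table A `cpsn_cohort` conforming to `schema`.
#' @param schema A [cohort_schema()].
#' @return A `cpsn_encoder`: the schema, per-variable fitted cut points and
#'   training ranges, the ordered feature names (`"variable=state"`),
#'   grouped contiguously by variable in schema order, and the total
#'   feature count.
#' @examples
#' sch <- cohort_schema(list(
#'   variable_spec("marker", "continuous"),
#'   variable_spec("node", "binary", c("Yes", "No"), allow_missing = FALSE)))
#' tab <- cohort_table(data.frame(patient_id = paste0("P", 1:8),
#'                                marker = 1:8,
#'                                node = rep(c("Yes", "No"), 4)), sch)
#' enc <- fit_encoder(tab, sch)
#' n_features(enc)  # 5 quartile/NA features + 2 binary states
#' @export
fit_encoder <- function(table, schema) {
  stopifnot(inherits(schema, "cpsn_schema"))
  table <- cohort_table(table, schema)
  if (nrow(table) == 0L)
    stop("cannot fit an encoder on an empty cohort", call. = FALSE)
  edges <- list(); states <- list()
  for (nm in schema_variables(schema)) {
    v <- schema$variables[[nm]]
    col <- table[[nm]]
    miss_seen <- anyNA(col)
    if (v$kind == "continuous") {
      x <- col[!is.na(col)]
      if (length(unique(x)) < 4L)
        stop("continuous variable '", nm, "' has fewer than 4 distinct ",
             "non-missing values; quartile bins are degenerate",
             call. = FALSE)
      q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      edges[[nm]] <- list(cuts = q, range = range(x))
      states[[nm]] <- c("Q1", "Q2", "Q3", "Q4",
                        if (v$allow_missing || miss_seen) "NA")
    } else {
      states[[nm]] <- if (miss_seen && !"NA" %in% v$states)
        c(v$states, "NA") else v$states
    }
  }
  feature_names <- unlist(lapply(names(states), function(nm)
    paste0(nm, "=", states[[nm]])), use.names = FALSE)
  structure(
    list(schema = schema, edges = edges, states = states,
         feature_names = feature_names,
         feature_variable = rep(names(states),
                                lengths(states)),
         n_features = length(feature_names)),
    class = "cpsn_encoder")
}

#' @export
print.cpsn_encoder <- function(x, ...) {
  cat("<cpsn_encoder> ", length(x$states), " variables -> ",
      x$n_features, " one-hot features\n", sep = "")
  invisible(x)
}

#' Total one-hot feature count of a fitted encoder
#'
#' The width of the feature embedding matrix: the sum over variables of
#' their post-encoding state counts.
#'
#' @param model A `cpsn_encoder`.
#' @return Integer feature count.
#' @export
n_features <- function(model) {
  stopifnot(inherits(model, "cpsn_encoder"))
  model$n_features
}

#' Map continuous values to quartile bin labels
#'
#' Bins are upper-inclusive: `value <= Q1` gives `"Q1"`, `Q1 < value <= Q2`
#' gives `"Q2"`, `Q2 < value <= Q3` gives `"Q3"`, and anything above Q3
#' gives `"Q4"`; values outside the training range clamp into the outer
#' bins. Missing values map to `"NA"`.
#'
#' @param value Numeric vector (may contain `NA`).
#' @param edges Numeric vector of the three interior cut points
#'   `c(Q1, Q2, Q3)`, or the per-variable entry of a fitted encoder.
#' @return Character vector of bin labels.
#' @export
discretize <- function(value, edges) {
  if (is.list(edges)) edges <- edges$cuts
  stopifnot(is.numeric(edges), length(edges) == 3L, !is.unsorted(edges))
  value <- as.numeric(value)
  if (any(!is.na(value) & !is.finite(value)))
    stop("non-finite value passed to discretize()", call. = FALSE)
  out <- rep(NA_character_, length(value))
  obs <- !is.na(value)
  out[obs] <- c("Q1", "Q2", "Q3", "Q4")[
    1L + (value[obs] > edges[1]) + (value[obs] > edges[2]) +
      (value[obs] > edges[3])]
  out[!obs] <- "NA"
  out
}

#' Encode a cohort into the binary feature embedding matrix
#'
#' Applies a fitted encoder to a cohort: every patient becomes a 0/1 row
#' with exactly one active feature inside each variable's block (the
#' matching state, quartile bin, or the `"NA"` feature when the value is
#' unobserved). Row sums therefore always equal the number of variables.
#'
#' @param model A fitted `cpsn_encoder`.
#' @param table A `cpsn_cohort` conforming to the encoder's schema.
#' @param lenient If `TRUE`, a state label unseen by the model maps to the
#'   variable's `"NA"` feature when the variable has one; the default
#'   (`FALSE`) raises an error, the safe behaviour for clinical data.
#' @return A `cpsn_features` binary matrix (patients x features) with
#'   patient ids as row names, `"variable=state"` column names, and a
#'   `"variable"` attribute giving each column's variable block.
#' @export
encode_cohort <- function(model, table, lenient = FALSE) {
  stopifnot(inherits(model, "cpsn_encoder"))
  table <- cohort_table(table, model$schema)
  n <- nrow(table)
  vars <- names(model$states)
  X <- matrix(0L, nrow = n, ncol = model$n_features,
              dimnames = list(table$patient_id, model$feature_names))
  offset <- 0L
  for (nm in vars) {
    st <- model$states[[nm]]
    v <- model$schema$variables[[nm]]
    col <- table[[nm]]
    lab <- if (v$kind == "continuous")
      discretize(col, model$edges[[nm]])
    else ifelse(is.na(col), "NA", col)
    idx <- match(lab, st)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))
      if (lenient && "NA" %in% st) {
        idx[bad] <- match("NA", st)
      } else {
        stop("variable '", nm, "', patient '", table$patient_id[bad[1]],
             "': state '", lab[bad[1]], "' is not part of the fitted model",
             call. = FALSE)
      }
    }
    X[cbind(seq_len(n), offset + idx)] <- 1L
    offset <- offset + length(st)
  }
  structure(X, variable = model$feature_variable,
            class = c("cpsn_features", class(X)))
}

# strip the subclass when matrix math would be confused by it
as_feature_matrix <- function(X) {
  stopifnot(is.matrix(X))
  v <- attr(X, "variable")
  if (is.null(v))
    stop("feature matrix lacks the 'variable' block attribute; ",
         "use encode_cohort()", call. = FALSE)
  X
}
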