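#' Declare a clinical variable
#'
#' A variable specification records how one column of a cohort table is
#' interpreted: as a continuous measurement (later discretized into quartile
#' bins) or as a binary/categorical variable with a fixed set of state
#' labels. Missingness is first-class: a variable that may be unobserved
#' carries the literal state `"NA"`, which becomes its own indicator feature
#' during encoding — no value is ever imputed.
#'
#' For binary and categorical variables, `allow_missing = TRUE` (or an
#' explicit `"NA"` entry in `states`) materializes the `"NA"` state as the
#' last state label. Continuous variables keep an empty state list until an
#' encoder is fitted; `allow_missing` then decides whether they contribute a
#' fifth (missing) feature on top of the four quartile bins.
#'
#' @param name Variable name; must match the cohort column header.
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param states Character vector of state labels for binary/categorical
#'   variables, in display order. Must be empty for continuous variables.
#' @param allow_missing May this variable be unobserved? Default `TRUE`.
#' @param units Optional free-text units (continuous variables).
#' @return An object of class `cpsn_variable`.
#' @examples
#' variable_spec("Nerve_invasion", "binary", c("Yes", "No"),
#'               allow_missing = FALSE)
#' variable_spec("age", "continuous", units = "years")
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                          states = character(), allow_missing = TRUE,
                          units = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  states <- as.character(states)
  if (anyDuplicated(states))
    stop("duplicate state labels in variable '", name, "'", call. = FALSE)
  if (kind == "continuous") {
    if (length(states))
      stop("continuous variable '", name, "' must not declare states",
           call. = FALSE)
  } else {
    if ("NA" %in% states) allow_missing <- TRUE
    non_missing <- setdiff(states, "NA")
    if (kind == "binary" && length(non_missing) != 2L)
      stop("binary variable '", name, "' must have exactly 2 non-missing ",
           "states, got ", length(non_missing), call. = FALSE)
    if (kind == "categorical" && length(non_missing) < 2L)
      stop("categorical variable '", name, "' needs at least 2 non-missing ",
           "states", call. = FALSE)
    # materialize the missing state so downstream feature counts are
    # read straight off the state list
    if (allow_missing && !"NA" %in% states) states <- c(states, "NA")
  }
  structure(
    list(name = name, kind = kind, states = states,
         allow_missing = isTRUE(allow_missing), units = units),
    class = "cpsn_variable")
}

#' @export
print.cpsn_variable <- function(x, ...) {
  cat("<cpsn_variable> ", x$name, " (", x$kind, ")", sep = "")
  if (!is.null(x$units)) cat(" [", x$units, "]", sep = "")
  cat("\n")
  if (length(x$states))
    cat("  states:", paste(x$states, collapse = ", "), "\n")
  else
    cat("  states: quartile bins after encoder fitting",
        if (x$allow_missing) "+ NA", "\n")
  invisible(x)
}

#' Assemble a cohort schema
#'
#' A schema is an ordered collection of [variable_spec()] objects; the order
#' fixes the column order of cohort tables and the feature-block order of
#' every encoded matrix downstream.
#'
#' @param variables List of `cpsn_variable` objects.
#' @param name,version Free-text identifiers carried into serialized files.
#' @return An object of class `cpsn_schema`.
#' @seealso [gc_schema()] for the built-in gastric-cancer schema.
#' @export
cohort_schema <- function(variables, name = "cohort", version = "1") {
  if (!length(variables) || !all(vapply(variables, inherits, logical(1),
                                        "cpsn_variable")))
    stop("'variables' must be a non-empty list of cpsn_variable objects",
         call. = FALSE)
  nm <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate variable names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(variables) <- nm
  structure(list(variables = variables, name = name,
                 version = as.character(version)),
            class = "cpsn_schema")
}

#' @export
length.cpsn_schema <- function(x) length(x$variables)

#' @export
print.cpsn_schema <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, character(1), "kind")
  cat("<cpsn_schema> '", x$name, "' v", x$version, ": ",
      length(x$variables), " variables (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds != "continuous"), " binary/categorical)\n", sep = "")
  invisible(x)
}

#' Variable names of a schema, in column order
#' @param schema A `cpsn_schema`.
#' @export
schema_variables <- function(schema) {
  stopifnot(inherits(schema, "cpsn_schema"))
  names(schema$variables)
}

#' Post-encoding state count of a variable or schema
#'
#' The number of one-hot features a variable contributes: its state count
#' for binary/categorical variables (the `"NA"` state included when
#' declared), or four quartile bins plus one missing state (when
#' `allow_missing`) for continuous variables. For a schema, the sum over
#' variables — the width of the feature embedding matrix.
#'
#' @param x A `cpsn_variable` or `cpsn_schema`.
#' @return Integer state/feature count.
#' @export
n_states <- function(x) UseMethod("n_states")

#' @export
n_states.cpsn_variable <- function(x) {
  if (x$kind == "continuous") 4L + as.integer(x$allow_missing)
  else length(x$states)
}

#' @export
n_states.cpsn_schema <- function(x)
  sum(vapply(x$variables, n_states, integer(1)))

#' Write a schema to YAML
#' @param schema A `cpsn_schema`.
#' @param path Output file path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cpsn_schema"))
  doc <- list(
    name = schema$name, version = schema$version,
    variables = lapply(unname(schema$variables), function(v) {
      out <- list(name = v$name, kind = v$kind,
                  allow_missing = v$allow_missing)
      if (length(v$states)) out$states <- as.list(v$states)
      if (!is.null(v$units)) out$units <- v$units
      out
    }))
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' Read a schema from YAML
#' @param path Path to a YAML file produced by [write_schema()] (or written
#'   by hand in the same layout).
#' @return A `cpsn_schema`.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- lapply(doc$variables, function(v)
    variable_spec(v$name, v$kind,
                  states = unlist(v$states %||% character()),
                  allow_missing = v$allow_missing %||% TRUE,
                  units = v$units))
  cohort_schema(vars, name = doc$name %||% "cohort",
                version = doc$version %||% "1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
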