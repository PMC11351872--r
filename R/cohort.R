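#' Construct and validate a cohort table
#'
#' Checks a raw data frame of per-patient clinical values against a schema
#' and normalizes it: the patient-id column first, then one column per
#' schema variable in schema order; continuous columns numeric; categorical
#' entries either a declared state label or `NA`.
#'
#' @param data A data frame with a patient-id column and one column per
#'   schema variable.
#' @param schema A [cohort_schema()].
#' @param id_col Name of the patient-id column (default `"patient_id"`).
#' @return The validated data frame, classed `cpsn_cohort`.
#' @export
cohort_table <- function(data, schema, id_col = "patient_id") {
  stopifnot(inherits(schema, "cpsn_schema"), is.data.frame(data))
  data <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(data))
    stop("cohort table lacks the patient-id column '", id_col, "'",
         call. = FALSE)
  vn <- schema_variables(schema)
  absent <- setdiff(vn, names(data))
  if (length(absent))
    stop("cohort table lacks schema column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate patient id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (nm in vn) {
    v <- schema$variables[[nm]]
    col <- data[[nm]]
    if (v$kind == "continuous") {
      if (is.character(col) || is.factor(col)) {
        chr <- trimws(as.character(col))
        chr[!nzchar(chr)] <- NA_character_
        num <- suppressWarnings(as.numeric(chr))
        bad <- which(!is.na(chr) & is.na(num))
        if (length(bad))
          stop("variable '", nm, "', row ", bad[1],
               ": value '", chr[bad[1]], "' is not numeric", call. = FALSE)
        col <- num
      }
      col <- as.numeric(col)
      if (any(!is.na(col) & !is.finite(col)))
        stop("variable '", nm, "' contains non-finite values", call. = FALSE)
    } else {
      col <- as.character(col)
      col[!is.na(col) & col == "NA"] <- NA_character_
      bad <- which(!is.na(col) & !col %in% setdiff(v$states, "NA"))
      if (length(bad))
        stop("variable '", nm, "', row ", bad[1], ": '", col[bad[1]],
             "' is not a declared state (",
             paste(v$states, collapse = ", "), ")", call. = FALSE)
    }
    out[[nm]] <- col
  }
  class(out) <- c("cpsn_cohort", "data.frame")
  out
}

.delim_for <- function(path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a cohort table from a delimited file
#'
#' Reads a CSV/TSV file (delimiter inferred from the extension, tab unless
#' `.csv`) with a header row, a `patient_id` column, and one column per
#' schema variable. Cells equal to `missing_marker` become missing values.
#'
#' @inheritParams cohort_table
#' @param path Path to the delimited file.
#' @param missing_marker String marking unobserved values (default `"NA"`).
#' @return A validated `cpsn_cohort`.
#' @seealso [save_cohort()]
#' @export
load_cohort <- function(path, schema, missing_marker = "NA",
                        id_col = "patient_id") {
  raw <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                           colClasses = "character", check.names = FALSE,
                           na.strings = missing_marker, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  cohort_table(raw, schema, id_col = id_col)
}

#' Write a cohort table to a delimited file
#'
#' Inverse of [load_cohort()]: `load_cohort(save_cohort(x, f), schema)`
#' restores `x` (values, not byte layout). Missing values are written as
#' `missing_marker`.
#'
#' @param table A `cpsn_cohort`.
#' @param path Output path (`.csv` comma-separated, otherwise tab).
#' @param missing_marker String written for missing values.
#' @export
save_cohort <- function(table, path, missing_marker = "NA") {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, na = missing_marker)
  invisible(path)
}

#' Read / write survival records
#'
#' Survival files are delimited tables with columns `patient_id`, `time`
#' (follow-up in months, nonnegative) and `event` (1 = death observed,
#' 0 = censored at last follow-up).
#'
#' @param path File path (`.csv` comma-separated, otherwise tab).
#' @return `read_survival()`: a data frame with the three columns validated.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_survival(df)
}

#' @rdname read_survival
#' @param survival Data frame with `patient_id`, `time`, `event`.
#' @export
write_survival <- function(survival, path) {
  validate_survival(survival)
  utils::write.table(survival, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_survival <- function(df) {
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival times must be nonnegative and non-missing", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("'event' must be 0 (censored) or 1 (death)", call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids in survival records", call. = FALSE)
  df[need]
}

#' Summarize a cohort, baseline-characteristics style
#'
#' For every continuous variable: the number observed, number missing, and
#' the median and range of the non-missing values. For every binary or
#' categorical variable: the head count of each state, with unobserved
#' values counted under the `"NA"` state, so that counts per variable sum
#' to the cohort size.
#'
#' @param table A `cpsn_cohort`.
#' @param schema The matching `cpsn_schema`.
#' @return A `cpsn_summary`: list with data frames `continuous`
#'   (`variable`, `n`, `n_missing`, `median`, `min`, `max`) and
#'   `categorical` (`variable`, `state`, `count`).
#' @export
summarize_cohort <- function(table, schema) {
  stopifnot(inherits(schema, "cpsn_schema"), is.data.frame(table))
  n <- nrow(table)
  cont <- list(); cats <- list()
  for (nm in schema_variables(schema)) {
    v <- schema$variables[[nm]]
    col <- table[[nm]]
    if (v$kind == "continuous") {
      x <- col[!is.na(col)]
      cont[[nm]] <- data.frame(
        variable = nm, n = length(x), n_missing = n - length(x),
        median = if (length(x)) stats::median(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        stringsAsFactors = FALSE)
    } else {
      lab <- ifelse(is.na(col), "NA", col)
      states <- if ("NA" %in% v$states || any(is.na(col)))
        union(v$states, "NA") else v$states
      cnt <- vapply(states, function(s) sum(lab == s), integer(1))
      cats[[nm]] <- data.frame(variable = nm, state = states,
                               count = unname(cnt), stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst) if (length(lst))
    do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  structure(list(n = n, continuous = bind(cont), categorical = bind(cats)),
            class = "cpsn_summary")
}

#' @export
print.cpsn_summary <- function(x, ...) {
  cat("<cpsn_summary> n =", x$n, "patients\n")
  if (!is.null(x$continuous) && nrow(x$continuous)) {
    cat("\nContinuous variables (median [range], missing):\n")
    with(x$continuous, cat(sprintf("  %-20s %g [%g-%g]  NA:%d\n",
                                   variable, median, min, max, n_missing),
                           sep = ""))
  }
  if (!is.null(x$categorical) && nrow(x$categorical)) {
    cat("\nCategorical variables (state: count):\n")
    for (nm in unique(x$categorical$variable)) {
      d <- x$categorical[x$categorical$variable == nm, ]
      cat("  ", nm, ": ",
          paste(d$state, d$count, sep = "=", collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
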