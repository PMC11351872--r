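#' Run the full patient-similarity analysis end to end
#'
#' One-command orchestration: load (or simulate) a cohort, fit the one-hot
#' encoder, build the feature embedding matrix and the Euclidean distance
#' network, scan cluster numbers, select K (elbow or gap statistic), name
#' the subgroups `Cluster_1..K` by descending size, validate them against
#' overall survival and optional categorical markers, profile each
#' cluster, and embed the network for plotting. Every intermediate
#' artifact is written under `out_dir` together with a manifest of file
#' checksums; identical inputs and seed reproduce identical artifacts.
#'
#' Exactly one of `cohort` or `sim_config` must be given. File inputs may
#' be paths (read with [load_cohort()] / [read_survival()]) or in-memory
#' objects.
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort A `cpsn_cohort` or path to a cohort table.
#' @param survival Survival records or path; required with `cohort`.
#' @param schema A `cpsn_schema` or path to a schema YAML (default:
#'   the built-in gastric-cancer schema).
#' @param sim_config A `cpsn_sim_config`: simulate the cohort instead of
#'   loading one.
#' @param k_values Candidate cluster numbers (default `2:10`).
#' @param select `"elbow"` or `"gap"`.
#' @param markers Categorical variables tested for association with the
#'   clustering.
#' @param seed Master seed for simulation and clustering.
#' @param n_init K-means restarts per K.
#' @param gap_B Reference datasets for the gap statistic.
#' @param embed_dims 2 or 3 embedding dimensions.
#' @param lenient Passed to [encode_cohort()].
#' @return A `cpsn_manifest` (invisibly): settings echo, chosen K,
#'   validity flag, per-artifact paths and MD5 checksums, timing.
#' @examples
#' \donttest{
#' cfg <- default_gc_config(n = 120)
#' man <- run_pipeline(tempfile("cpsn"), sim_config = cfg, k_values = 2:6,
#'                     seed = 1)
#' man$chosen_k
#' }
#' @export
run_pipeline <- function(out_dir,
                         cohort = NULL, survival = NULL,
                         schema = gc_schema(),
                         sim_config = NULL,
                         k_values = 2:10,
                         select = c("elbow", "gap"),
                         markers = c("dMMR", "EGFR-IHC", "ERBB2-IHC",
                                     "p53-IHC"),
                         seed = 0L, n_init = 10L, gap_B = 10L,
                         embed_dims = 2L, lenient = FALSE) {
  select <- match.arg(select)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort) == is.null(sim_config))
    stop("give exactly one of 'cohort' or 'sim_config'", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(schema)) schema <- read_schema(schema)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(sim_config)) {
    sim <- stage("simulate", simulate_cohort(sim_config, seed = seed))
    cohort <- sim$cohort
    survival <- sim$survival
    schema <- sim_config$schema
    truth <- sim$true_labels
  } else {
    if (is.character(cohort))
      cohort <- stage("load", load_cohort(cohort, schema))
    else cohort <- stage("load", cohort_table(cohort, schema))
    if (is.null(survival))
      stop("'survival' is required with a loaded cohort", call. = FALSE)
    if (is.character(survival)) survival <- read_survival(survival)
  }

  paths <- list()
  put <- function(key, file) { paths[[key]] <<- file.path(out_dir, file) }
  put("cohort", "cohort.tsv"); put("survival", "survival.tsv")
  save_cohort(cohort, paths$cohort)
  write_survival(survival, paths$survival)
  if (!is.null(truth)) {
    put("truth", "truth.tsv")
    utils::write.table(
      data.frame(patient_id = names(truth), true_cluster = unname(truth)),
      paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enc <- stage("encode", fit_encoder(cohort, schema))
  X <- stage("encode", encode_cohort(enc, cohort, lenient = lenient))
  put("features", "features.tsv")
  utils::write.table(
    data.frame(patient_id = rownames(X), X, check.names = FALSE),
    paths$features, sep = "\t", quote = FALSE, row.names = FALSE)
  put("features_meta", "features.meta.json")
  jsonlite::write_json(
    list(n_patients = nrow(X), n_variables = length(enc$states),
         n_features = enc$n_features, feature_names = enc$feature_names,
         edges = lapply(enc$edges, function(e)
           list(cuts = e$cuts, range = e$range))),
    paths$features_meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  D <- stage("distances", psn_distances(X))
  put("distances", "distances.tsv")
  utils::write.table(
    data.frame(patient_id = rownames(D), D, check.names = FALSE),
    paths$distances, sep = "\t", quote = FALSE, row.names = FALSE)

  scan <- stage("cluster", kmeans_scan(X, k_values = k_values, seed = seed,
                                       n_init = n_init))
  sel <- stage("select", switch(select,
    elbow = elbow_select(scan),
    gap   = gap_statistic(X, k_values = k_values, B = gap_B, seed = seed,
                          n_init = n_init)))
  assignments <- if (select == "gap" && !sel$chosen_k %in% scan$k_values)
    stop("gap-selected K missing from scan") else
      scan_assignments(scan, sel$chosen_k)
  put("kscan", "kscan.json")
  jsonlite::write_json(
    list(k_values = scan$k_values, inertia = scan$inertia,
         method = sel$method, chosen_k = sel$chosen_k,
         diagnostics = sel$diagnostics),
    paths$kscan, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  put("assignments", "assignments.tsv")
  utils::write.table(
    data.frame(patient_id = names(assignments),
               cluster = cluster_names(assignments)),
    paths$assignments, sep = "\t", quote = FALSE, row.names = FALSE)

  markers <- intersect(markers, schema_variables(schema))
  rep_ <- stage("validate",
                validate_clustering(cohort, schema, assignments, survival,
                                    markers = markers, encoder = enc))
  put("validation", "validation.json")
  jsonlite::write_json(
    list(logrank = list(statistic = rep_$logrank$statistic,
                        df = rep_$logrank$df,
                        p_value = rep_$logrank$p_value),
         valid = rep_$valid,
         chisq = lapply(rep_$chisq, function(t)
           list(statistic = t$statistic, df = t$df, p_value = t$p_value,
                low_expected = t$low_expected,
                significant = t$significant))),
    paths$validation, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  put("profiles", "profiles.tsv")
  utils::write.table(rep_$profiles, paths$profiles, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  emb <- stage("embed", embed_psn(D, dims = embed_dims))
  emb$cluster <- cluster_names(assignments)[match(emb$patient_id,
                                                  names(assignments))]
  put("embedding", "embedding.tsv")
  utils::write.table(emb, paths$embedding, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- unlist(paths)
  checksums <- tools::md5sum(unname(files))
  names(checksums) <- names(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cpsn")),
    seed = as.integer(seed),
    settings = list(k_values = k_values, select = select,
                    n_init = n_init, markers = markers,
                    simulated = !is.null(truth)),
    n_patients = nrow(X), n_variables = length(enc$states),
    n_features = enc$n_features,
    chosen_k = sel$chosen_k,
    logrank_p = rep_$logrank$p_value,
    valid = rep_$valid,
    files = as.list(files),
    checksums = as.list(checksums),
    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "cpsn_manifest"
  invisible(manifest)
}

#' @export
print.cpsn_manifest <- function(x, ...) {
  cat("<cpsn_manifest> n =", x$n_patients, ", variables =", x$n_variables,
      ", features =", x$n_features, "\n  chosen K =", x$chosen_k,
      ", log-rank p =", format.pval(x$logrank_p, digits = 4),
      ", clinically valid:", x$valid, "\n")
  invisible(x)
}
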