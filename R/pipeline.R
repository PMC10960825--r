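#' Discover disease-associated multi-omic modules
#'
#' The full pipeline on an in-memory dataset: shared preprocessing,
#' repeated sGCCA on label-stratified subsamples with the phenotype as an
#' extra single-feature block, consensus network construction at the
#' `edge` co-occurrence threshold, connected-component consensus modules,
#' and evaluation of every module against size-matched random modules.
#' Fully reproducible given `config$seed`.
#'
#' @param dataset a `multi_omic_dataset` of raw tables (see
#'   [align_samples()] or [simulate_multiomics()]).
#' @param config a [pipeline_config()].
#' @return A `module_discovery` object: list with `modules`
#'   (`consensus_modules`), `evaluation` ([evaluate_modules()] tibble),
#'   `counts` (`cooccurrence_counts`), `preprocessed` dataset, removal
#'   `report`, `config`, and `log` (character).
#' @export
discover_modules <- function(dataset, config = pipeline_config()) {
  log <- character()
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  note("preprocessing dataset '", dataset$dataset_id, "' (",
       n_samples(dataset), " samples, ", length(dataset$omics), " omics)")
  prep <- stage("preprocess", preprocess_dataset(dataset, config))
  note("removed ", nrow(prep$report), " feature(s); ",
       sum(lengths(lapply(prep$dataset$omics, feature_ids))), " remain")

  note("accumulating co-occurrence over ", config$n_runs, " subsampled sGCCA runs")
  counts <- stage("consensus", accumulate_cooccurrence(prep$dataset, config))

  graph <- stage("network", build_consensus_network(counts, config$edge))
  modules <- stage("modules", extract_consensus_modules(graph))
  note(dplyr::n_distinct(modules$members$module_id), " consensus module(s) at edge >= ",
       config$edge)

  evaluation <- stage("evaluation", evaluate_modules(prep$dataset, modules, config))
  note(sum(evaluation$disease_associated), " disease-associated multi-omic module(s)")

  structure(
    list(modules = modules, evaluation = evaluation, counts = counts,
         preprocessed = prep$dataset, report = prep$report,
         config = config, log = log),
    class = "module_discovery"
  )
}

#' @export
print.module_discovery <- function(x, ...) {
  cat(sprintf("<module_discovery> dataset '%s'\n", x$preprocessed$dataset_id))
  print(x$modules)
  if (nrow(x$evaluation) > 0) {
    ev <- x$evaluation
    for (i in seq_len(nrow(ev))) {
      cat(sprintf("  %s: AUC %.3f (null %.3f) rho %s (null %s)%s\n",
                  ev$module_id[i], ev$auc[i], ev$auc_null_mean[i],
                  formatC(ev$rho[i], digits = 3, format = "f"),
                  formatC(ev$rho_null_mean[i], digits = 3, format = "f"),
                  if (ev$disease_associated[i]) "  ** disease-associated" else ""))
    }
  }
  invisible(x)
}

#' Tidy module membership of a discovery result
#'
#' Module members joined with each module's headline evaluation columns.
#'
#' @param x a `module_discovery`.
#' @param ... unused.
#' @return A tibble: `module_id`, `omic`, `feature`, `degree`, `auc`,
#'   `rho`, `disease_associated`.
#' @export
#' @method tidy module_discovery
tidy.module_discovery <- function(x, ...) {
  dplyr::left_join(
    x$modules$members,
    dplyr::select(tibble::as_tibble(x$evaluation), "module_id", "auc", "rho",
                  "disease_associated"),
    by = "module_id"
  )
}

#' One-row summary of a discovery result
#'
#' @param x a `module_discovery`.
#' @param ... unused.
#' @return A one-row tibble: module counts, total runs, best module AUC.
#' @export
#' @method glance module_discovery
glance.module_discovery <- function(x, ...) {
  ev <- x$evaluation
  tibble::tibble(
    n_modules = dplyr::n_distinct(x$modules$members$module_id),
    n_disease_associated = sum(ev$disease_associated),
    n_features = nrow(x$modules$members),
    total_runs = x$counts$total_runs,
    best_auc = if (nrow(ev) > 0) max(ev$auc) else NA_real_
  )
}

#' Write pipeline results to a directory
#'
#' Emits `modules.tsv` (module_id, omic, feature, degree), `edges.tsv`
#' (feature_a, feature_b, frequency), `network.graphml`,
#' `evaluation.json`, `removal_report.tsv`, and `run.log`.
#'
#' @param result a `module_discovery`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(result$modules$members, "modules.tsv")
  tsv(result$modules$edges, "edges.tsv")
  tsv(result$report, "removal_report.tsv")
  g <- build_consensus_network(result$counts, result$config$edge)
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  ev <- tibble::as_tibble(result$evaluation)
  jsonlite::write_json(
    list(dataset = result$preprocessed$dataset_id,
         modules = ev,
         pairwise = attr(result$evaluation, "pairwise")),
    file.path(dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Run the pipeline from files on disk
#'
#' Thin orchestration over [read_feature_table()], [read_metadata()],
#' [align_samples()], [discover_modules()] and [write_results()].
#'
#' @param feature_tables named character vector: omic tag -> TSV path.
#' @param metadata path to the metadata TSV.
#' @param label_column,case_value passed to [read_metadata()].
#' @param out_dir output directory.
#' @param config a [pipeline_config()] (or path to YAML/JSON readable by
#'   [read_config()]).
#' @param dataset_id dataset identifier.
#' @return The `module_discovery`, invisibly.
#' @export
run_pipeline <- function(feature_tables, metadata, label_column, case_value,
                         out_dir, config = pipeline_config(),
                         dataset_id = "dataset") {
  if (is.character(config)) config <- read_config(config)
  omics <- purrr::imap(as.list(feature_tables), function(path, tag) {
    read_feature_table(path, tag)
  })
  labels <- read_metadata(metadata, label_column, case_value)
  dataset <- align_samples(unname(omics), labels, dataset_id)
  result <- discover_modules(dataset, config)
  write_results(result, out_dir)
  invisible(result)
}
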