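#' Pipeline configuration
#'
#' Collects every tunable of the module discovery pipeline with the default
#' values used throughout: subsampling at 80% of samples ((nfol-1)/nfol with
#' nfol = 5) for 100 sGCCA runs, 5 components per run with 10 features kept
#' per omic, a fully connected design (`des = 1`) between omic blocks,
#' consensus edges at 80% co-occurrence, and module evaluation against 100
#' size-matched random modules at an AUC cutoff of 0.7.
#'
#' @param keep features retained per omic block and component; a single
#'   count recycled over omics, or a named vector (`c(T = 10, M = 5)`).
#' @param des design weight between pairs of omic blocks; the label block
#'   is always connected to every omic block with weight 1.
#' @param n_runs total number of subsampled sGCCA runs.
#' @param nfol folds per repetition; each run uses `nfol - 1` folds, i.e. a
#'   fraction `(nfol - 1) / nfol` of samples.
#' @param nrep number of repetitions of the fold split; default
#'   `ceiling(n_runs / nfol)`.
#' @param ncomp sGCCA components (putative modules) per run.
#' @param edge minimum co-occurrence frequency for a consensus edge.
#' @param auc_threshold AUC a module's first PC must exceed.
#' @param n_null random null modules drawn per observed module.
#' @param min_prevalence minimum fraction of non-zero values per feature.
#' @param min_mean_abundance minimum mean relative abundance (taxa and
#'   pathway omics only).
#' @param collinearity_threshold absolute Spearman correlation above which
#'   features are collapsed to one representative.
#' @param pseudocount pseudocount added before log-transforming metabolite
#'   intensities; `NULL` means half the minimum positive value per feature.
#' @param exclude character vector of feature ids to drop (e.g. pathways
#'   outside the expected taxonomic range), checked after prefixing.
#' @param seed master seed; child seeds for each stochastic stage
#'   (collinearity representatives, subsampling, null draws, forests) are
#'   derived from it so stages stay independent.
#' @param tol,max_iter sGCCA convergence controls.
#' @param restart_width blocks at most this wide additionally restart the
#'   sGCCA inner loop from every signed basis vector (see [fit_sgcca()]).
#' @param exceedance `"mean"` (observed statistic must exceed the null
#'   mean) or `"q95"` (must exceed the null 95th percentile).
#' @param rho_absolute use the absolute instead of the signed mean
#'   cross-omic correlation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(keep = 10,
                            des = 1,
                            n_runs = 100,
                            nfol = 5,
                            nrep = NULL,
                            ncomp = 5,
                            edge = 0.8,
                            auc_threshold = 0.7,
                            n_null = 100,
                            min_prevalence = 0.15,
                            min_mean_abundance = 5e-5,
                            collinearity_threshold = 0.99,
                            pseudocount = NULL,
                            exclude = character(),
                            seed = 1L,
                            tol = 1e-6,
                            max_iter = 1000L,
                            restart_width = 12L,
                            exceedance = c("mean", "q95"),
                            rho_absolute = FALSE) {
  cfg <- list(
    keep = keep, des = des, n_runs = n_runs, nfol = nfol,
    nrep = nrep %||% ceiling(n_runs / nfol), ncomp = ncomp, edge = edge,
    auc_threshold = auc_threshold, n_null = n_null,
    min_prevalence = min_prevalence, min_mean_abundance = min_mean_abundance,
    collinearity_threshold = collinearity_threshold,
    pseudocount = pseudocount, exclude = exclude,
    seed = as.integer(seed), tol = tol, max_iter = max_iter,
    restart_width = restart_width,
    exceedance = match.arg(exceedance), rho_absolute = rho_absolute
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$edge > 0, cfg$edge <= 1,
    cfg$nfol >= 2,
    cfg$ncomp >= 1,
    all(cfg$keep >= 1),
    cfg$auc_threshold > 0.5, cfg$auc_threshold < 1,
    cfg$n_runs >= 1, cfg$n_null >= 1,
    cfg$min_prevalence >= 0, cfg$min_prevalence <= 1,
    cfg$des >= 0
  )
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields mirror the arguments of [pipeline_config()]; unknown fields are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$keep)) vals$keep <- unlist(vals$keep)
  do.call(pipeline_config, vals)
}

# Per-omic keep counts in the dataset's omic order.
keep_per_omic <- function(cfg, tags) {
  k <- cfg$keep
  if (is.null(names(k))) {
    out <- rep_len(k, length(tags))
    names(out) <- tags
    return(out)
  }
  missing <- setdiff(tags, names(k))
  if (length(missing) > 0) stop("no `keep` for omic(s): ", paste(missing, collapse = ", "), call. = FALSE)
  k[tags]
}

# Deterministic child seeds per pipeline stage, derived from the master
# seed. Adding draws in one stage never perturbs another.
stage_seeds <- function(seed) {
  # bounded well below 2^31 so per-module offsets never overflow
  withr::with_seed(seed, {
    s <- sample.int(2L^30L, 6L)
  })
  names(s) <- c("collinearity", "subsample", "null", "rf", "simulate", "misc")
  as.list(s)
}
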