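#' Label-stratified subsample index sets
#'
#' Draws `n_runs` subsamples, each a union of `nfol - 1` folds of a
#' label-stratified partition (so each run holds a fraction
#' `(nfol - 1) / nfol` of the samples and class proportions stay within one
#' sample of the full data). Fold partitions are redrawn per repetition and
#' runs are taken round-robin across repetitions.
#'
#' @param labels 0/1 vector.
#' @param nfol folds per repetition.
#' @param n_runs total subsamples to return.
#' @param seed seed making the draw reproducible.
#' @return List of integer index vectors (sorted), length `n_runs`.
#' @export
draw_subsamples <- function(labels, nfol = 5, n_runs = 100, seed = 1L) {
  stopifnot(nfol >= 2)
  n <- length(labels)
  nrep <- ceiling(n_runs / nfol)
  withr::with_seed(seed, {
    reps <- lapply(seq_len(nrep), function(r) stratified_fold_ids(labels, nfol))
    runs <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      r <- ((i - 1L) %% nrep) + 1L
      f <- ((i - 1L) %/% nrep) + 1L
      runs[[i]] <- sort(which(reps[[r]] != f))
    }
    runs
  })
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin over folds.
stratified_fold_ids <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Accumulate feature co-occurrence over subsampled sGCCA runs
#'
#' For every subsample: the omic blocks are re-standardized on the
#' subsample only, sGCCA is fitted with the label as an extra block, the
#' putative modules are extracted, and every unordered feature pair that
#' shares at least one putative module in that run is counted once.
#' Features constant within a subsample sit out that run. A run whose fit
#' fails is skipped with a warning and the run total decremented.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param config a [pipeline_config()].
#' @param subsamples optional list of index sets (default: drawn from the
#'   config's subsampling child seed).
#' @return A `cooccurrence_counts` object: integer pair-count matrix over
#'   all features, plus `total_runs`.
#' @export
accumulate_cooccurrence <- function(dataset, config = pipeline_config(),
                                    subsamples = NULL) {
  seeds <- stage_seeds(config$seed)
  subsamples <- subsamples %||%
    draw_subsamples(dataset$labels, config$nfol, config$n_runs, seed = seeds$subsample)
  tags <- omic_tags(dataset)
  keep <- keep_per_omic(config, tags)
  design <- make_design(length(tags), config$des, label_block = TRUE)
  universe <- feature_universe(dataset)$feature
  p <- length(universe)
  counts <- matrix(0L, p, p, dimnames = list(universe, universe))
  total_runs <- 0L

  for (idx in subsamples) {
    run <- tryCatch({
      blocks <- lapply(dataset$omics, function(o) {
        v <- o$values[idx, , drop = FALSE]
        sds <- apply(v, 2, sd)
        v <- v[, sds > 0, drop = FALSE]
        standardize_block(v)
      })
      blocks$label <- encode_label_block(dataset$labels[idx])
      fit <- fit_sgcca(blocks, design, keep = c(keep, label = 1L),
                       ncomp = config$ncomp, tol = config$tol,
                       max_iter = config$max_iter, label = "label",
                       restart_width = config$restart_width)
      extract_putative_modules(fit)
    }, error = function(e) e)
    if (inherits(run, "error")) {
      warning("subsample run skipped: ", conditionMessage(run), call. = FALSE)
      next
    }
    total_runs <- total_runs + 1L
    seen <- matrix(FALSE, p, p)
    for (h in unique(run$component)) {
      members <- match(run$feature[run$component == h], universe)
      if (length(members) >= 2) seen[members, members] <- TRUE
    }
    diag(seen) <- FALSE
    counts <- counts + seen
  }
  if (total_runs == 0L) stop("every subsample run failed", call. = FALSE)
  structure(
    list(counts = counts, total_runs = total_runs, features = universe),
    class = "cooccurrence_counts"
  )
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf("<cooccurrence_counts> %d features, %d runs, %d co-occurring pairs\n",
              length(x$features), x$total_runs, sum(x$counts[upper.tri(x$counts)] > 0)))
  invisible(x)
}

#' Build the consensus co-occurrence network
#'
#' Features become nodes; an edge connects two features whose
#' co-occurrence frequency (pair count / total runs) is at least `edge`,
#' weighted by that frequency. Isolated features are dropped.
#'
#' @param counts a `cooccurrence_counts`.
#' @param edge frequency threshold in (0, 1].
#' @return An undirected [igraph::graph][igraph] with a `weight` edge
#'   attribute.
#' @export
build_consensus_network <- function(counts, edge = 0.8) {
  stopifnot(counts$total_runs > 0, edge > 0, edge <= 1)
  freq <- counts$counts / counts$total_runs
  freq[freq < edge] <- 0
  g <- igraph::graph_from_adjacency_matrix(freq, mode = "undirected", weighted = TRUE)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Extract consensus modules from the network
#'
#' Maximal connected components with at least two features, ordered by
#' decreasing size then lexicographically by first member, labelled
#' `M1, M2, ...`.
#'
#' @param graph network from [build_consensus_network()].
#' @return A `consensus_modules` object: list with `members` (tibble
#'   `module_id`, `omic`, `feature`, `degree`) and `edges` (tibble
#'   `module_id`, `feature_a`, `feature_b`, `frequency`).
#' @export
extract_consensus_modules <- function(graph) {
  comp <- igraph::components(graph)
  keep <- which(comp$csize >= 2)
  if (length(keep) == 0) {
    return(structure(list(members = empty_members(), edges = empty_edges()),
                     class = "consensus_modules"))
  }
  groups <- lapply(keep, function(k) sort(names(comp$membership)[comp$membership == k]))
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  members <- purrr::imap_dfr(groups, function(feats, i) {
    tibble::tibble(
      module_id = paste0("M", i),
      omic = omic_of_feature(feats),
      feature = feats,
      degree = igraph::degree(graph, feats)
    )
  })
  edf <- igraph::as_data_frame(graph, what = "edges")
  membership_of <- setNames(members$module_id, members$feature)
  edges <- tibble::tibble(
    module_id = unname(membership_of[edf$from]),
    feature_a = pmin(edf$from, edf$to),
    feature_b = pmax(edf$from, edf$to),
    frequency = edf$weight
  ) |>
    dplyr::arrange(.data$module_id, .data$feature_a, .data$feature_b)
  structure(list(members = members, edges = edges), class = "consensus_modules")
}

empty_members <- function() {
  tibble::tibble(module_id = character(), omic = character(),
                 feature = character(), degree = integer())
}
empty_edges <- function() {
  tibble::tibble(module_id = character(), feature_a = character(),
                 feature_b = character(), frequency = numeric())
}

#' @export
print.consensus_modules <- function(x, ...) {
  n_mod <- dplyr::n_distinct(x$members$module_id)
  cat(sprintf("<consensus_modules> %d module(s), %d feature(s)\n",
              n_mod, nrow(x$members)))
  if (n_mod > 0) {
    sizes <- dplyr::count(x$members, .data$module_id)
    for (i in seq_len(nrow(sizes))) {
      cat(sprintf("  %s: %d features\n", sizes$module_id[i], sizes$n[i]))
    }
  }
  invisible(x)
}

# named list module_id -> character vector of features
module_feature_sets <- function(modules) {
  split(modules$members$feature, modules$members$module_id)
}
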