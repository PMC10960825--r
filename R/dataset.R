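#' Align omic tables and labels into a multi-omic dataset
#'
#' Intersects sample ids across all omic tables and the label vector,
#' orders the intersection deterministically (sorted), and subsets every
#' table accordingly. Omic tags must be unique.
#'
#' @param omics list of [omic_table()] objects.
#' @param labels named 0/1 integer vector (1 = case), names = sample ids.
#' @param dataset_id identifier carried through outputs.
#' @return A `multi_omic_dataset`: list with elements `omics` (named list
#'   of omic tables sharing identical sample order), `labels`, `dataset_id`.
#' @export
align_samples <- function(omics, labels, dataset_id = "dataset") {
  stopifnot(length(omics) >= 1)
  tags <- vapply(omics, function(o) o$omic_id, character(1))
  if (anyDuplicated(tags)) stop("duplicate omic tags: ", paste(tags, collapse = ", "), call. = FALSE)
  names(omics) <- tags
  shared <- Reduce(intersect, c(lapply(omics, sample_ids), list(names(labels))))
  if (length(shared) == 0L) stop("no samples shared by all omics and the metadata", call. = FALSE)
  shared <- sort(shared)
  dropped <- length(union(unlist(lapply(omics, sample_ids)), names(labels))) - length(shared)
  if (dropped > 0) message(dropped, " sample(s) not shared by all inputs were dropped")
  omics <- lapply(omics, function(o) {
    o$values <- o$values[shared, , drop = FALSE]
    o
  })
  labels <- labels[shared]
  check_two_classes(labels)
  new_dataset(omics, labels, dataset_id)
}

new_dataset <- function(omics, labels, dataset_id) {
  structure(
    list(omics = omics, labels = labels, dataset_id = dataset_id),
    class = "multi_omic_dataset"
  )
}

#' @export
print.multi_omic_dataset <- function(x, ...) {
  cat(sprintf("<multi_omic_dataset '%s'> %d samples (%d cases / %d controls)\n",
              x$dataset_id, length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  for (o in x$omics) {
    cat(sprintf("  %s: %d features (%s scale)\n", o$omic_id, ncol(o$values), o$scale_state))
  }
  invisible(x)
}

n_samples <- function(dataset) length(dataset$labels)

omic_tags <- function(dataset) names(dataset$omics)

#' Feature inventory of a dataset
#'
#' @param dataset a `multi_omic_dataset`.
#' @return Tibble with columns `omic`, `feature` covering every feature in
#'   every omic table.
#' @export
feature_universe <- function(dataset) {
  purrr::map_dfr(dataset$omics, function(o) {
    tibble::tibble(omic = o$omic_id, feature = feature_ids(o))
  })
}

# Column-bind selected (namespaced) features across omics, preserving the
# requested order. Errors on unknown features.
feature_matrix <- function(dataset, features) {
  all_vals <- do.call(cbind, lapply(dataset$omics, function(o) o$values))
  missing <- setdiff(features, colnames(all_vals))
  if (length(missing) > 0) {
    stop("feature(s) not in dataset: ", paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  all_vals[, features, drop = FALSE]
}

omic_of_feature <- function(features) sub(":.*$", "", features)

#' Shuffle phenotype labels
#'
#' Permutes the label vector uniformly while leaving every omic table
#' untouched; class counts are preserved. Used to build empirical-null
#' datasets for calibrating the module discovery pipeline.
#'
#' @param dataset a `multi_omic_dataset`.
#' @param seed optional integer seed for a reproducible permutation.
#' @return The dataset with permuted labels.
#' @export
permute_labels <- function(dataset, seed = NULL) {
  perm <- if (is.null(seed)) {
    sample.int(n_samples(dataset))
  } else {
    withr::with_seed(seed, sample.int(n_samples(dataset)))
  }
  new_labels <- unname(dataset$labels[perm])
  names(new_labels) <- names(dataset$labels)
  dataset$labels <- new_labels
  dataset
}
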