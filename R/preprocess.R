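#' Total-sum scaling to relative abundances
#'
#' Divides each sample's counts by their sum so rows lie on the simplex.
#' Applies to taxa/pathway omics; rows already on the simplex pass through
#' unchanged (the map is idempotent).
#'
#' @param table an [omic_table()] in raw scale.
#' @return The table in `"relative"` scale.
#' @export
tss_normalize <- function(table) {
  rs <- rowSums(table$values)
  zero <- rs == 0
  if (any(zero)) {
    stop("all-zero sample(s) cannot be normalized: ",
         paste(head(sample_ids(table)[zero], 5), collapse = ", "), call. = FALSE)
  }
  table$values <- table$values / rs
  table$scale_state <- "relative"
  validate_omic_table(table)
}

#' Natural-log transform for metabolite intensities
#'
#' `value <- log(value + pseudocount)`. The default pseudocount is half the
#' minimum positive value of each feature, which keeps zeros below the
#' smallest observed intensity; a single constant can be supplied instead.
#'
#' @param table an [omic_table()] with non-negative values.
#' @param pseudocount positive scalar, or `NULL` for the per-feature
#'   default.
#' @return The table in `"log"` scale.
#' @export
log_transform <- function(table, pseudocount = NULL) {
  v <- table$values
  if (any(v < 0)) stop("negative intensities cannot be log-transformed", call. = FALSE)
  if (is.null(pseudocount)) {
    pc <- apply(v, 2, function(col) {
      pos <- col[col > 0]
      if (length(pos) == 0) 1 else min(pos) / 2
    })
    # features with no zeros need no pseudocount
    pc[colSums(v == 0) == 0] <- 0
    v <- sweep(v, 2, pc, `+`)
  } else {
    stopifnot(pseudocount > 0)
    v <- v + pseudocount
  }
  table$values <- log(v)
  table$scale_state <- "log"
  validate_omic_table(table)
}

#' Drop constant and rare features
#'
#' Removes features that are constant, that are non-zero in fewer than
#' `min_prevalence` of samples, or -- for taxa/pathway omics in relative
#' scale -- whose mean relative abundance falls below
#' `min_mean_abundance`. Prevalence is assessed on the values as given, so
#' for metabolites it should be applied before log-transforming (zeros are
#' no longer zeros afterwards).
#'
#' @param table an [omic_table()].
#' @param min_prevalence minimum non-zero fraction.
#' @param min_mean_abundance minimum mean abundance; only enforced when
#'   `table$scale_state == "relative"`.
#' @return List with `table` (filtered) and `removed`, a tibble of
#'   `feature`, `omic`, `reason`.
#' @export
filter_features <- function(table, min_prevalence = 0.15, min_mean_abundance = 5e-5) {
  v <- table$values
  constant <- apply(v, 2, function(col) all(col == col[1]))
  prevalence <- colMeans(v != 0)
  low_prev <- prevalence < min_prevalence
  low_abund <- if (table$scale_state == "relative") {
    colMeans(v) < min_mean_abundance
  } else {
    rep(FALSE, ncol(v))
  }
  reason <- dplyr::case_when(
    constant ~ "constant",
    low_prev ~ "low_prevalence",
    low_abund ~ "low_abundance",
    .default = NA_character_
  )
  drop <- !is.na(reason)
  if (all(drop)) stop("all features of omic '", table$omic_id, "' were filtered out", call. = FALSE)
  removed <- tibble::tibble(
    feature = feature_ids(table)[drop],
    omic = table$omic_id,
    reason = reason[drop]
  )
  table$values <- v[, !drop, drop = FALSE]
  list(table = table, removed = removed)
}

#' Remove features on an exclusion list
#'
#' Stand-in for curated exclusion sets such as non-bacterial pathways: the
#' listed features are dropped; ids not present are reported but harmless.
#'
#' @param table an [omic_table()].
#' @param exclusion_list character vector of feature ids (with or without
#'   the omic prefix).
#' @return List with `table` and `removed` as in [filter_features()].
#' @export
exclude_features <- function(table, exclusion_list) {
  ids <- prefix_features(exclusion_list, table$omic_id)
  present <- ids[ids %in% feature_ids(table)]
  absent <- setdiff(ids, present)
  if (length(absent) > 0) {
    warning(length(absent), " exclusion id(s) not present in omic '",
            table$omic_id, "'", call. = FALSE)
  }
  removed <- tibble::tibble(feature = present, omic = table$omic_id, reason = "excluded")
  if (length(present) > 0) {
    if (length(present) == ncol(table$values)) {
      stop("exclusion list would remove every feature of omic '", table$omic_id, "'", call. = FALSE)
    }
    table$values <- table$values[, setdiff(feature_ids(table), present), drop = FALSE]
  }
  list(table = table, removed = removed)
}

#' Collapse near-duplicate features
#'
#' Complete-linkage clusters of features whose pairwise absolute Spearman
#' correlations all exceed `threshold` are replaced by a single randomly
#' chosen representative. Such near-duplicates typically reflect technical
#' redundancy (e.g. the same signal reported twice) and destabilise sparse
#' fits downstream.
#'
#' @param table an [omic_table()].
#' @param threshold absolute correlation above which features may be
#'   merged.
#' @param seed seed for the representative choice.
#' @return List with `table`, `removed` (reason `collinear_with:<rep>`),
#'   and `map`, a tibble of `representative`, `member`.
#' @export
cluster_collinear <- function(table, threshold = 0.99, seed = 1L) {
  all_removed <- list()
  all_map <- list()
  # collapsing two clusters can leave their representatives above the
  # threshold (complete linkage is conservative); iterate to a fixed point
  # so the output has no remaining pair with |rho| > threshold
  repeat {
    step <- collinear_step(table, threshold, seed)
    if (nrow(step$removed) == 0) break
    all_removed[[length(all_removed) + 1]] <- step$removed
    all_map[[length(all_map) + 1]] <- step$map
    table <- step$table
    seed <- seed + 1L
  }
  list(
    table = table,
    removed = if (length(all_removed)) dplyr::bind_rows(all_removed) else empty_removal(),
    map = if (length(all_map)) dplyr::bind_rows(all_map) else empty_map()
  )
}

collinear_step <- function(table, threshold, seed) {
  v <- table$values
  p <- ncol(v)
  if (p < 2) {
    return(list(table = table, removed = empty_removal(), map = empty_map()))
  }
  rho <- suppressWarnings(cor(v, method = "spearman"))
  rho[is.na(rho)] <- 0
  d <- stats::as.dist(1 - abs(rho))
  tree <- stats::hclust(d, method = "complete")
  # complete linkage: a cluster cut at height h has every internal pair at
  # distance <= h, i.e. |rho| >= 1 - h; cut just below 1 - threshold so
  # only pairs with |rho| > threshold merge
  cl <- stats::cutree(tree, h = (1 - threshold) * (1 - 1e-12))
  sizes <- base::table(cl)
  multi <- as.integer(names(sizes)[sizes > 1])
  if (length(multi) == 0) {
    return(list(table = table, removed = empty_removal(), map = empty_map()))
  }
  ids <- feature_ids(table)
  map <- withr::with_seed(seed, {
    purrr::map_dfr(multi, function(k) {
      members <- ids[cl == k]
      rep_ <- sample(members, 1L)
      tibble::tibble(representative = rep_, member = members)
    })
  })
  dropped <- setdiff(map$member, map$representative)
  rep_of <- setNames(map$representative, map$member)
  removed <- tibble::tibble(
    feature = dropped,
    omic = table$omic_id,
    reason = paste0("collinear_with:", rep_of[dropped])
  )
  table$values <- v[, setdiff(ids, dropped), drop = FALSE]
  list(table = table, removed = removed, map = map)
}

empty_removal <- function() {
  tibble::tibble(feature = character(), omic = character(), reason = character())
}
empty_map <- function() {
  tibble::tibble(representative = character(), member = character())
}

#' Standardize columns against reference statistics
#'
#' Centers and scales each column using means and sample (n-1) standard
#' deviations, by default computed on the matrix itself. Inside subsampled
#' fits, reference statistics come from the subsample so no information
#' leaks across runs.
#'
#' @param m numeric matrix.
#' @param center,scale optional reference means / SDs (default: computed
#'   from `m`).
#' @return The standardized matrix.
#' @export
standardize_block <- function(m, center = NULL, scale = NULL) {
  center <- center %||% colMeans(m)
  scale <- scale %||% apply(m, 2, sd)
  bad <- scale == 0 | !is.finite(scale)
  if (any(bad)) {
    stop("constant column(s) cannot be standardized: ",
         paste(head(colnames(m)[bad], 5), collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(m, 2, center, `-`), 2, scale, `/`)
  out
}

#' Shared preprocessing for a multi-omic dataset
#'
#' Applies, per omic: taxa/pathways -- total-sum scaling, rare/constant
#' feature filtering, exclusion list, collinearity collapse; metabolites --
#' rare/constant filtering on raw intensities (zeros are only meaningful
#' there), log transform, collinearity collapse.
#'
#' @param dataset a `multi_omic_dataset` with raw tables.
#' @param config a [pipeline_config()].
#' @return List with `dataset` (processed) and `report`, a tibble listing
#'   every removed feature with its reason.
#' @export
preprocess_dataset <- function(dataset, config = pipeline_config()) {
  seeds <- stage_seeds(config$seed)
  reports <- list()
  dataset$omics <- lapply(dataset$omics, function(o) {
    compositional <- o$omic_id %in% c("T", "P")
    if (compositional) {
      if (o$scale_state == "raw") o <- tss_normalize(o)
      f <- filter_features(o, config$min_prevalence, config$min_mean_abundance)
      reports[[length(reports) + 1]] <<- f$removed
      o <- f$table
      e <- exclude_features(o, config$exclude)
      reports[[length(reports) + 1]] <<- e$removed
      o <- e$table
    } else {
      f <- filter_features(o, config$min_prevalence, config$min_mean_abundance)
      reports[[length(reports) + 1]] <<- f$removed
      o <- f$table
      if (o$scale_state == "raw") o <- log_transform(o, config$pseudocount)
    }
    cc <- cluster_collinear(o, config$collinearity_threshold, seed = seeds$collinearity)
    reports[[length(reports) + 1]] <<- cc$removed
    cc$table
  })
  list(dataset = dataset, report = dplyr::bind_rows(reports))
}
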