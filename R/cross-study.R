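#' Fisher's exact test for the overlap of two modules
#'
#' The modules are first restricted to the features present in both
#' datasets' (post-preprocessing) universes; the 2x2 table over that
#' shared universe -- in/out of module A by in/out of module B -- is then
#' tested with Fisher's exact test. Pairs overlapping in fewer than 2
#' features are recorded but flagged untested.
#'
#' @param module_a,module_b character vectors of feature ids.
#' @param universe_a,universe_b all features available in each dataset.
#' @param alternative `"two.sided"` (default) or `"greater"` for an
#'   enrichment-only test.
#' @return One-row tibble: `universe`, `a`, `b`, `overlap`, `odds_ratio`,
#'   `p`, `tested`.
#' @export
module_overlap_test <- function(module_a, module_b, universe_a, universe_b,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  universe <- intersect(universe_a, universe_b)
  if (length(universe) == 0) stop("the datasets share no features", call. = FALSE)
  a <- intersect(module_a, universe)
  b <- intersect(module_b, universe)
  k <- length(intersect(a, b))
  if (k < 2) {
    return(tibble::tibble(universe = length(universe), a = length(a),
                          b = length(b), overlap = k,
                          odds_ratio = NA_real_, p = NA_real_, tested = FALSE))
  }
  tab <- matrix(c(
    k, length(a) - k,
    length(b) - k, length(universe) - length(a) - length(b) + k
  ), nrow = 2)
  ft <- fisher.test(tab, alternative = alternative)
  # sample odds ratio (the conditional MLE in fisher.test differs)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble::tibble(universe = length(universe), a = length(a), b = length(b),
                 overlap = k, odds_ratio = or, p = ft$p.value, tested = TRUE)
}

#' BH correction over a set of overlap tests
#'
#' @param tests tibble of rows from [module_overlap_test()] (column `p`;
#'   untested rows keep `NA`).
#' @param fdr significance cutoff on the q-value (default 0.1).
#' @return The tibble with `q` and `significant` columns appended.
#' @export
overlap_fdr <- function(tests, fdr = 0.1) {
  tests$q <- p.adjust(tests$p, method = "BH")
  tests$significant <- !is.na(tests$q) & tests$q < fdr
  tests
}

#' All pairwise module overlaps across datasets
#'
#' Convenience wrapper running [module_overlap_test()] for every module
#' pair from two different datasets and applying [overlap_fdr()].
#'
#' @param module_tables named list (by dataset id) of module member
#'   tibbles (`module_id`, `feature`).
#' @param universes named list (by dataset id) of feature universes.
#' @param fdr cutoff passed to [overlap_fdr()].
#' @param alternative passed to [module_overlap_test()].
#' @return Tibble with `dataset_a`, `module_a`, `dataset_b`, `module_b`
#'   and the test columns.
#' @export
cross_study_overlaps <- function(module_tables, universes, fdr = 0.1,
                                 alternative = "two.sided") {
  ids <- names(module_tables)
  stopifnot(!is.null(ids), all(ids %in% names(universes)))
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      sets_i <- split(module_tables[[i]]$feature, module_tables[[i]]$module_id)
      sets_j <- split(module_tables[[j]]$feature, module_tables[[j]]$module_id)
      for (mi in names(sets_i)) {
        for (mj in names(sets_j)) {
          res <- module_overlap_test(sets_i[[mi]], sets_j[[mj]],
                                     universes[[ids[i]]], universes[[ids[j]]],
                                     alternative = alternative)
          rows[[length(rows) + 1]] <- dplyr::mutate(
            res, dataset_a = ids[i], module_a = mi,
            dataset_b = ids[j], module_b = mj, .before = 1
          )
        }
      }
    }
  }
  overlap_fdr(dplyr::bind_rows(rows), fdr = fdr)
}

#' Genus co-occurrence permutation test
#'
#' Tests whether species in modules co-occur with congeners more often
#' than chance. The statistic is the percentage of species occurrences
#' (pooled over all modules and datasets) that share a genus with at least
#' one other species in the same module. The null redraws each module's
#' species as a uniform same-size sample from its dataset's species
#' universe; `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param module_species named list (by dataset id) of lists of character
#'   vectors: each module's species names.
#' @param species_universes named list (by dataset id) of species-name
#'   universes.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param genus_of function mapping species names to genus (default:
#'   first whitespace-delimited token after stripping any `"omic:"`
#'   prefix), or a named character vector used as a lookup map.
#' @return List with `observed` (percent), `null_mean`, `null_ci` (central
#'   95% interval), `p`, `n_perm`, and `degenerate` (TRUE when no module
#'   has two species).
#' @export
genus_cooccurrence_test <- function(module_species, species_universes,
                                    n_perm = 1000, seed = 1L,
                                    genus_of = NULL) {
  if (is.character(genus_of)) {
    map <- genus_of
    genus_of <- function(x) unname(map[x])
  }
  genus_of <- genus_of %||% default_genus
  stat <- function(mods_by_ds) {
    shared <- 0L
    total <- 0L
    for (ds in names(mods_by_ds)) {
      for (sp in mods_by_ds[[ds]]) {
        if (length(sp) == 0) next
        g <- genus_of(sp)
        dup <- g %in% g[duplicated(g)]
        shared <- shared + sum(dup)
        total <- total + length(sp)
      }
    }
    if (total == 0) return(NA_real_)
    100 * shared / total
  }
  observed <- stat(module_species)
  degenerate <- all(vapply(unlist(module_species, recursive = FALSE),
                           length, integer(1)) < 2)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- purrr::imap(module_species, function(mods, ds) {
        uni <- species_universes[[ds]]
        lapply(mods, function(sp) sample(uni, length(sp)))
      })
      stat(perm)
    }, numeric(1))
  })
  list(
    observed = observed,
    null_mean = mean(nulls),
    null_ci = unname(quantile(nulls, c(0.025, 0.975))),
    p = (1 + sum(nulls >= observed)) / (n_perm + 1),
    n_perm = n_perm,
    degenerate = degenerate
  )
}

default_genus <- function(x) {
  x <- sub("^[A-Za-z]+:", "", x)
  vapply(strsplit(x, "\\s+"), `[`, character(1), 1)
}
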