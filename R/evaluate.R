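#' First principal component of a module's features
#'
#' Centers and unit-scales the module's submatrix (across all omics) and
#' returns the first PC scores as the module's single representative.
#' Constant features cannot be scaled and are dropped with a warning.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param features character vector of namespaced feature ids (>= 2).
#' @return Numeric score vector (one value per sample) with attribute
#'   `"explained"`, the fraction of variance PC1 captures.
#' @export
module_pc1 <- function(dataset, features) {
  stopifnot(length(features) >= 2)
  m <- feature_matrix(dataset, features)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("constant module feature(s) dropped: ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 1) stop("no non-constant module features left", call. = FALSE)
  }
  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1]
  attr(scores, "explained") <- pca$sdev[1]^2 / sum(pca$sdev^2)
  scores
}

#' Rank-based AUC of a score vector, orientation-corrected
#'
#' The probability that a random case outranks a random control
#' (Mann-Whitney AUC), folded to `max(A, 1 - A)` because the sign of a
#' principal component is arbitrary. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector, both classes present.
#' @param orient fold the AUC above 0.5? (Set `FALSE` for the raw
#'   direction-sensitive value.)
#' @return AUC in `[0.5, 1]` (or `[0, 1]` unoriented).
#' @export
pc1_auc <- function(scores, labels, orient = TRUE) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) max(a, 1 - a) else a
}

#' Draw one size-matched null module
#'
#' Samples, uniformly without replacement within each omic, the same
#' number of features as the observed module holds from that omic.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param size_per_omic named integer vector, e.g. `c(T = 2, M = 1)`.
#' @return Character vector of feature ids.
#' @export
sample_null_module <- function(dataset, size_per_omic) {
  size_per_omic <- size_per_omic[size_per_omic > 0]
  out <- purrr::imap(as.list(size_per_omic), function(k, tag) {
    pool <- feature_ids(dataset$omics[[tag]])
    if (length(pool) < k) {
      stop("omic '", tag, "' has only ", length(pool), " features; ", k, " requested",
           call. = FALSE)
    }
    sample(pool, k)
  })
  unname(unlist(out))
}

#' Cross-omic Spearman correlation of a module
#'
#' Spearman's rho for every feature pair spanning two different omics,
#' with Benjamini-Hochberg q-values across the module's pairs, and the
#' (signed, by default) mean as the module-level statistic. Modules
#' confined to one omic have no cross-omic pairs; they return `NA` and are
#' excluded from the disease-associated classification.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param features namespaced feature ids.
#' @param absolute average `|rho|` instead of signed rho.
#' @param pvalues compute per-pair p/q-values (asymptotic t
#'   approximation, as in `cor.test`)? Skipping them makes the null-module
#'   path cheap.
#' @param partial additionally report `partial_rho`, the Spearman
#'   correlation of each pair after residualizing both features' ranks on
#'   the disease label -- a descriptive check that a pair's coupling is
#'   not driven by the case/control contrast alone. Never used in
#'   classification.
#' @return List with `mean_rho` and `pairs` (tibble `feature_a`,
#'   `feature_b`, `rho`, and -- with `pvalues = TRUE` -- `p`, `q`).
#' @export
cross_omic_correlation <- function(dataset, features, absolute = FALSE,
                                   pvalues = TRUE, partial = FALSE) {
  omic <- omic_of_feature(features)
  if (length(unique(omic)) < 2) {
    return(list(mean_rho = NA_real_, pairs = tibble::tibble(
      feature_a = character(), feature_b = character(),
      rho = numeric(), p = numeric(), q = numeric()
    )))
  }
  m <- feature_matrix(dataset, features)
  rho_mat <- suppressWarnings(cor(m, method = "spearman"))
  pairs <- tidyr::crossing(a = seq_along(features), b = seq_along(features)) |>
    dplyr::filter(.data$a < .data$b, omic[.data$a] != omic[.data$b])
  res <- tibble::tibble(
    feature_a = features[pairs$a], feature_b = features[pairs$b],
    rho = rho_mat[cbind(pairs$a, pairs$b)]
  )
  if (pvalues) {
    # t approximation on n - 2 df, matching cor.test(exact = FALSE)
    n <- nrow(m)
    tstat <- res$rho * sqrt((n - 2) / pmax(1 - res$rho^2, .Machine$double.eps))
    res$p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    res$q <- p.adjust(res$p, method = "BH")
  }
  if (partial) {
    # ranks residualized on the label, then correlated
    y <- dataset$labels
    resid_ranks <- apply(m, 2, function(col) stats::residuals(stats::lm(rank(col) ~ y)))
    pr <- cor(resid_ranks)
    res$partial_rho <- pr[cbind(pairs$a, pairs$b)]
  }
  mean_rho <- if (absolute) mean(abs(res$rho)) else mean(res$rho)
  list(mean_rho = mean_rho, pairs = res)
}

#' Null distributions for a module's AUC and cross-omic correlation
#'
#' Draws `n_null` random modules with the observed module's per-omic
#' feature counts, evaluates each one exactly like the observed module
#' (PC1 AUC, mean cross-omic Spearman), and summarises the null mean and
#' SD. The exceedance flag reports whether the observed statistic beats
#' the null (mean rule by default, 95th percentile optional).
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param features observed module feature ids.
#' @param n_null number of null modules.
#' @param seed RNG seed for the draws.
#' @param exceedance `"mean"` or `"q95"`.
#' @param absolute passed to [cross_omic_correlation()].
#' @return Tibble with one row per statistic (`auc`, `rho`): observed
#'   value, null mean/SD, exceedance flag.
#' @export
null_distributions <- function(dataset, features, n_null = 100, seed = NULL,
                               exceedance = c("mean", "q95"), absolute = FALSE) {
  exceedance <- match.arg(exceedance)
  sizes <- base::table(omic_of_feature(features))
  size_per_omic <- setNames(as.integer(sizes), names(sizes))
  obs_auc <- pc1_auc(module_pc1(dataset, features), dataset$labels)
  obs_rho <- cross_omic_correlation(dataset, features, absolute,
                                    pvalues = FALSE)$mean_rho

  draw_one <- function() {
    nf <- sample_null_module(dataset, size_per_omic)
    c(
      auc = pc1_auc(suppressWarnings(module_pc1(dataset, nf)), dataset$labels),
      rho = cross_omic_correlation(dataset, nf, absolute, pvalues = FALSE)$mean_rho
    )
  }
  nulls <- if (is.null(seed)) {
    replicate(n_null, draw_one())
  } else {
    withr::with_seed(seed, replicate(n_null, draw_one()))
  }
  summarise_null <- function(stat, obs) {
    vals <- nulls[stat, ]
    vals <- vals[!is.na(vals)]
    ref <- if (exceedance == "mean") mean(vals) else quantile(vals, 0.95, names = FALSE)
    tibble::tibble(
      statistic = stat, observed = obs,
      null_mean = mean(vals), null_sd = sd(vals),
      n_null = length(vals),
      exceeds = !is.na(obs) && obs > ref
    )
  }
  dplyr::bind_rows(summarise_null("auc", obs_auc), summarise_null("rho", obs_rho))
}

#' Classify a module as disease-associated
#'
#' A module qualifies only if it spans at least two omics, its PC1 AUC
#' exceeds `auc_threshold`, and both its AUC and its mean cross-omic
#' correlation exceed the corresponding null references.
#'
#' @param auc observed oriented PC1 AUC.
#' @param auc_exceeds,rho_exceeds null exceedance flags.
#' @param multi_omic does the module span >= 2 omics?
#' @param auc_threshold AUC cutoff (default 0.7).
#' @return Logical.
#' @export
classify_module <- function(auc, auc_exceeds, rho_exceeds, multi_omic,
                            auc_threshold = 0.7) {
  isTRUE(multi_omic) && !is.na(auc) && auc > auc_threshold &&
    isTRUE(auc_exceeds) && isTRUE(rho_exceeds)
}

#' Evaluate consensus modules against null modules
#'
#' Runs the full evaluation protocol for every consensus module: PC1 AUC,
#' mean cross-omic Spearman correlation, size-matched null benchmarks for
#' both, and the final disease-associated classification.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param modules a `consensus_modules` object (or its `members` tibble).
#' @param config a [pipeline_config()].
#' @return A `module_evaluation` tibble: one row per module with columns
#'   `module_id`, `n_features`, `n_omics`, `auc`, `auc_null_mean`,
#'   `auc_null_sd`, `auc_exceeds`, `rho`, `rho_null_mean`, `rho_null_sd`,
#'   `rho_exceeds`, `multi_omic`, `disease_associated`; the per-pair
#'   correlation table is attached as attribute `"pairwise"`.
#' @export
evaluate_modules <- function(dataset, modules, config = pipeline_config()) {
  members <- if (inherits(modules, "consensus_modules")) modules$members else modules
  seeds <- stage_seeds(config$seed)
  sets <- split(members$feature, members$module_id)
  if (length(sets) == 0) {
    out <- empty_evaluation()
    attr(out, "pairwise") <- tibble::tibble()
    class(out) <- c("module_evaluation", class(out))
    return(out)
  }
  pairwise <- list()
  rows <- purrr::imap(sets, function(feats, id) {
    co <- cross_omic_correlation(dataset, feats, config$rho_absolute)
    pairwise[[id]] <<- dplyr::mutate(co$pairs, module_id = id, .before = 1)
    multi <- length(unique(omic_of_feature(feats))) >= 2
    nulls <- null_distributions(
      dataset, feats, n_null = config$n_null,
      seed = seeds$null + match(id, names(sets)),
      exceedance = config$exceedance, absolute = config$rho_absolute
    )
    auc_row <- nulls[nulls$statistic == "auc", ]
    rho_row <- nulls[nulls$statistic == "rho", ]
    tibble::tibble(
      module_id = id,
      n_features = length(feats),
      n_omics = length(unique(omic_of_feature(feats))),
      auc = auc_row$observed,
      auc_null_mean = auc_row$null_mean, auc_null_sd = auc_row$null_sd,
      auc_exceeds = auc_row$exceeds,
      rho = rho_row$observed,
      rho_null_mean = rho_row$null_mean, rho_null_sd = rho_row$null_sd,
      rho_exceeds = rho_row$exceeds,
      multi_omic = multi,
      disease_associated = classify_module(auc_row$observed, auc_row$exceeds,
                                           rho_row$exceeds, multi,
                                           config$auc_threshold)
    )
  })
  out <- dplyr::bind_rows(rows)
  # keep module order M1, M2, ... (split() sorts alphabetically)
  out <- out[order(as.integer(sub("^M", "", out$module_id))), ]
  attr(out, "pairwise") <- dplyr::bind_rows(pairwise)
  class(out) <- c("module_evaluation", class(out))
  out
}

empty_evaluation <- function() {
  tibble::tibble(
    module_id = character(), n_features = integer(), n_omics = integer(),
    auc = numeric(), auc_null_mean = numeric(), auc_null_sd = numeric(),
    auc_exceeds = logical(), rho = numeric(), rho_null_mean = numeric(),
    rho_null_sd = numeric(), rho_exceeds = logical(), multi_omic = logical(),
    disease_associated = logical()
  )
}

#' Per-feature direction of change between classes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per module feature,
#' with BH correction within each omic of the module; direction is the
#' sign of the case-minus-control median difference, reported as
#' `"up"`/`"down"` when the q-value clears `fdr` and `"ns"` otherwise.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param features namespaced feature ids.
#' @param fdr significance cutoff on the q-value (default 0.05).
#' @return Tibble `feature`, `omic`, `direction`, `median_diff`, `p`, `q`.
#' @export
differential_direction <- function(dataset, features, fdr = 0.05) {
  m <- feature_matrix(dataset, features)
  y <- dataset$labels
  res <- purrr::map_dfr(seq_along(features), function(i) {
    x <- m[, i]
    wt <- suppressWarnings(wilcox.test(x[y == 1], x[y == 0], exact = FALSE))
    tibble::tibble(
      feature = features[i],
      omic = omic_of_feature(features[i]),
      median_diff = median(x[y == 1]) - median(x[y == 0]),
      p = wt$p.value
    )
  })
  res |>
    dplyr::group_by(.data$omic) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$q >= fdr ~ "ns",
      .data$median_diff > 0 ~ "up",
      .data$median_diff < 0 ~ "down",
      .default = "ns"
    )) |>
    dplyr::select("feature", "omic", "direction", "median_diff", "p", "q")
}

#' Cross-validated AUC of a forest on module representatives
#'
#' Trains a random forest whose inputs are the modules' first principal
#' components and estimates its AUC by repeated stratified k-fold
#' cross-validation. PCA loadings (and the scaling underlying them) are
#' fitted on training folds only and applied to the held-out fold, so the
#' estimate is leakage-free.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param modules a `consensus_modules` object or members tibble.
#' @param nfold folds (default 10).
#' @param repeats repetitions of the fold split.
#' @param num_trees forest size.
#' @param seed RNG seed.
#' @return List with `mean_auc`, `sd_auc` and the per-fold tibble `folds`.
#' @export
modules_pc_rf <- function(dataset, modules, nfold = 10, repeats = 5,
                          num_trees = 500, seed = 1L) {
  members <- if (inherits(modules, "consensus_modules")) modules$members else modules
  sets <- split(members$feature, members$module_id)
  stopifnot(length(sets) >= 1)
  y <- dataset$labels
  folds_tbl <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- stratified_fold_ids(y, nfold)
      purrr::map_dfr(seq_len(nfold), function(f) {
        tr <- which(fold != f)
        te <- which(fold == f)
        if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
          warning("fold with a single class skipped", call. = FALSE)
          return(NULL)
        }
        pcs <- purrr::map(sets, function(feats) train_test_pc1(dataset, feats, tr, te))
        xtr <- do.call(cbind, purrr::map(pcs, "train"))
        xte <- do.call(cbind, purrr::map(pcs, "test"))
        colnames(xtr) <- colnames(xte) <- names(sets)
        rf <- ranger::ranger(
          x = as.data.frame(xtr), y = factor(y[tr], levels = c(0, 1)),
          num.trees = num_trees, probability = TRUE,
          seed = seed + r * 1000L + f
        )
        prob <- predict(rf, data = as.data.frame(xte))$predictions[, "1"]
        tibble::tibble(repeat_ = r, fold = f,
                       auc = pc1_auc(prob, y[te], orient = FALSE))
      })
    })
  })
  list(mean_auc = mean(folds_tbl$auc), sd_auc = sd(folds_tbl$auc), folds = folds_tbl)
}

# PC1 fitted on training rows, projected onto held-out rows. Features
# constant in training are dropped for both splits.
train_test_pc1 <- function(dataset, features, train_idx, test_idx) {
  m <- feature_matrix(dataset, features)
  mtr <- m[train_idx, , drop = FALSE]
  ctr <- colMeans(mtr)
  str_ <- apply(mtr, 2, sd)
  ok <- str_ > 0
  mtr <- standardize_block(mtr[, ok, drop = FALSE], ctr[ok], str_[ok])
  mte <- standardize_block(m[test_idx, ok, drop = FALSE], ctr[ok], str_[ok])
  v <- svd(mtr, nu = 0, nv = 1)$v[, 1]
  list(train = drop(mtr %*% v), test = drop(mte %*% v))
}
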