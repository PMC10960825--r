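#' Shadow-feature (all-relevant) feature selection
#'
#' Boruta-style selection: each iteration appends a shuffled "shadow" copy
#' of every candidate feature, fits a random forest with permutation
#' importance, and scores a hit for candidates whose importance beats the
#' best shadow. Features whose hit counts are binomially significantly
#' below chance are dropped as they resolve; after the final iteration the
#' selected set contains every feature with a hit fraction of at least
#' one half.
#'
#' @param x numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param n_iter shadow iterations (default 10).
#' @param num_trees trees per forest.
#' @param alpha binomial rejection level for early dropping.
#' @param seed RNG seed.
#' @return Character vector of selected feature names.
#' @export
select_features_shadow <- function(x, y, n_iter = 10, num_trees = 300,
                                   alpha = 0.01, seed = 1L) {
  stopifnot(!is.null(colnames(x)))
  withr::with_seed(seed, {
    active <- colnames(x)
    hits <- setNames(integer(ncol(x)), colnames(x))
    iters <- setNames(integer(ncol(x)), colnames(x))
    for (it in seq_len(n_iter)) {
      if (length(active) == 0) break
      xa <- x[, active, drop = FALSE]
      shadow <- apply(xa, 2, sample)
      colnames(shadow) <- paste0(".shadow.", active)
      df <- as.data.frame(cbind(xa, shadow))
      rf <- ranger::ranger(
        x = df, y = factor(y, levels = c(0, 1)),
        num.trees = num_trees, importance = "permutation",
        seed = sample.int(2^30, 1)
      )
      imp <- rf$variable.importance
      max_shadow <- max(imp[startsWith(names(imp), ".shadow.")])
      hit <- imp[active] > max_shadow
      hits[active] <- hits[active] + hit
      iters[active] <- iters[active] + 1L
      # two-sided binomial check: features already resolvably below chance
      # stop being refit
      if (it >= 4) {
        p_low <- stats::pbinom(hits[active], iters[active], 0.5)
        active <- active[p_low >= alpha / 2]
      }
    }
    frac <- ifelse(iters > 0, hits / iters, 0)
    names(frac)[frac >= 0.5]
  })
}

#' Early-integration random-forest baseline
#'
#' Concatenates all omic feature tables, then estimates disease
#' predictability by repeated stratified k-fold cross-validation: within
#' each training fold, shadow-feature selection reduces the feature set
#' and a random forest is trained on the survivors; AUC is scored on the
#' held-out fold. Selection and training never see held-out samples.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param folds folds per repetition (default 5).
#' @param repeats repetitions (default 10).
#' @param num_trees trees for the fold models.
#' @param selection_iters shadow iterations per fold.
#' @param seed RNG seed.
#' @return A `cv_result`: list with `mean_auc`, `sd_auc`, `folds` (tibble
#'   `repeat_`, `fold`, `auc`, `n_selected`), `selection` (tibble
#'   `feature`, `omic`, `selection_freq`), and the fitted fold details
#'   needed for importance analysis.
#' @export
early_integration_cv <- function(dataset, folds = 5, repeats = 10,
                                 num_trees = 500, selection_iters = 10,
                                 seed = 1L) {
  x <- feature_matrix(dataset, feature_universe(dataset)$feature)
  y <- dataset$labels
  fold_rows <- list()
  importances <- list()
  selected_sets <- list()
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_fold_ids(y, folds)
      for (f in seq_len(folds)) {
        tr <- which(fold != f)
        te <- which(fold == f)
        if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
          warning("fold with a single class skipped", call. = FALSE)
          next
        }
        sel <- select_features_shadow(
          x[tr, , drop = FALSE], y[tr],
          n_iter = selection_iters, seed = sample.int(2^30, 1)
        )
        if (length(sel) == 0) {
          # nothing survives selection: an uninformative fold model
          fold_rows[[length(fold_rows) + 1]] <-
            tibble::tibble(repeat_ = r, fold = f, auc = 0.5, n_selected = 0L)
          selected_sets[[length(selected_sets) + 1]] <- character()
          next
        }
        rf <- ranger::ranger(
          x = as.data.frame(x[tr, sel, drop = FALSE]),
          y = factor(y[tr], levels = c(0, 1)),
          num.trees = num_trees, probability = TRUE,
          importance = "permutation", seed = sample.int(2^30, 1)
        )
        prob <- predict(rf, data = as.data.frame(x[te, sel, drop = FALSE]))$predictions[, "1"]
        fold_rows[[length(fold_rows) + 1]] <-
          tibble::tibble(repeat_ = r, fold = f,
                         auc = pc1_auc(prob, y[te], orient = FALSE),
                         n_selected = length(sel))
        selected_sets[[length(selected_sets) + 1]] <- sel
        importances[[length(importances) + 1]] <- rf$variable.importance
      }
    }
  })
  folds_tbl <- dplyr::bind_rows(fold_rows)
  n_models <- length(selected_sets)
  all_feats <- colnames(x)
  sel_freq <- vapply(all_feats, function(ft) {
    mean(vapply(selected_sets, function(s) ft %in% s, logical(1)))
  }, numeric(1))
  # a feature absent from a fold model contributed nothing there: count it
  # as zero so the average is not conditioned on having been selected
  mean_imp <- vapply(all_feats, function(ft) {
    vals <- vapply(importances, function(im) {
      v <- im[ft]
      if (is.na(v)) 0 else v
    }, numeric(1))
    if (length(vals) == 0) 0 else sum(vals) / max(n_models, 1L)
  }, numeric(1))
  structure(
    list(
      mean_auc = mean(folds_tbl$auc), sd_auc = sd(folds_tbl$auc),
      mean_n_selected = mean(folds_tbl$n_selected),
      folds = folds_tbl,
      selection = tibble::tibble(
        feature = all_feats, omic = omic_of_feature(all_feats),
        selection_freq = unname(sel_freq), importance = unname(mean_imp)
      ),
      n_models = n_models
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean AUC %.3f (SD %.3f) over %d fold-models; mean %.1f features selected\n",
              x$mean_auc, x$sd_auc, nrow(x$folds), x$mean_n_selected))
  invisible(x)
}

#' Permutation-based importance p-values (label-permutation null)
#'
#' Builds a null importance distribution per feature by refitting the
#' forest on label-permuted data `n_label_perms` times; the p-value is the
#' smoothed fraction of null refits whose importance reaches the observed
#' mean importance, `(1 + #{null >= obs}) / (B + 1)`. q-values are BH
#' across the supplied feature set, and features selected in at least half
#' the fold models with `q < fdr` are flagged as contributors.
#'
#' @param dataset a preprocessed `multi_omic_dataset`.
#' @param cv_result result of [early_integration_cv()].
#' @param features features to test (default: those ever selected).
#' @param n_label_perms permutation refits (default 100).
#' @param num_trees trees per refit.
#' @param fdr contributor q-value cutoff (default 0.1).
#' @param seed RNG seed.
#' @return Tibble `feature`, `omic`, `selection_freq`, `importance`, `p`,
#'   `q`, `contributor`.
#' @export
feature_importance <- function(dataset, cv_result, features = NULL,
                               n_label_perms = 100, num_trees = 500,
                               fdr = 0.1, seed = 1L) {
  sel <- cv_result$selection
  features <- features %||% sel$feature[sel$selection_freq > 0]
  stopifnot(length(features) > 0)
  x <- feature_matrix(dataset, features)
  y <- dataset$labels
  obs <- setNames(sel$importance[match(features, sel$feature)], features)
  null_imp <- withr::with_seed(seed, {
    vapply(seq_len(n_label_perms), function(b) {
      rf <- ranger::ranger(
        x = as.data.frame(x), y = factor(sample(y), levels = c(0, 1)),
        num.trees = num_trees, importance = "permutation",
        seed = sample.int(2^30, 1)
      )
      rf$variable.importance[features]
    }, numeric(length(features)))
  })
  if (is.null(dim(null_imp))) null_imp <- matrix(null_imp, nrow = 1)
  p <- vapply(seq_along(features), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    (1 + sum(null_imp[i, ] >= obs[i])) / (n_label_perms + 1)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  freq <- sel$selection_freq[match(features, sel$feature)]
  tibble::tibble(
    feature = features, omic = omic_of_feature(features),
    selection_freq = freq, importance = unname(obs),
    p = p, q = q,
    contributor = !is.na(q) & freq >= 0.5 & q < fdr
  )
}

#' Overlap between module members and baseline contributors
#'
#' For each module, the fraction of its features that are contributors of
#' the early-integration model, with the mean and SD across modules.
#'
#' @param modules a `consensus_modules` object or members tibble.
#' @param contributors character vector of contributor feature ids (e.g.
#'   from [feature_importance()]).
#' @return List with `per_module` (tibble `module_id`, `n_features`,
#'   `n_contributors`, `fraction`) and `mean`, `sd`.
#' @export
contributor_overlap <- function(modules, contributors) {
  members <- if (inherits(modules, "consensus_modules")) modules$members else modules
  per_module <- members |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_contributors = sum(.data$feature %in% contributors),
      fraction = .data$n_contributors / .data$n_features
    )
  list(per_module = per_module,
       mean = mean(per_module$fraction),
       sd = sd(per_module$fraction))
}
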