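#' Specification for a synthetic multi-omic dataset
#'
#' Describes a benchmark dataset with known ground truth: balanced
#' case/control labels, lognormal-compositional taxa ("T") and pathway
#' ("P") profiles, lognormal metabolite intensities ("M"), and one or more
#' planted cross-omic modules. Each planted module has a latent factor
#' `z = 2 * alpha * (label - 1/2) + N(0, 1)`; each planted feature tracks
#' it as `beta * z + sigma * N(0, 1)` on the log scale, so `alpha` is the
#' between-class shift of the module axis in SD units, `beta` the loading
#' strength, and `sigma` the feature-level noise. The defaults plant a
#' single (5, 5, 5)-feature module with `alpha = 1.5`, `beta = 1`,
#' `sigma = 0.7` in a 200-sample dataset with 100 T, 100 P and 60 M
#' features.
#'
#' @param n_samples number of samples (labels balanced).
#' @param n_features named per-omic background+planted feature counts.
#' @param modules list of planted module specs; each a list with
#'   `size` (named per-omic feature counts), `alpha`, `beta`, `sigma`.
#'   `alpha = 0` plants a label-free (null) module. Default: one module of
#'   up to 5 features per omic at the default effect sizes above.
#' @param dropout fraction of T/P count mass randomly zeroed before
#'   closure (default 0: no zero-inflation).
#' @param dataset_id carried into the generated dataset.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200,
                           n_features = c(T = 100, P = 100, M = 60),
                           modules = NULL,
                           dropout = 0,
                           dataset_id = "synthetic") {
  stopifnot(n_samples >= 8, all(n_features >= 1), dropout >= 0, dropout < 1)
  if (is.null(modules)) {
    size <- setNames(pmin(5L, n_features), names(n_features))
    modules <- list(list(size = size, alpha = 1.5, beta = 1, sigma = 0.7))
  }
  for (m in modules) {
    stopifnot(!is.null(names(m$size)),
              all(names(m$size) %in% names(n_features)),
              all(m$size >= 1), m$beta > 0, m$sigma >= 0, m$alpha >= 0)
  }
  planted_per_omic <- colSums(do.call(rbind, lapply(modules, function(m) {
    v <- setNames(numeric(length(n_features)), names(n_features))
    v[names(m$size)] <- m$size
    v
  })))
  if (any(planted_per_omic > n_features)) {
    stop("planted features exceed omic widths", call. = FALSE)
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 modules = modules, dropout = dropout, dataset_id = dataset_id),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-omic dataset with planted modules
#'
#' Labels are balanced. Taxa and pathway features are lognormal counts
#' closed to relative abundances (compositional); metabolite features are
#' lognormal raw intensities whose log the preprocessing pipeline
#' recovers. Planted features of a module share the module's latent
#' factor; planted features are disjoint across modules and are drawn
#' from the first columns of each omic (named `<omic>:mod<m>_f<k>`),
#' backgrounds are `<omic>:bg<k>`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return List with `dataset` (a `multi_omic_dataset` of raw tables and
#'   labels) and `truth` (tibble `module_id`, `omic`, `feature`, `alpha`,
#'   `beta`, `sigma`).
#' @export
simulate_multiomics <- function(spec = synthetic_spec(), seed = 1L) {
  withr::with_seed(seed, {
    n <- spec$n_samples
    labels <- rep_len(c(0L, 1L), n)
    ids <- sprintf("s%03d", seq_len(n))
    names(labels) <- ids

    z <- lapply(spec$modules, function(m) 2 * m$alpha * (labels - 0.5) + rnorm(n))

    truth <- list()
    omics <- list()
    for (tag in names(spec$n_features)) {
      p <- spec$n_features[[tag]]
      compositional <- tag %in% c("T", "P")
      # per-feature baseline log-abundance / log-intensity
      mu <- if (compositional) rnorm(p, 0, 1.5) else rnorm(p, 8, 1)
      logv <- matrix(rnorm(n * p), n, p) + matrix(mu, n, p, byrow = TRUE)
      fnames <- sprintf("bg%03d", seq_len(p))
      col <- 1L
      for (mi in seq_along(spec$modules)) {
        m <- spec$modules[[mi]]
        k <- m$size[tag]
        if (is.na(k) || k == 0) next
        for (j in seq_len(k)) {
          logv[, col] <- mu[col] + m$beta * z[[mi]] + m$sigma * rnorm(n)
          fnames[col] <- sprintf("mod%d_f%d", mi, j)
          truth[[length(truth) + 1]] <- tibble::tibble(
            module_id = paste0("P", mi), omic = tag,
            feature = paste0(tag, ":", fnames[col]),
            alpha = m$alpha, beta = m$beta, sigma = m$sigma
          )
          col <- col + 1L
        }
      }
      raw <- exp(logv)
      if (compositional) {
        if (spec$dropout > 0) {
          raw[matrix(runif(n * p) < spec$dropout, n, p)] <- 0
        }
        rs <- rowSums(raw)
        rs[rs == 0] <- 1
        raw <- raw / rs
      }
      dimnames(raw) <- list(ids, fnames)
      omics[[tag]] <- omic_table(raw, tag, scale_state = "raw")
    }
    list(
      dataset = new_dataset(omics, labels, spec$dataset_id),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Recovery of planted modules by discovered modules
#'
#' For every planted module, the best F1 between its member set and any
#' discovered module; also counts discovered modules with no planted
#' member at all that were nevertheless classified disease-associated
#' (false-positive modules).
#'
#' @param found a `consensus_modules` object or members tibble
#'   (`module_id`, `feature`); optionally an evaluation tibble via
#'   `evaluation` to identify false positives.
#' @param truth truth tibble from [simulate_multiomics()].
#' @param evaluation optional `module_evaluation` tibble.
#' @return List with `per_module` (tibble `module_id`, `best_match`,
#'   `precision`, `recall`, `f1`), `mean_f1`, and `n_false_positive`.
#' @export
recovery_score <- function(found, truth, evaluation = NULL) {
  members <- if (inherits(found, "consensus_modules")) found$members else found
  found_sets <- split(members$feature, members$module_id)
  truth_sets <- split(truth$feature, truth$module_id)
  per_module <- purrr::imap_dfr(truth_sets, function(tf, id) {
    if (length(found_sets) == 0) {
      return(tibble::tibble(module_id = id, best_match = NA_character_,
                            precision = 0, recall = 0, f1 = 0))
    }
    scores <- purrr::imap_dfr(found_sets, function(ff, fid) {
      tp <- length(intersect(tf, ff))
      prec <- tp / length(ff)
      rec <- tp / length(tf)
      f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
      tibble::tibble(best_match = fid, precision = prec, recall = rec, f1 = f1)
    })
    best <- scores[which.max(scores$f1), ]
    dplyr::mutate(best, module_id = id, .before = 1)
  })
  planted <- unique(truth$feature)
  fp_ids <- names(found_sets)[vapply(found_sets, function(ff) {
    length(intersect(ff, planted)) == 0
  }, logical(1))]
  if (!is.null(evaluation)) {
    assoc <- evaluation$module_id[evaluation$disease_associated]
    fp_ids <- intersect(fp_ids, assoc)
  }
  list(per_module = per_module, mean_f1 = mean(per_module$f1),
       n_false_positive = length(fp_ids))
}
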