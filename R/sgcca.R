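#' Encode a binary phenotype as a single-feature block
#'
#' The label enters the multi-block fit as one centered, unit-SD column
#' (positive for cases, negative for controls). Flipping the class coding
#' only flips the column's sign, which leaves selected feature sets
#' unchanged.
#'
#' @param labels 0/1 vector with both classes present.
#' @return An n x 1 matrix named `"label"`.
#' @export
encode_label_block <- function(labels) {
  check_two_classes(labels)
  col <- (labels - mean(labels)) / sd(labels)
  matrix(unname(col), ncol = 1, dimnames = list(names(labels), "label"))
}

#' Block design matrix with a label block
#'
#' Every pair of omic blocks is connected with weight `des`; the label
#' block (last row/column when present) is connected to every omic block
#' with weight 1. The diagonal is zero. With `des = 0` the omic blocks
#' interact only through the label.
#'
#' @param n_omics number of omic blocks.
#' @param des pairwise weight between omic blocks, `>= 0`.
#' @param label_block append the label row/column?
#' @return A symmetric `(n_omics + label_block)` square matrix.
#' @export
make_design <- function(n_omics, des = 1, label_block = TRUE) {
  stopifnot(n_omics >= 1, des >= 0)
  J <- n_omics + as.integer(label_block)
  C <- matrix(des, J, J)
  if (label_block) {
    C[J, ] <- 1
    C[, J] <- 1
  }
  diag(C) <- 0
  C
}

check_design <- function(C, n_blocks) {
  if (!is.matrix(C) || nrow(C) != n_blocks || ncol(C) != n_blocks ||
      !isTRUE(all.equal(C, t(C))) || any(diag(C) != 0) || any(C < 0)) {
    stop("design must be a symmetric non-negative matrix with zero diagonal over all blocks",
         call. = FALSE)
  }
  invisible(C)
}

# Soft-threshold u at its (keep+1)-th largest |entry| so exactly `keep`
# entries stay non-zero; ties broken toward the lowest feature index.
soft_keep <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  a <- abs(u)
  ord <- order(-a, seq_len(p))
  thr <- a[ord[keep + 1L]]
  out <- sign(u) * pmax(a - thr, 0)
  keep_idx <- ord[seq_len(keep)]
  out[-keep_idx] <- 0
  zeroed <- keep_idx[out[keep_idx] == 0]
  if (length(zeroed) > 0) {
    # exact ties with the threshold: keep the lowest-index tied entries at
    # a negligible magnitude so the non-zero count stays exact
    out[zeroed] <- sign(u[zeroed]) * max(thr, 1) * 1e-9
  }
  out
}

sgcca_criterion <- function(C, t_list) {
  J <- length(t_list)
  s <- 0
  for (j in seq_len(J - 1)) {
    for (k in (j + 1):J) {
      if (C[j, k] != 0) s <- s + C[j, k] * cov(t_list[[j]], t_list[[k]])
    }
  }
  drop(s)
}

dominant_right_sv <- function(X) {
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

# One alternating-update solve for a single component, from a given start.
# start = NULL: dense warm-up from each block's dominant right singular
# vector (no sparsity for a few sweeps), then sparse updates. start =
# list(j, i, s): block j starts at the signed basis vector s * e_i and is
# updated last in each sweep so the other blocks respond to it first.
sgcca_component <- function(blocks, C, keep, tol, max_iter, start = NULL) {
  J <- length(blocks)
  a <- lapply(blocks, dominant_right_sv)
  sweep_order <- seq_len(J)
  t_list <- mapply(function(X, ai) drop(X %*% ai), blocks, a, SIMPLIFY = FALSE)
  if (is.null(start)) {
    for (it in seq_len(25L)) {
      for (j in sweep_order) {
        w <- inner_target(C, t_list, j)
        u <- drop(crossprod(blocks[[j]], w))
        nrm <- sqrt(sum(u^2))
        if (nrm > 0) {
          a[[j]] <- u / nrm
          t_list[[j]] <- drop(blocks[[j]] %*% a[[j]])
        }
      }
    }
  } else {
    a[[start$j]] <- replace(numeric(ncol(blocks[[start$j]])), start$i, start$s)
    t_list[[start$j]] <- drop(blocks[[start$j]] %*% a[[start$j]])
    sweep_order <- c(setdiff(seq_len(J), start$j), start$j)
  }
  converged <- FALSE
  iters <- 0L
  trace <- numeric(0)
  # first sparse sweep is unconditional: it imposes the support constraint
  # on the (dense) warm start, necessarily lowering the criterion once
  for (j in sweep_order) {
    w <- inner_target(C, t_list, j)
    u <- drop(crossprod(blocks[[j]], w))
    u <- soft_keep(u, keep[j])
    nrm <- sqrt(sum(u^2))
    if (nrm > 0) {
      a[[j]] <- u / nrm
      t_list[[j]] <- drop(blocks[[j]] %*% a[[j]])
    }
  }
  crit <- sgcca_criterion(C, t_list)
  for (it in seq_len(max_iter)) {
    iters <- it
    a_prev <- a
    for (j in sweep_order) {
      w <- inner_target(C, t_list, j)
      u <- drop(crossprod(blocks[[j]], w))
      u <- soft_keep(u, keep[j])
      nrm <- sqrt(sum(u^2))
      if (nrm > 0) {
        cand_a <- u / nrm
        cand_t <- drop(blocks[[j]] %*% cand_a)
        t_try <- t_list
        t_try[[j]] <- cand_t
        cand_crit <- sgcca_criterion(C, t_try)
        # the exact-count threshold is a moving target, so the raw block
        # update is not guaranteed ascent; accept only non-decreasing steps
        if (cand_crit >= crit - 1e-12) {
          a[[j]] <- cand_a
          t_list[[j]] <- cand_t
          crit <- cand_crit
        }
      }
    }
    trace[it] <- crit
    delta <- max(vapply(seq_len(J), function(j) max(abs(a[[j]] - a_prev[[j]])), numeric(1)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(a = a, t = t_list, iters = iters, converged = converged,
       criterion = sgcca_criterion(C, t_list), trace = trace)
}

inner_target <- function(C, t_list, j) {
  w <- 0
  for (k in seq_along(t_list)) {
    if (C[j, k] != 0) w <- w + C[j, k] * t_list[[k]]
  }
  w
}

#' Sparse generalized canonical correlation analysis
#'
#' Multi-block sGCCA maximising the design-weighted sum of covariances
#' between block variates, with per-block sparsity enforced by
#' soft-thresholding each raw direction at its `(keep + 1)`-th largest
#' absolute entry so exactly `keep` loadings stay non-zero. After each
#' component every omic block is deflated in regression mode
#' (`X <- X - t (t'X)/(t't)`); a designated label block is never deflated,
#' so later components stay label-informed.
#'
#' The inner loop is alternating block-coordinate ascent. It always starts
#' from a dense warm start (each block's dominant right singular vector,
#' relaxed without sparsity for a few sweeps). Blocks of width at most
#' `restart_width` additionally restart the loop from every signed basis
#' vector of that block, and the fit with the largest criterion wins; on
#' narrow blocks coordinate ascent is prone to local optima and these
#' enumerative restarts are cheap insurance that the reported support
#' maximises the criterion.
#'
#' @param blocks named list of standardized numeric matrices (same rows).
#' @param design symmetric design matrix over blocks, zero diagonal; see
#'   [make_design()].
#' @param keep integer vector of non-zero loadings per block (recycled);
#'   values wider than a block are clamped with a warning.
#' @param ncomp number of deflated components.
#' @param tol convergence tolerance on `max |a - a_prev|`.
#' @param max_iter maximum sweeps per component (warning on
#'   non-convergence; best iterate returned).
#' @param label name or index of the block that is never deflated and never
#'   contributes members to putative modules, or `NULL`.
#' @param restart_width maximum block width for basis-vector restarts.
#' @return An `sgcca_fit` with per-component loadings and variates.
#' @export
fit_sgcca <- function(blocks, design, keep, ncomp = 1, tol = 1e-6,
                      max_iter = 1000L, label = NULL, restart_width = 12L) {
  stopifnot(is.list(blocks), length(blocks) >= 2)
  J <- length(blocks)
  blocks <- lapply(blocks, as.matrix)
  n <- nrow(blocks[[1]])
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(all(vapply(blocks, nrow, integer(1)) == n))
  check_design(design, J)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(J))
  label_idx <- if (is.null(label)) 0L else {
    if (is.character(label)) match(label, names(blocks)) else as.integer(label)
  }
  if (!is.null(label) && is.na(label_idx)) stop("label block '", label, "' not found", call. = FALSE)
  widths <- vapply(blocks, ncol, integer(1))
  keep <- rep_len(as.integer(keep), J)
  if (label_idx > 0) keep[label_idx] <- 1L
  if (any(keep > widths)) {
    warning("`keep` exceeds block width for: ",
            paste(names(blocks)[keep > widths], collapse = ", "), "; clamped",
            call. = FALSE)
    keep <- pmin(keep, widths)
  }
  feat <- lapply(blocks, colnames)

  work <- blocks
  components <- vector("list", ncomp)
  for (h in seq_len(ncomp)) {
    starts <- list(NULL)
    for (j in seq_len(J)) {
      if (j != label_idx && widths[j] <= restart_width && keep[j] < widths[j]) {
        for (i in seq_len(widths[j])) {
          starts[[length(starts) + 1L]] <- list(j = j, i = i, s = 1)
          starts[[length(starts) + 1L]] <- list(j = j, i = i, s = -1)
        }
      }
    }
    best <- NULL
    for (st in starts) {
      fit <- sgcca_component(work, design, keep, tol, max_iter, start = st)
      if (is.null(best) || fit$criterion > best$criterion + 1e-10) best <- fit
    }
    if (!best$converged) {
      warning("component ", h, " did not converge in ", max_iter,
              " iterations; returning best iterate", call. = FALSE)
    }
    components[[h]] <- best
    # regression deflation of omic blocks only
    for (j in seq_len(J)) {
      if (j == label_idx) next
      tj <- best$t[[j]]
      denom <- sum(tj^2)
      if (denom > 0) {
        work[[j]] <- work[[j]] - tj %*% crossprod(tj, work[[j]]) / denom
      }
    }
  }

  structure(
    list(
      components = components,
      design = design,
      keep = keep,
      block_names = names(blocks),
      features = feat,
      label_index = label_idx,
      n = n
    ),
    class = "sgcca_fit"
  )
}

#' @export
print.sgcca_fit <- function(x, ...) {
  cat(sprintf("<sgcca_fit> %d blocks (%s), %d component(s), n = %d\n",
              length(x$block_names), paste(x$block_names, collapse = ", "),
              length(x$components), x$n))
  invisible(x)
}

#' Putative modules of a fitted sGCCA model
#'
#' For each component, the features across all omic blocks with non-zero
#' loadings form one putative module; the label block never contributes.
#'
#' @param fit an `sgcca_fit`.
#' @return Tibble with columns `component`, `omic`, `feature`.
#' @export
extract_putative_modules <- function(fit) {
  purrr::map_dfr(seq_along(fit$components), function(h) {
    comp <- fit$components[[h]]
    purrr::map_dfr(seq_along(fit$block_names), function(j) {
      if (j == fit$label_index) return(NULL)
      nz <- comp$a[[j]] != 0
      if (!any(nz)) return(NULL)
      tibble::tibble(component = h, omic = fit$block_names[j],
                     feature = fit$features[[j]][nz])
    })
  })
}

#' Tidy the loadings of a fitted sGCCA model
#'
#' One row per component, block and non-zero loading.
#'
#' @param x an `sgcca_fit`.
#' @param ... unused.
#' @return A tibble with columns `component`, `block`, `feature`,
#'   `loading`.
#' @export
#' @method tidy sgcca_fit
tidy.sgcca_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$components), function(h) {
    comp <- x$components[[h]]
    purrr::map_dfr(seq_along(x$block_names), function(j) {
      nz <- comp$a[[j]] != 0
      tibble::tibble(component = h, block = x$block_names[j],
                     feature = x$features[[j]][nz],
                     loading = comp$a[[j]][nz])
    })
  })
}

#' Per-component summary of a fitted sGCCA model
#'
#' @param x an `sgcca_fit`.
#' @param ... unused.
#' @return A tibble with one row per component: criterion value,
#'   iterations, convergence.
#' @export
#' @method glance sgcca_fit
glance.sgcca_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$components),
    criterion = vapply(x$components, `[[`, numeric(1), "criterion"),
    iterations = vapply(x$components, `[[`, integer(1), "iters"),
    converged = vapply(x$components, `[[`, logical(1), "converged")
  )
}
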