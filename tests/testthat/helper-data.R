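# Small deterministic fixtures built in code.

tiny_matrix <- function(n, p, prefix = "f", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(n * p)) + 0.1, n, p)
    dimnames(m) <- list(sprintf("s%02d", seq_len(n)), paste0(prefix, seq_len(p)))
    m
  })
}

# Two-omic dataset with one feature per omic tracking the label, the rest
# noise; raw-scale tables ready for preprocess_dataset().
tiny_dataset <- function(n = 40, p_t = 8, p_m = 6, signal = 2, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep_len(c(0L, 1L), n)
    ids <- sprintf("s%02d", seq_len(n))
    names(labels) <- ids
    tv <- matrix(rlnorm(n * p_t), n, p_t,
                 dimnames = list(ids, paste0("taxon", seq_len(p_t))))
    mv <- matrix(rlnorm(n * p_m, meanlog = 5), n, p_m,
                 dimnames = list(ids, paste0("met", seq_len(p_m))))
    if (signal > 0) {
      z <- signal * (labels - 0.5) * 2 + rnorm(n)
      tv[, 1] <- exp(log(tv[, 1]) + z)
      mv[, 1] <- exp(log(mv[, 1]) + z)
    }
    new_dataset <- getFromNamespace("new_dataset", "modulomics")
    new_dataset(
      list(T = omic_table(tv, "T"), M = omic_table(mv, "M")),
      labels, "tiny"
    )
  })
}

# Standardized random blocks for sGCCA tests.
random_blocks <- function(n, widths, seed = 1, names_ = LETTERS[seq_along(widths)]) {
  withr::with_seed(seed, {
    out <- lapply(seq_along(widths), function(i) {
      m <- scale(matrix(rnorm(n * widths[i]), n))
      colnames(m) <- paste0(tolower(names_[i]), seq_len(widths[i]))
      rownames(m) <- sprintf("s%02d", seq_len(n))
      m
    })
    names(out) <- names_
    out
  })
}

# A processed dataset (standardizable, no zeros) used by evaluation tests.
processed_dataset <- function(n = 60, p_t = 10, p_m = 8, signal = 1.5, seed = 2) {
  ds <- tiny_dataset(n, p_t, p_m, signal, seed)
  preprocess_dataset(ds, pipeline_config(min_prevalence = 0, min_mean_abundance = 0,
                                         seed = seed))$dataset
}
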