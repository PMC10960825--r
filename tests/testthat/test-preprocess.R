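test_that("total-sum scaling maps rows onto the simplex", {
  m <- matrix(c(2, 3, 5,
                1, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  out <- tss_normalize(omic_table(m, "T"))
  expect_equal(unname(out$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(out$values)), c(1, 1), tolerance = 1e-12)
  expect_identical(out$scale_state, "relative")

  # idempotent on the simplex
  again <- out
  again$scale_state <- "raw"
  expect_equal(tss_normalize(again)$values, out$values)

  m[1, ] <- 0
  expect_error(tss_normalize(omic_table(m, "T")), "s1")
})

test_that("log transform inverts exp, maps 0 to 0 with unit pseudocount, keeps ranks", {
  pc <- 1
  m <- matrix(c(exp(1) - pc, 0, 3, 9), nrow = 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  out <- log_transform(omic_table(m, "M"), pseudocount = pc)
  expect_equal(unname(out$values[1, 1]), 1)
  expect_equal(unname(out$values[2, 1]), 0)
  expect_identical(out$scale_state, "log")

  v <- tiny_matrix(10, 4, seed = 3)
  logd <- log_transform(omic_table(v, "M"), pseudocount = 0.5)
  for (j in 1:4) expect_identical(rank(logd$values[, j]), rank(v[, j]))

  neg <- matrix(c(-1, 1, 2, 3), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(log_transform(omic_table(neg, "M")), "negative")
})

test_that("default pseudocount is half the minimum positive value per feature", {
  m <- matrix(c(0, 4, 8,
                2, 2, 2), ncol = 2,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  out <- log_transform(omic_table(m, "M"))
  expect_equal(unname(out$values[1, 1]), log(0 + 4 / 2))   # zero gets min/2
  expect_equal(unname(out$values[1, 2]), log(2))           # no zeros: untouched
})

test_that("rare, low-abundance and constant features are dropped with reasons", {
  n <- 10
  m <- cbind(
    rare = c(1, rep(0, n - 1)),              # 10% prevalence < 15%
    tiny = rep(4e-5 * n / n, n),             # constant AND low abundance
    ok = seq(0.1, 1, length.out = n),
    flat = rep(0.5, n)
  )
  rownames(m) <- sprintf("s%02d", 1:n)
  tab <- omic_table(m, "T")
  tab$scale_state <- "relative"  # bypass row-sum check: testing the filter rules
  tab$values <- tab$values       # (rules read scale_state only)
  res <- suppressWarnings(filter_features(tab, 0.15, 5e-5))
  expect_setequal(res$removed$feature, c("T:rare", "T:tiny", "T:flat"))
  expect_identical(
    res$removed$reason[match("T:rare", res$removed$feature)], "low_prevalence")
  expect_identical(
    res$removed$reason[match("T:tiny", res$removed$feature)], "constant")
  expect_identical(colnames(res$table$values), "T:ok")

  # mean relative abundance below 0.005% is dropped even when prevalent
  m2 <- cbind(low = seq(3e-5, 5e-5, length.out = n),  # mean 4e-5 < 5e-5
              hi = seq(0.5, 1, length.out = n))
  rownames(m2) <- rownames(m)
  tab2 <- omic_table(m2, "T"); tab2$scale_state <- "relative"
  m2_res <- filter_features(tab2, 0.15, 5e-5)
  expect_true("T:low" %in% m2_res$removed$feature)
  expect_identical(m2_res$removed$reason, "low_abundance")
})

test_that("filtering is idempotent and never grows the table", {
  ds <- tiny_dataset(n = 30, seed = 9)
  tab <- tss_normalize(ds$omics$T)
  once <- filter_features(tab)
  twice <- filter_features(once$table)
  expect_identical(twice$table$values, once$table$values)
  expect_identical(nrow(twice$removed), 0L)
  expect_lte(ncol(once$table$values), ncol(tab$values))
})

test_that("exclusion lists drop named features and tolerate unknowns", {
  tab <- omic_table(tiny_matrix(5, 4), "P")
  res <- exclude_features(tab, "f2")
  expect_false("P:f2" %in% colnames(res$table$values))
  expect_identical(res$removed$reason, "excluded")

  expect_identical(exclude_features(tab, character())$table$values, tab$values)
  expect_warning(res2 <- exclude_features(tab, "nope"), "not present")
  expect_identical(res2$table$values, tab$values)
})

test_that("duplicate and monotone-transformed features collapse to one representative", {
  n <- 20
  base <- sort(rnorm(n))
  m <- cbind(x = base, dup = base, mono = exp(base), other = rev(base) + rnorm(n, sd = 3))
  rownames(m) <- sprintf("s%02d", 1:n)
  res <- cluster_collinear(omic_table(m, "M"), threshold = 0.99, seed = 4)
  # x, dup, mono all have |spearman| = 1: one survivor
  survivors <- colnames(res$table$values)
  expect_length(intersect(survivors, c("M:x", "M:dup", "M:mono")), 1)
  expect_true("M:other" %in% survivors)
  expect_setequal(unique(res$map$representative), intersect(survivors, c("M:x", "M:dup", "M:mono")))
})

test_that("collinearity clustering matches a brute-force complete-linkage oracle", {
  # independent oracle: agglomerate greedily, merging the closest pair of
  # clusters whose complete-linkage distance stays below 1 - threshold
  brute_clusters <- function(rho, threshold) {
    p <- nrow(rho)
    clusters <- as.list(seq_len(p))
    repeat {
      best <- NULL; best_d <- 1 - threshold
      for (i in seq_along(clusters)) {
        for (j in seq_len(i - 1)) {
          d <- 1 - min(abs(rho[clusters[[i]], clusters[[j]]]))
          if (d < best_d) { best <- c(j, i); best_d <- d }
        }
      }
      if (is.null(best)) break
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    sets <- lapply(clusters, sort)
    sets[order(vapply(sets, `[`, integer(1), 1))]
  }
  threshold <- 0.9
  for (seed in 1:8) {
    m <- withr::with_seed(seed, {
      n <- 30
      latent <- matrix(rnorm(n * 2), n)
      noise <- matrix(rnorm(n * 6, sd = 0.1), n)
      latent[, c(1, 1, 1, 2, 2, 2)] + noise
    })
    colnames(m) <- paste0("f", 1:6)
    rownames(m) <- sprintf("s%02d", 1:30)
    rho <- cor(m, method = "spearman")
    expected <- brute_clusters(rho, threshold)
    res <- cluster_collinear(omic_table(m, "M"), threshold = threshold, seed = seed)
    # representatives + map reproduce the same partition of merged features
    got_sets <- split(sub("^M:", "", res$map$member), res$map$representative)
    got <- lapply(got_sets, function(s) sort(match(s, colnames(m))))
    exp_multi <- Filter(function(s) length(s) > 1, expected)
    expect_setequal(
      vapply(got, paste, "", collapse = ","),
      vapply(exp_multi, paste, "", collapse = ",")
    )
  }
})

test_that("no pair above the threshold survives collapsing", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, {
      latent <- matrix(rnorm(25 * 3), 25)
      latent[, sample(1:3, 10, replace = TRUE)] + matrix(rnorm(25 * 10, sd = 0.05), 25)
    })
    colnames(m) <- paste0("f", 1:10)
    rownames(m) <- sprintf("s%02d", 1:25)
    res <- cluster_collinear(omic_table(m, "M"), threshold = 0.95, seed = seed)
    if (ncol(res$table$values) > 1) {
      rho <- cor(res$table$values, method = "spearman")
      expect_lte(max(abs(rho[upper.tri(rho)])), 0.95)
    }
  }
})

test_that("standardization uses sample SD, is idempotent, rejects constants", {
  m <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "a"))
  out <- standardize_block(m)
  expect_equal(unname(out[, 1]), c(-1, 0, 1), tolerance = 1e-12)

  m2 <- tiny_matrix(10, 3)
  z <- standardize_block(m2)
  expect_equal(standardize_block(z), z, tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3))

  m3 <- cbind(m2, const = 1)
  expect_error(standardize_block(m3), "const")

  # reference statistics from another sample are honoured
  ref_c <- c(a = 10); ref_s <- c(a = 2)
  expect_equal(unname(standardize_block(m, ref_c, ref_s)[, 1]), (c(1, 2, 3) - 10) / 2)
})

test_that("whole-dataset preprocessing leaves standardizable blocks and a report", {
  ds <- tiny_dataset(n = 30, seed = 11)
  res <- preprocess_dataset(ds, pipeline_config(seed = 11))
  expect_identical(res$dataset$omics$T$scale_state, "relative")
  expect_identical(res$dataset$omics$M$scale_state, "log")
  expect_true(all(c("feature", "omic", "reason") %in% names(res$report)))
  for (o in res$dataset$omics) {
    expect_silent(standardize_block(o$values))
  }
})
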