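test_that("module PC1 matches the closed-form 2x2 eigen-decomposition", {
  # hand-checkable 3-sample, 2-feature module
  m <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  rownames(m) <- paste0("s", 1:3)
  ds <- list(
    omics = list(M = omic_table(m, "M", scale_state = "log")),
    labels = setNames(c(0L, 0L, 1L), paste0("s", 1:3)),
    dataset_id = "toy"
  )
  class(ds) <- "multi_omic_dataset"
  scores <- module_pc1(ds, c("M:a", "M:b"))
  z <- scale(m)
  r <- cor(z[, 1], z[, 2])
  # 2x2 correlation matrix: eigenvector (1,1)/sqrt(2), eigenvalue 1 + r
  expected <- (z[, 1] + z[, 2]) / sqrt(2)
  expect_equal(abs(cor(scores, expected)), 1, tolerance = 1e-10)
  expect_equal(attr(scores, "explained"), (1 + r) / 2, tolerance = 1e-10)
})

test_that("PC1 explained variance hits the symmetry limits", {
  perf <- cbind(a = c(-3, -1, 1, 3), b = c(-3, -1, 1, 3))
  rownames(perf) <- paste0("s", 1:4)
  ds <- list(omics = list(M = omic_table(perf, "M", scale_state = "log")),
             labels = setNames(c(0L, 0L, 1L, 1L), paste0("s", 1:4)))
  class(ds) <- "multi_omic_dataset"
  expect_equal(attr(module_pc1(ds, c("M:a", "M:b")), "explained"), 1)

  orth <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  rownames(orth) <- paste0("s", 1:4)
  ds$omics$M <- omic_table(orth, "M", scale_state = "log")
  expect_equal(attr(module_pc1(ds, c("M:a", "M:b")), "explained"), 0.5)
})

test_that("rank AUC reproduces hand-enumerated pair concordance", {
  expect_equal(pc1_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(pc1_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 1.0)  # orientation
  expect_equal(pc1_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75) # 3 of 4 pairs
  # monotone-transform and sign invariance
  s <- rnorm(30); y <- rep_len(c(0, 1), 30)
  expect_equal(pc1_auc(exp(s), y), pc1_auc(s, y))
  expect_equal(pc1_auc(-s, y), pc1_auc(s, y))
})

test_that("null modules match the observed per-omic composition", {
  ds <- processed_dataset(n = 30, seed = 3)
  withr::with_seed(1, {
    nm <- sample_null_module(ds, c(T = 3, M = 2))
    expect_identical(as.integer(table(sub(":.*", "", nm))[c("M", "T")]), c(2L, 3L))
    expect_error(sample_null_module(ds, c(T = 999)), "requested")
    draws <- replicate(5, paste(sort(sample_null_module(ds, c(T = 3))), collapse = ","))
    expect_gt(length(unique(draws)), 1)
  })
})

test_that("cross-omic correlation averages cross-pairs only, flags single-omic", {
  n <- 5
  # hand-built ranks on 5 samples
  ta <- c(1, 2, 3, 4, 5); tb <- c(2, 1, 3, 5, 4)
  ma <- c(5, 4, 3, 2, 1); mb <- c(1, 3, 2, 4, 5)
  tm <- cbind(x = ta, y = tb); mm <- cbind(u = ma, v = mb)
  rownames(tm) <- rownames(mm) <- paste0("s", 1:5)
  ds <- list(omics = list(T = omic_table(tm, "T", scale_state = "log"),
                          M = omic_table(mm, "M", scale_state = "log")),
             labels = setNames(rep_len(c(0L, 1L), 5), paste0("s", 1:5)))
  class(ds) <- "multi_omic_dataset"
  res <- cross_omic_correlation(ds, c("T:x", "T:y", "M:u", "M:v"))
  # manual spearman: pearson on the rank vectors
  manual <- c(cor(ta, ma), cor(ta, mb), cor(tb, ma), cor(tb, mb))
  expect_equal(sort(res$pairs$rho), sort(manual), tolerance = 1e-12)
  expect_equal(res$mean_rho, mean(manual), tolerance = 1e-12)
  expect_identical(nrow(res$pairs), 4L)  # no within-omic pairs

  single <- cross_omic_correlation(ds, c("T:x", "T:y"))
  expect_true(is.na(single$mean_rho))

  # p-values agree with the asymptotic cor.test route
  ct <- suppressWarnings(cor.test(ta, ma, method = "spearman", exact = FALSE))
  expect_equal(res$pairs$p[res$pairs$feature_a == "T:x" & res$pairs$feature_b == "M:u"],
               ct$p.value, tolerance = 1e-10)

  # optional label-adjusted correlation: residualizing ranks on a
  # label-free contrast leaves the ordinary rank correlation intact
  pp <- cross_omic_correlation(ds, c("T:x", "T:y", "M:u", "M:v"), partial = TRUE)
  expect_true("partial_rho" %in% names(pp$pairs))
  expect_true(all(abs(pp$pairs$partial_rho) <= 1 + 1e-12))
})

test_that("a perfectly monotone cross-omic pair has rho 1", {
  n <- 12
  base <- rnorm(n)
  tm <- cbind(x = base, y = rnorm(n))
  mm <- cbind(u = exp(base), v = rnorm(n))  # u is a monotone transform of x
  rownames(tm) <- rownames(mm) <- sprintf("s%02d", 1:n)
  ds <- list(omics = list(T = omic_table(tm, "T", scale_state = "log"),
                          M = omic_table(mm, "M", scale_state = "log")),
             labels = setNames(rep_len(c(0L, 1L), n), sprintf("s%02d", 1:n)))
  class(ds) <- "multi_omic_dataset"
  res <- cross_omic_correlation(ds, c("T:x", "M:u"))
  expect_equal(res$pairs$rho, 1)
})

test_that("classification gates on threshold, exceedances and multi-omic status", {
  expect_true(classify_module(0.86, TRUE, TRUE, TRUE))
  expect_false(classify_module(0.69, TRUE, TRUE, TRUE))   # below threshold
  expect_false(classify_module(0.9, TRUE, TRUE, FALSE))   # single-omic
  expect_false(classify_module(0.86, FALSE, TRUE, TRUE))
  expect_false(classify_module(0.86, TRUE, FALSE, TRUE))
  # monotone: improving AUC never flips associated -> not
  expect_true(classify_module(0.95, TRUE, TRUE, TRUE))
})

test_that("null summaries flag exceedance for planted modules, not permuted labels", {
  spec <- synthetic_spec(n_samples = 80, n_features = c(T = 20, M = 15),
                         modules = list(list(size = c(T = 3, M = 3),
                                             alpha = 2, beta = 1, sigma = 0.5)))
  sim <- simulate_multiomics(spec, seed = 41)
  prep <- preprocess_dataset(sim$dataset, pipeline_config(seed = 41))
  planted <- intersect(sim$truth$feature, feature_universe(prep$dataset)$feature)
  nd <- null_distributions(prep$dataset, planted, n_null = 50, seed = 41)
  expect_true(nd$exceeds[nd$statistic == "auc"])
  expect_true(nd$exceeds[nd$statistic == "rho"])
  expect_gt(nd$observed[nd$statistic == "auc"], nd$null_mean[nd$statistic == "auc"])

  # permuted labels: observed AUC should sit inside null mean +/- 2 SD in
  # the vast majority of repetitions
  inside <- 0L
  for (r in 1:15) {
    perm <- permute_labels(prep$dataset, seed = 100 + r)
    ndp <- null_distributions(perm, planted, n_null = 30, seed = 200 + r)
    aucs <- ndp[ndp$statistic == "auc", ]
    if (abs(aucs$observed - aucs$null_mean) <= 2 * aucs$null_sd) inside <- inside + 1L
  }
  expect_gte(inside, 12L)
})

test_that("module evaluation composes statistics and respects gates", {
  spec <- synthetic_spec(n_samples = 60, n_features = c(T = 15, M = 12),
                         modules = list(list(size = c(T = 3, M = 2),
                                             alpha = 2, beta = 1.2, sigma = 0.4)))
  sim <- simulate_multiomics(spec, seed = 51)
  cfg <- pipeline_config(seed = 51, n_null = 40)
  prep <- preprocess_dataset(sim$dataset, cfg)
  planted <- intersect(sim$truth$feature, feature_universe(prep$dataset)$feature)
  members <- tibble::tibble(module_id = "M1",
                            omic = sub(":.*", "", planted), feature = planted)
  ev <- evaluate_modules(prep$dataset, members, cfg)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$multi_omic)
  expect_gte(ev$auc, 0.5)
  expect_true(all(c("auc_null_mean", "rho_null_sd") %in% names(ev)))
  pw <- attr(ev, "pairwise")
  expect_true(all(pw$module_id == "M1"))
  # evaluation is deterministic under the config seed
  ev2 <- evaluate_modules(prep$dataset, members, cfg)
  expect_equal(tibble::as_tibble(ev), tibble::as_tibble(ev2))
})

test_that("differential direction matches hand-computed rank sums on 6 samples", {
  x <- c(1.2, 2.1, 3.3, 7.4, 8.9, 9.6)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  m <- cbind(up = x, flat = c(5, 6, 7, 5, 6, 7))
  rownames(m) <- paste0("s", 1:6)
  ds <- list(omics = list(M = omic_table(m, "M", scale_state = "log")),
             labels = setNames(y, paste0("s", 1:6)))
  class(ds) <- "multi_omic_dataset"
  # hand enumeration: all case values above all control values -> U = 9
  u_hand <- sum(outer(x[y == 1], x[y == 0], ">"))
  expect_equal(u_hand, 9)
  expect_equal(pc1_auc(x, y, orient = FALSE) * 9, u_hand)  # AUC = U / (n1 n0)
  res <- differential_direction(ds, c("M:up", "M:flat"), fdr = 0.2)
  expect_identical(res$direction[res$feature == "M:up"], "up")
  expect_identical(res$direction[res$feature == "M:flat"], "ns")
  expect_gt(res$median_diff[res$feature == "M:up"], 0)
})

test_that("a label-tracking feature is significantly up, identical distributions are ns", {
  n <- 60
  y <- rep_len(c(0L, 1L), n)
  m <- cbind(sig = y + rnorm(n, sd = 0.05), noise = rnorm(n))
  rownames(m) <- sprintf("s%02d", 1:n)
  ds <- list(omics = list(M = omic_table(m, "M", scale_state = "log")),
             labels = setNames(y, sprintf("s%02d", 1:n)))
  class(ds) <- "multi_omic_dataset"
  res <- differential_direction(ds, c("M:sig", "M:noise"))
  expect_identical(res$direction[res$feature == "M:sig"], "up")
  expect_lt(res$q[res$feature == "M:sig"], 1e-6)
  expect_identical(res$direction[res$feature == "M:noise"], "ns")
})

test_that("forest on module PCs separates signal from noise", {
  spec <- synthetic_spec(n_samples = 80, n_features = c(T = 15, M = 12),
                         modules = list(list(size = c(T = 3, M = 3),
                                             alpha = 2.5, beta = 1.5, sigma = 0.3)))
  sim <- simulate_multiomics(spec, seed = 61)
  cfg <- pipeline_config(seed = 61)
  prep <- preprocess_dataset(sim$dataset, cfg)
  planted <- intersect(sim$truth$feature, feature_universe(prep$dataset)$feature)
  members <- tibble::tibble(module_id = "M1",
                            omic = sub(":.*", "", planted), feature = planted)
  strong <- modules_pc_rf(prep$dataset, members, nfold = 5, repeats = 2, seed = 61)
  expect_gt(strong$mean_auc, 0.9)

  # pure-noise module: AUC near chance. Background metabolites are
  # label-free by construction; background taxa are not a clean null here
  # because closure lets the strong planted taxa bleed into them.
  m_universe <- feature_universe(prep$dataset)$feature
  noise_feats <- setdiff(grep("^M:", m_universe, value = TRUE), planted)[1:6]
  noise_members <- tibble::tibble(module_id = "M1",
                                  omic = sub(":.*", "", noise_feats),
                                  feature = noise_feats)
  null_rf <- modules_pc_rf(prep$dataset, noise_members, nfold = 5, repeats = 2,
                           seed = 62)
  expect_lt(abs(null_rf$mean_auc - 0.5), 0.2)
})
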