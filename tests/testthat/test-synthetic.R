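test_that("label hierarchy is a valid nested partition and deterministic", {
  h1 <- make_label_hierarchy(seed = 0)
  h2 <- make_label_hierarchy(seed = 0)
  expect_identical(h1$mid_of_fine, h2$mid_of_fine)
  expect_identical(h1$coarse_of_mid, h2$coarse_of_mid)
  # every fine resolves through mid to coarse without orphans
  expect_true(all(h1$mid_of_fine %in% 0:9))
  expect_true(all(h1$coarse_of_mid %in% 0:4))
  expect_length(unique(h1$mid_of_fine), 10L)      # all 10 mids used
  expect_length(unique(h1$coarse_of_mid), 5L)     # all 5 coarse used
  expect_true(all(tabulate(h1$mid_of_fine + 1L, 10L) >= 1L))
  # different seeds give different nestings (not a constant)
  h3 <- make_label_hierarchy(seed = 99)
  expect_false(identical(h1$mid_of_fine, h3$mid_of_fine) &&
                 identical(h1$coarse_of_mid, h3$coarse_of_mid))
  # resolution helpers agree with composed maps
  fine <- 0:22
  expect_identical(coarse_of_fine(h1, fine),
                   h1$coarse_of_mid[h1$mid_of_fine[fine + 1L] + 1L])
})

test_that("feature simulation honours shapes, scaling and determinism", {
  cfg <- sim_config(n_train = 80, n_val = 20, feature_dims = c(64L, 128L), seed = 5)
  f1 <- simulate_features(cfg)
  expect_named(f1, c("layer1", "layer2"))
  expect_equal(dim(f1$layer1), c(100L, 64L))
  expect_equal(dim(f1$layer2), c(100L, 128L))
  # standard-normal columns: means within 4/sqrt(n)
  expect_true(all(abs(colMeans(f1$layer1)) < 4 / sqrt(100)))
  f2 <- simulate_features(cfg)
  expect_identical(f1, f2)
  expect_error(sim_config(feature_dims = c(0L, 8L)))
})

test_that("feature-driven voxels are standardized and match the stated snr", {
  cfg <- sim_config(n_train = 1000, n_val = 50, voxels_per_area = 6,
                    feature_dims = c(16L, 16L), sparsity_k = 2, snr = 4, seed = 2)
  feats <- simulate_features(cfg)
  vox <- simulate_voxels_from_features(feats, cfg)
  tr <- seq_len(cfg$n_train)
  for (a in names(vox$areas)) {
    m <- vox$areas[[a]]
    expect_true(all(abs(colMeans(m[tr, ])) < 1e-9))
    expect_true(all(abs(apply(m[tr, ], 2, var) - 1) < 1e-9))
  }
  # empirical signal/noise variance ratio within 20% of snr at n=1000
  ratios <- vapply(colnames(vox$areas$V1), function(id) {
    L <- vox$truth$layer_of_voxel[[id]]
    s <- feats[[L]][tr, vox$truth$supports[[id]], drop = FALSE] %*% vox$truth$values[[id]]
    m <- vox$areas$V1[tr, id]
    # reconstruct noise as standardized response minus standardized signal fit
    b <- lsfit(s, m)$coefficients
    resid <- m - (b[1] + s * b[2])
    (var(as.numeric(s)) * b[2]^2) / var(resid)
  }, numeric(1))
  expect_true(all(abs(ratios / cfg$snr - 1) < 0.2))
})

test_that("noiseless voxels equal the standardized sparse signal exactly", {
  cfg <- sim_config(n_train = 60, n_val = 10, voxels_per_area = 4,
                    feature_dims = 12L, sparsity_k = 2, snr = Inf, seed = 8)
  feats <- simulate_features(cfg)
  vox <- simulate_voxels_from_features(feats, cfg)
  tr <- seq_len(cfg$n_train)
  id <- colnames(vox$areas$V2)[2]
  L <- vox$truth$layer_of_voxel[[id]]
  sig <- as.numeric(feats[[L]][, vox$truth$supports[[id]], drop = FALSE] %*%
                      vox$truth$values[[id]])
  expect_equal(vox$areas$V2[, id],
               (sig - mean(sig[tr])) / sd(sig[tr]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(simulate_voxels_from_features(
    feats, sim_config(feature_dims = 12L, sparsity_k = 13L)))
})

test_that("area sequences are balanced, reproducible and carry tunable signal", {
  sim <- tiny_marginal_sim(seed = 4)
  expect_s3_class(sim$train, "sequence_set")
  expect_equal(dim(sim$train$x), c(200L, 5L, 8L))
  # fine labels balanced within +/- 1 across train+val
  fine_all <- c(sim$train$labels$fine, sim$val$labels$fine)
  counts <- tabulate(fine_all + 1L, 23L)
  expect_lte(max(counts) - min(counts), 1L)
  sim2 <- tiny_marginal_sim(seed = 4)
  expect_identical(sim$train$x, sim2$train$x)
  expect_identical(sim$train$labels, sim2$train$labels)
})

test_that("a per-area linear classifier succeeds on strong marginal signal only", {
  skip_if_not_installed("MASS")
  sim <- tiny_marginal_sim(seed = 6, beta = 4, n_train = 300, n_val = 150)
  one_area_train <- sim$train$x[, 5, ]  # LO node only
  one_area_val <- sim$val$x[, 5, ]
  # each coarse class is a mixture of fine clusters, so the linear read-out
  # separates the 23 unimodal fine clusters and resolves them to coarse
  fit <- MASS::lda(one_area_train,
                   grouping = factor(sim$train$labels$fine, levels = 0:22))
  pred_fine <- as.integer(as.character(predict(fit, one_area_val)$class))
  pred_coarse <- coarse_of_fine(sim$hierarchy, pred_fine)
  expect_gt(mean(pred_coarse == sim$val$labels$coarse), 0.95)
})

test_that("with no category signal a trained classifier sits at chance", {
  skip_if_not_installed("MASS")
  cfg <- sim_config(n_train = 300, n_val = 400, voxels_per_area = 8, snr = 10,
                    beta_marginal = rep(0, 5), beta_relational = 0, seed = 12)
  sim <- simulate_area_sequences(cfg, make_label_hierarchy(12))
  fit <- MASS::lda(flatten_sequences(sim$train),
                   grouping = factor(sim$train$labels$coarse, levels = 0:4))
  acc <- mean(predict(fit, flatten_sequences(sim$val))$class ==
                factor(sim$val$labels$coarse, levels = 0:4))
  # 99% binomial CI around chance 0.2 at n=400
  expect_lt(abs(acc - 0.2), 2.576 * sqrt(0.2 * 0.8 / 400) + 1e-12)
})

test_that("label shuffling preserves the histogram and the voxel data", {
  sim <- tiny_marginal_sim(seed = 7)
  sh <- shuffle_labels(sim$train, seed = 1)
  expect_identical(sh$x, sim$train$x)
  expect_identical(sort(sh$labels$fine), sort(sim$train$labels$fine))
  expect_identical(sort(sh$labels$coarse), sort(sim$train$labels$coarse))
  expect_false(identical(sh$labels$fine, sim$train$labels$fine))
  expect_identical(shuffle_labels(sim$train, seed = 1)$labels, sh$labels)
  # shuffled labels stay internally consistent with the hierarchy
  h <- sim$hierarchy
  expect_identical(coarse_of_fine(h, sh$labels$fine), sh$labels$coarse)
})

test_that("the relational signal leaves per-area marginals label-free", {
  cfg <- sim_config(n_train = 2000, n_val = 50, voxels_per_area = 4, snr = 10,
                    beta_marginal = rep(0, 5), beta_relational = 2, seed = 21)
  sim <- simulate_area_sequences(cfg, make_label_hierarchy(21))
  # per-class mean of any single area's pattern is ~0 (no marginal signal)
  x1 <- sim$train$x[, 1, ]
  for (cl in 0:4) {
    mu <- colMeans(x1[sim$train$labels$coarse == cl, , drop = FALSE])
    expect_true(all(abs(mu) < 0.35)) # ~ (1+beta_rel^2)^.5/sqrt(n_cl) scale
  }
  # but cross-area covariance differs by class: compare V1-V2 coupling norms
  cov_norm <- vapply(0:4, function(cl) {
    idx <- sim$train$labels$coarse == cl
    norm(crossprod(sim$train$x[idx, 1, ], sim$train$x[idx, 2, ]) / sum(idx), "F")
  }, numeric(1))
  expect_true(all(cov_norm > 1)) # label-dependent coupling present
})
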