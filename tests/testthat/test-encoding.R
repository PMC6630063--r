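test_that("pearson correlation matches the closed form and flags degeneracy", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  # direct formula oracle on 4 points
  p <- c(1, 2, 3, 4); o <- c(2, 4, 6, 9)
  r_oracle <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(pearson_correlation(p, o), r_oracle)
  r <- pearson_correlation(rep(1, 4), 1:4)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_error(pearson_correlation(1:3, 1:4))
})

make_enc_fixture <- function(seed = 11) {
  cfg <- sim_config(n_train = 120, n_val = 60, voxels_per_area = 3,
                    feature_dims = c(24L, 24L), sparsity_k = 2, snr = 15,
                    layer_of_area = rep(1L, 5), seed = seed)
  feats <- simulate_features(cfg)
  vox <- simulate_voxels_from_features(feats, cfg)
  list(cfg = cfg, feats = feats, vox = vox,
       split = list(train = 1:120, val = 121:180))
}

test_that("encoding fits cover every voxel-layer pair with held-out scores", {
  fx <- make_enc_fixture()
  enc <- fit_encoding_models(fx$feats, fx$vox$areas[c("V1", "V2")], fx$split,
                             max_nonzeros = 4L)
  expect_equal(nrow(enc$fits), 2L * 3L * 2L) # 2 areas x 3 voxels x 2 layers
  expect_true(all(enc$fits$val_correlation >= -1 & enc$fits$val_correlation <= 1,
                  na.rm = TRUE))
  # voxels generated from layer 1 correlate better on layer 1 than layer 2
  w <- reshape(enc$fits[, c("voxel_id", "layer", "val_correlation")],
               idvar = "voxel_id", timevar = "layer", direction = "wide")
  frac <- mean(w$val_correlation.1 > w$val_correlation.2)
  expect_gte(frac, 0.9)
})

test_that("voxels with non-finite responses are dropped before fitting", {
  fx <- make_enc_fixture()
  areas <- fx$vox$areas["V1"]
  areas$V1[5, 2] <- NA
  expect_message(
    enc <- fit_encoding_models(fx$feats, areas, fx$split, max_nonzeros = 4L),
    "dropping 1 voxel")
  expect_equal(length(unique(enc$fits$voxel_id)), 2L)
})

test_that("layer selection recovers the generating layer and breaks ties low", {
  fx <- make_enc_fixture()
  enc <- fit_encoding_models(fx$feats, fx$vox$areas, fx$split, max_nonzeros = 4L)
  layers <- select_layer_per_area(enc, top_n = 200)  # clips to 3 available
  expect_true(all(layers == 1L))
  # single layer: chosen for every area
  one <- enc$fits[enc$fits$layer == 2L, ]
  expect_true(all(select_layer_per_area(one) == 2L))
  # exact ties break toward the lower layer index
  tie <- data.frame(voxel_id = c("a", "a"), area = "V1", layer = c(1L, 2L),
                    n_support = 1L, val_correlation = c(0.5, 0.5))
  expect_identical(unname(select_layer_per_area(tie)), 1L)
  expect_error(select_layer_per_area(tie[0, ]), "empty")
})

test_that("voxel selection orders by correlation with deterministic ties", {
  tab <- data.frame(voxel_id = c("v3", "v1", "v2", "v4"), area = "V1",
                    layer = 1L, n_support = 1L,
                    val_correlation = c(0.9, 0.4, 0.9, NA))
  sel <- select_voxels(tab, "V1", 1L, k = 4L)
  expect_identical(sel$voxel_ids, c("v2", "v3", "v1", "v4")) # tie: lower id first
  expect_warning(sel2 <- select_voxels(tab, "V1", 1L, k = 10L), "clipping")
  expect_length(sel2$voxel_ids, 4L)
  # deterministic function of the fit table
  expect_identical(select_voxels(tab, "V1", 1L, k = 3L)$voxel_ids,
                   select_voxels(tab, "V1", 1L, k = 3L)$voxel_ids)
})

test_that("planted high-signal voxels dominate the selection", {
  fx <- make_enc_fixture(seed = 13)
  # add pure-noise voxels alongside the feature-driven ones
  areas <- fx$vox$areas
  set.seed(99)
  for (a in names(areas)) {
    noise <- matrix(rnorm(nrow(areas[[a]]) * 3), ncol = 3)
    colnames(noise) <- paste0(a, "_noise", 1:3)
    areas[[a]] <- cbind(areas[[a]], noise)
  }
  enc <- fit_encoding_models(fx$feats, areas, fx$split, max_nonzeros = 4L)
  sel <- select_voxels(enc, "V1", 1L, k = 3L)
  planted <- colnames(fx$vox$areas$V1)
  expect_gte(mean(sel$voxel_ids %in% planted), 0.95)
})

test_that("assembled sequences preserve samples, order and selection", {
  cfg <- sim_config(n_train = 40, n_val = 10, voxels_per_area = 6,
                    feature_dims = 8L, sparsity_k = 1, seed = 3)
  ds <- simulate_dataset(cfg, make_label_hierarchy(3))
  sels <- lapply(names(ds$areas), function(a) {
    structure(list(area = a, chosen_layer = 1L,
                   voxel_ids = colnames(ds$areas[[a]])[c(3, 1, 5)]),
              class = "area_selection")
  })
  names(sels) <- names(ds$areas)
  seqs <- assemble_sequences(sels, ds)
  expect_equal(dim(seqs$train$x), c(40L, 5L, 3L))
  expect_equal(dim(seqs$val$x), c(10L, 5L, 3L))
  # node a carries exactly the selected voxels, in selection order
  expect_equal(seqs$train$x[, 2, ], unname(ds$areas$V2[1:40, c(3, 1, 5)]))
  # reversing the area list reverses node order
  rev_seqs <- reverse_sequences(seqs$train)
  expect_identical(rev_seqs$areas, rev(seqs$train$areas))
  expect_equal(rev_seqs$x[, 1, ], seqs$train$x[, 5, ])
  # missing area errors
  expect_error(assemble_sequences(sels[1:4], ds), "cover exactly")
})
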