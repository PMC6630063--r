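#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the simulator. Defaults mirror the study conditions
#' the package targets: a 1750/120 train/validation split, five visual areas
#' ordered V1..LO, 100 voxels per area, and per-area marginal category signal
#' that strengthens from V1 to LO (the hierarchical-representation gradient),
#' plus a cross-area relational category signal realised as label-dependent
#' orthogonal coupling between area patterns.
#'
#' @param n_train,n_val sample counts for the two splits.
#' @param areas ordered character vector of 5 area names.
#' @param voxels_per_area voxel count per area.
#' @param feature_dims integer vector of per-layer stimulus feature dimensions.
#' @param sparsity_k number of true nonzero encoding weights per voxel.
#' @param snr signal-to-noise ratio (variance ratio) for the feature-driven
#'   voxel generator; `Inf` means noiseless.
#' @param beta_marginal length-5 per-area strengths of the marginal (per-area
#'   mean) category signal, nondecreasing by default.
#' @param beta_relational strength of the label-dependent cross-area coupling.
#' @param layer_of_area integer vector (length 5) assigning each area's voxels
#'   to a generating feature layer; defaults to an even low-to-high spread
#'   across the configured layers.
#' @param seed integer global seed; child seeds for each component are derived
#'   from it with fixed offsets (see [child_seed()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_train = 1750L, n_val = 120L,
                       areas = DEFAULT_AREAS,
                       voxels_per_area = 100L,
                       feature_dims = c(32L, 64L, 128L),
                       sparsity_k = 3L,
                       snr = 10,
                       beta_marginal = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       beta_relational = 0.5,
                       layer_of_area = NULL,
                       seed = 1L) {
  stopifnot(n_train > 0, n_val > 0, voxels_per_area > 0,
            length(areas) == 5L, !anyDuplicated(areas),
            length(feature_dims) >= 1L, all(feature_dims > 0),
            sparsity_k > 0, snr > 0,
            length(beta_marginal) == 5L, all(is.finite(beta_marginal)),
            is.finite(beta_relational))
  if (is.null(layer_of_area))
    layer_of_area <- as.integer(round(seq(1L, length(feature_dims), length.out = 5L)))
  stopifnot(length(layer_of_area) == 5L,
            all(layer_of_area >= 1L), all(layer_of_area <= length(feature_dims)))
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 areas = areas, voxels_per_area = as.integer(voxels_per_area),
                 feature_dims = as.integer(feature_dims),
                 sparsity_k = as.integer(sparsity_k), snr = snr,
                 beta_marginal = as.numeric(beta_marginal),
                 beta_relational = as.numeric(beta_relational),
                 layer_of_area = as.integer(layer_of_area),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate layerwise stimulus feature matrices
#'
#' Stand-in for the hierarchical image features a pretrained network would
#' provide: one standard-normal matrix per configured layer, rows =
#' `n_train + n_val` samples.
#'
#' @param config a [sim_config()].
#' @return named list of `n x dim` matrices (`layer1`, `layer2`, ...), with
#'   attribute `n_train`/`n_val` split sizes.
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_train + config$n_val
  set.seed(child_seed(config$seed, 1L))
  out <- lapply(config$feature_dims, function(d) {
    matrix(stats::rnorm(n * d), n, d)
  })
  names(out) <- paste0("layer", seq_along(out))
  attr(out, "n_train") <- config$n_train
  attr(out, "n_val") <- config$n_val
  out
}

#' Simulate voxel responses as sparse linear functions of features
#'
#' Each voxel's response is `X w + noise` where `X` is its area's assigned
#' feature layer and `w` has exactly `sparsity_k` nonzeros; noise variance is
#' set from `snr` as `Var(signal)/snr` (estimated on the training rows).
#' Responses are then standardized per voxel to zero mean and unit variance
#' over the training split, matching the preprocessing of real response
#' amplitudes.
#'
#' @param features output of [simulate_features()] built from the same config.
#' @param config a [sim_config()].
#' @return list with `areas` (named list of samples x voxels matrices) and
#'   `truth` (per-voxel generating layer, support and weights).
#' @export
simulate_voxels_from_features <- function(features, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$sparsity_k > min(config$feature_dims[config$layer_of_area]))
    stop("sparsity_k exceeds the dimension of an assigned feature layer")
  n <- config$n_train + config$n_val
  tr <- seq_len(config$n_train)
  set.seed(child_seed(config$seed, 2L))
  areas <- list(); supports <- list(); values <- list(); layer_of <- integer(0)
  for (a in seq_along(config$areas)) {
    L <- config$layer_of_area[a]
    X <- features[[L]]
    d <- ncol(X)
    V <- config$voxels_per_area
    resp <- matrix(0, n, V)
    ids <- sprintf("%s_v%03d", config$areas[a], seq_len(V))
    for (v in seq_len(V)) {
      sup <- sort(sample.int(d, config$sparsity_k))
      # magnitudes bounded away from zero so the support is identifiable
      w <- stats::runif(config$sparsity_k, 0.5, 1.5) *
        sample(c(-1, 1), config$sparsity_k, replace = TRUE)
      sig <- X[, sup, drop = FALSE] %*% w
      noise_sd <- if (is.finite(config$snr)) sqrt(stats::var(sig[tr]) / config$snr) else 0
      y <- sig + stats::rnorm(n, 0, noise_sd)
      resp[, v] <- (y - mean(y[tr])) / stats::sd(y[tr])
      supports[[ids[v]]] <- sup
      values[[ids[v]]] <- w
      layer_of[ids[v]] <- L
    }
    colnames(resp) <- ids
    areas[[config$areas[a]]] <- resp
  }
  list(areas = areas,
       truth = list(layer_of_voxel = layer_of, supports = supports,
                    values = values, layer_of_area = config$layer_of_area))
}

# label-dependent generative pieces shared by the sequence and full-dataset
# simulators: per-(fine label, area) mean patterns and per-coarse-label
# orthogonal coupling operators.
make_category_truth <- function(K, seed) {
  set.seed(seed)
  mu <- array(stats::rnorm(23L * 5L * K), dim = c(23L, 5L, K))
  mixing <- lapply(1:5, function(cl)
    lapply(1:5, function(a) qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))))
  list(mu = mu, mixing = mixing)
}

# balanced (within +/- 1) fine label assignment, seeded
balanced_fine_labels <- function(n, seed) {
  set.seed(seed)
  sample(rep(0:22, length.out = n))
}

category_patterns <- function(fine, coarse, truth, config, K, seed_noise) {
  n <- length(fine)
  set.seed(seed_noise)
  z <- matrix(stats::rnorm(n * K), n, K)      # shared latent per sample
  x <- array(stats::rnorm(n * 5L * K), dim = c(n, 5L, K)) # unit Gaussian noise
  for (a in 1:5) {
    marg <- matrix(truth$mu[fine + 1L, a, ], nrow = n)
    x[, a, ] <- x[, a, ] + config$beta_marginal[a] * marg
    if (config$beta_relational != 0) {
      for (cl in 0:4) {
        idx <- which(coarse == cl)
        if (length(idx))
          x[idx, a, ] <- x[idx, a, ] + config$beta_relational *
            z[idx, , drop = FALSE] %*% t(truth$mixing[[cl + 1L]][[a]])
      }
    }
  }
  x
}

#' Simulate labeled area-sequence samples
#'
#' Generates train/validation sets of five-node space sequences carrying two
#' distinct category signals: a per-area marginal signal (`beta_marginal[a]`
#' times a fine-label-specific mean pattern, strengthening from V1 to LO by
#' default) and a cross-area relational signal (`beta_relational` times a
#' coarse-label-specific orthogonal mixing of a shared latent vector — each
#' area's marginal distribution is label-independent standard normal, so the
#' label is carried only by the coupling between areas), plus unit Gaussian
#' noise. Fine labels are balanced within one sample.
#'
#' @param config a [sim_config()]; `voxels_per_area` is the per-node dimension.
#' @param hierarchy a [make_label_hierarchy()] result.
#' @return list with `train` and `val` ([sequence_set]s) and `truth`
#'   (mean patterns `mu`, coupling operators `mixing`).
#' @export
simulate_area_sequences <- function(config, hierarchy) {
  stopifnot(inherits(config, "sim_config"), inherits(hierarchy, "label_hierarchy"))
  K <- config$voxels_per_area
  n <- config$n_train + config$n_val
  fine <- balanced_fine_labels(n, child_seed(config$seed, 3L))
  labs <- label_frame(hierarchy, fine)
  truth <- make_category_truth(K, child_seed(config$seed, 4L))
  x <- category_patterns(labs$fine, labs$coarse, truth, config, K,
                         child_seed(config$seed, 5L))
  tr <- seq_len(config$n_train)
  va <- config$n_train + seq_len(config$n_val)
  list(train = sequence_set(x[tr, , , drop = FALSE], labs[tr, ], config$areas),
       val = sequence_set(x[va, , , drop = FALSE], labs[va, ], config$areas),
       truth = truth)
}

#' Randomly permute the labels of a sequence set
#'
#' Null control for significance testing: voxel data are untouched while the
#' three-level label rows are jointly permuted, so the label histogram is
#' preserved exactly and any real association between patterns and labels is
#' destroyed.
#'
#' @param dataset a [sequence_set].
#' @param seed integer seed for the permutation.
#' @return a [sequence_set] with permuted labels.
#' @export
shuffle_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "sequence_set"), nobs(dataset) > 0L)
  set.seed(child_seed(seed, 6L))
  perm <- sample.int(nobs(dataset))
  sequence_set(dataset$x, dataset$labels[perm, , drop = FALSE], dataset$areas)
}

#' Simulate a complete dataset for the end-to-end pipeline
#'
#' Composes the feature-driven and category-driven generators into one
#' [decoding_dataset]: each voxel's response is its sparse linear feature
#' signal plus its area's marginal and relational category components plus
#' noise, standardized per voxel over the training rows. Encoding-model
#' fitting, voxel selection and category decoding can all run on the result.
#'
#' @param config a [sim_config()].
#' @param hierarchy a [make_label_hierarchy()] result.
#' @return a [decoding_dataset] with attribute `truth` (supports, weights,
#'   category means, coupling operators) and `features` (the layer matrices).
#' @export
simulate_dataset <- function(config, hierarchy) {
  stopifnot(inherits(config, "sim_config"), inherits(hierarchy, "label_hierarchy"))
  feats <- simulate_features(config)
  vox <- simulate_voxels_from_features(feats, config)
  K <- config$voxels_per_area
  n <- config$n_train + config$n_val
  fine <- balanced_fine_labels(n, child_seed(config$seed, 3L))
  labs <- label_frame(hierarchy, fine)
  truth <- make_category_truth(K, child_seed(config$seed, 4L))
  cat_x <- category_patterns(labs$fine, labs$coarse, truth, config, K,
                             child_seed(config$seed, 5L))
  tr <- seq_len(config$n_train)
  areas <- vox$areas
  for (a in seq_along(areas)) {
    y <- areas[[a]] + cat_x[, a, ]
    areas[[a]] <- scale(y, center = colMeans(y[tr, , drop = FALSE]),
                        scale = apply(y[tr, , drop = FALSE], 2L, stats::sd))
    attr(areas[[a]], "scaled:center") <- NULL
    attr(areas[[a]], "scaled:scale") <- NULL
  }
  ds <- decoding_dataset(areas, labs,
                         split = list(train = tr, val = config$n_train + seq_len(config$n_val)),
                         meta = list(generator = "visseq::simulate_dataset",
                                     seed = config$seed))
  attr(ds, "truth") <- c(vox$truth, truth)
  attr(ds, "features") <- feats
  ds
}
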