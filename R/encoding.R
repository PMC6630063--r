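#' Pearson correlation with an explicit undefined flag
#'
#' Held-out correlation between predicted and observed voxel responses is the
#' encoding-performance score. When either vector is constant the correlation
#' is undefined; `NA` is returned with attribute `undefined = TRUE` so callers
#' can rank such voxels last rather than error.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @return scalar in `[-1, 1]`, or `NA` flagged undefined.
#' @export
pearson_correlation <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(pred, obs)
}

#' Fit voxel-wise encoding models for every (voxel, layer) pair
#'
#' For each voxel and each feature layer, a sparse linear model is fitted by
#' [fit_romp()] on the training rows (feature columns z-scored with
#' training-split statistics so that residual-correlation magnitudes are
#' comparable across columns), and scored by Pearson correlation between
#' predicted and observed responses on the validation rows. Voxels with any
#' non-finite response are dropped with a message.
#'
#' @param features named list of `n x dim` feature matrices (layers).
#' @param areas named list of `n x voxels` response matrices.
#' @param split list with integer vectors `train` and `val`.
#' @param max_nonzeros,residual_tol ROMP settings (see [fit_romp()]).
#' @return an object of class `encoding_fits`: a data frame `fits` with one
#'   row per (voxel, layer) — `voxel_id`, `area`, `layer`, `n_support`,
#'   `val_correlation` — plus the list of `romp_fit` objects in `weights`,
#'   keyed `"<voxel_id>.layer<j>"`.
#' @export
fit_encoding_models <- function(features, areas, split,
                                max_nonzeros = 20L, residual_tol = 1e-4) {
  stopifnot(is.list(features), length(features) >= 1L,
            is.list(areas), length(areas) >= 1L,
            length(split$train) >= 2L, length(split$val) >= 2L)
  tr <- split$train
  va <- split$val
  # z-score feature columns on training statistics, once per layer
  Xs <- lapply(features, function(X) {
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
  })
  rows <- list()
  weights <- list()
  for (a in names(areas)) {
    Y <- areas[[a]]
    bad <- !apply(is.finite(Y), 2L, all)
    if (any(bad)) {
      message("dropping ", sum(bad), " voxel(s) with non-finite responses in ", a)
      Y <- Y[, !bad, drop = FALSE]
    }
    ids <- colnames(Y)
    for (v in seq_len(ncol(Y))) {
      y <- Y[, v]
      for (j in seq_along(Xs)) {
        fit <- fit_romp(Xs[[j]][tr, , drop = FALSE], y[tr],
                        max_nonzeros = max_nonzeros, residual_tol = residual_tol)
        pred <- predict(fit, Xs[[j]][va, , drop = FALSE])
        r <- pearson_correlation(pred, y[va])
        key <- paste0(ids[v], ".layer", j)
        weights[[key]] <- fit
        rows[[key]] <- data.frame(voxel_id = ids[v], area = a, layer = j,
                                  n_support = length(fit$support),
                                  val_correlation = as.numeric(r))
      }
    }
  }
  fits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(fits = fits, weights = weights,
                 layers = names(features) %||% paste0("layer", seq_along(features))),
            class = "encoding_fits")
}

#' @export
print.encoding_fits <- function(x, ...) {
  cat("Encoding fits:", nrow(x$fits), "voxel-layer models over",
      length(unique(x$fits$area)), "areas and",
      length(unique(x$fits$layer)), "layers\n")
  agg <- stats::aggregate(val_correlation ~ area + layer, data = x$fits,
                          FUN = function(z) round(mean(z, na.rm = TRUE), 3))
  print(agg, row.names = FALSE)
  invisible(x)
}

fits_frame <- function(fits) {
  if (inherits(fits, "encoding_fits")) fits$fits else as.data.frame(fits)
}

#' Select the best feature layer for each visual area
#'
#' For each area and layer, the mean held-out correlation of the `top_n` best
#' voxels (default 200, clipped to availability; undefined correlations rank
#' last) is computed; the layer with the best mean is chosen, ties broken
#' toward the lower layer index.
#'
#' @param fits an `encoding_fits` object or its fit table.
#' @param top_n number of best voxels averaged per (area, layer).
#' @return named integer vector area -> chosen layer.
#' @export
select_layer_per_area <- function(fits, top_n = 200L) {
  tab <- fits_frame(fits)
  if (!nrow(tab)) stop("empty fit table")
  out <- integer(0)
  for (a in unique(tab$area)) {
    layers <- sort(unique(tab$layer[tab$area == a]))
    score <- vapply(layers, function(j) {
      r <- tab$val_correlation[tab$area == a & tab$layer == j]
      r <- sort(r[!is.na(r)], decreasing = TRUE)
      if (!length(r)) return(-Inf)
      mean(r[seq_len(min(top_n, length(r)))])
    }, numeric(1))
    out[a] <- layers[which.max(score)] # which.max keeps the first (lowest) on ties
  }
  out
}

#' Select the most predictable voxels of an area on its chosen layer
#'
#' Returns the `k` voxels with the highest held-out correlation, in
#' descending order; ties break by ascending voxel id, and undefined
#' correlations rank last. Asking for more voxels than exist clips with a
#' warning.
#'
#' @param fits an `encoding_fits` object or its fit table.
#' @param area area name.
#' @param chosen_layer layer index the selection is made on.
#' @param k number of voxels to keep (default 100).
#' @return an object of class `area_selection` with `area`, `chosen_layer`,
#'   `voxel_ids` and the selected rows of the fit table.
#' @export
select_voxels <- function(fits, area, chosen_layer, k = 100L) {
  tab <- fits_frame(fits)
  tab <- tab[tab$area == area & tab$layer == chosen_layer, , drop = FALSE]
  if (!nrow(tab)) stop("no fitted voxels for area ", area, " on layer ", chosen_layer)
  if (k > nrow(tab)) {
    warning("requested ", k, " voxels but only ", nrow(tab), " available in ",
            area, "; clipping", call. = FALSE)
    k <- nrow(tab)
  }
  r <- tab$val_correlation
  r[is.na(r)] <- -Inf
  ord <- order(-r, tab$voxel_id)
  sel <- tab[ord[seq_len(k)], , drop = FALSE]
  structure(list(area = area, chosen_layer = chosen_layer,
                 voxel_ids = sel$voxel_id, fits = sel),
            class = "area_selection")
}

#' @export
print.area_selection <- function(x, ...) {
  cat("Area ", x$area, ": ", length(x$voxel_ids), " voxels on layer ",
      x$chosen_layer, " (best r = ",
      format(x$fits$val_correlation[1L], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Assemble space-sequence samples from per-area voxel selections
#'
#' Builds the decoder's input: for every sample, the selected voxels of each
#' area form one node vector, nodes ordered V1 -> LO (the configured area
#' order). All selections must keep the same number of voxels.
#'
#' @param selections named list of [select_voxels()] results covering exactly
#'   the dataset's areas.
#' @param dataset a [decoding_dataset].
#' @return list with `train` and `val` [sequence_set]s.
#' @export
assemble_sequences <- function(selections, dataset) {
  stopifnot(inherits(dataset, "decoding_dataset"))
  areas <- names(dataset$areas)
  if (!setequal(names(selections), areas))
    stop("selections must cover exactly the areas: ", paste(areas, collapse = ", "))
  ks <- vapply(selections, function(s) length(s$voxel_ids), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all area selections must have the same number of voxels")
  K <- ks[[1L]]
  n <- nrow(dataset$labels)
  x <- array(0, dim = c(n, length(areas), K))
  for (a in seq_along(areas)) {
    sel <- selections[[areas[a]]]
    cols <- match(sel$voxel_ids, colnames(dataset$areas[[areas[a]]]))
    if (anyNA(cols)) stop("selection names missing from area ", areas[a])
    x[, a, ] <- dataset$areas[[areas[a]]][, cols, drop = FALSE]
  }
  full <- sequence_set(x, dataset$labels, areas)
  list(train = full[dataset$split$train], val = full[dataset$split$val])
}
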