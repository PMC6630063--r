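#' Validated configuration for the end-to-end pipeline
#'
#' A single declarative configuration covering every stage: data source
#' (synthetic simulator config or an on-disk dataset path), encoding
#' settings, decoder settings, the methods and label levels to run, and the
#' repeat seeds. Unknown keys are rejected so that typos fail before any
#' stage runs.
#'
#' @param sim a [sim_config()] for synthetic data, or `NULL` when loading.
#' @param dataset_path directory of an on-disk dataset (used when `sim` is
#'   `NULL`).
#' @param top_n voxels averaged for layer selection (default 200).
#' @param k voxels selected per area (default 100).
#' @param max_nonzeros,residual_tol ROMP settings.
#' @param methods character vector of decoders to train: any of
#'   `"brnn"`, `"lstm_forward"`, `"lstm_backward"`, `"nn"`,
#'   `"decision_tree"`, `"random_forest"`, `"adaboost"`, `"svm_linear"`,
#'   `"svm_rbf"`.
#' @param levels label levels to decode (subset of coarse/mid/fine).
#' @param seeds integer vector of repeat seeds (default `1:5`).
#' @param decoder named list of overrides passed to [brnn()] /
#'   [mlp_decoder()] (e.g. `epochs`, `hidden_dim`).
#' @param ... unknown keys: always an error.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), dataset_path = NULL,
                            top_n = 200L, k = 100L,
                            max_nonzeros = 20L, residual_tol = 1e-4,
                            methods = c("svm_linear", "nn", "brnn"),
                            levels = "coarse", seeds = 1:5,
                            decoder = list(), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  known <- c("brnn", "lstm_forward", "lstm_backward", "nn", "decision_tree",
             "random_forest", "adaboost", "svm_linear", "svm_rbf")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  stopifnot(is.null(sim) || inherits(sim, "sim_config"),
            !is.null(sim) || !is.null(dataset_path),
            all(levels %in% c("coarse", "mid", "fine")),
            top_n >= 1L, k >= 1L, length(seeds) >= 1L)
  structure(list(sim = sim, dataset_path = dataset_path,
                 top_n = as.integer(top_n), k = as.integer(k),
                 max_nonzeros = as.integer(max_nonzeros),
                 residual_tol = residual_tol,
                 methods = methods, levels = levels,
                 seeds = as.integer(seeds), decoder = decoder),
            class = "pipeline_config")
}

# stable hash of a configuration, for provenance stamping of outputs
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

train_one_method <- function(method, seqs, level, seed, decoder_opts) {
  d_args <- function(fn, extra) do.call(fn, c(list(train = seqs$train,
                                                   val = seqs$val,
                                                   level = level, seed = seed),
                                              extra))
  switch(method,
    brnn = d_args(brnn, c(decoder_opts, list(directions = "both"))),
    lstm_forward = d_args(brnn, c(decoder_opts, list(directions = "forward"))),
    lstm_backward = d_args(brnn, c(decoder_opts, list(directions = "backward"))),
    nn = d_args(mlp_decoder, decoder_opts),
    classical_decoder(seqs$train, seqs$val, kind = method, level = level,
                      seed = seed))
}

#' Run the full encode-select-decode-evaluate pipeline
#'
#' Executes every stage in order: simulate (or load) the dataset; fit
#' voxel-wise encoding models and select the best layer and top voxels per
#' area; assemble the space sequences; train each requested method once per
#' seed and level; and write the evaluation report. Every artifact directory
#' carries the configuration hash and seed list in `provenance.json`, and a
#' stage-granular `log.txt`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the output directory path, invisibly; artifacts are
#'   `fits.tsv` (encoding fit table), `selections.tsv`,
#'   `report/accuracy.tsv` (and confusions), `provenance.json`, `log.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "log.txt")
  cat(NULL, file = logf)
  stage <- function(name, expr) {
    cat("[", name, "] start\n", file = logf, sep = "", append = TRUE)
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE))
    cat("[", name, "] done\n", file = logf, sep = "", append = TRUE)
    out
  }
  ds <- stage("data", {
    if (!is.null(config$sim)) {
      hierarchy <- make_label_hierarchy(config$sim$seed)
      simulate_dataset(config$sim, hierarchy)
    } else {
      load_dataset(config$dataset_path)
    }
  })
  feats <- attr(ds, "features")
  seqs <- if (!is.null(feats)) {
    enc <- stage("encoding", {
      fit_encoding_models(feats, ds$areas, ds$split,
                          max_nonzeros = config$max_nonzeros,
                          residual_tol = config$residual_tol)
    })
    stage("selection", {
      utils::write.table(enc$fits, file.path(out_dir, "fits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      layers <- select_layer_per_area(enc, top_n = config$top_n)
      sels <- lapply(names(ds$areas), function(a)
        select_voxels(enc, a, layers[[a]],
                      k = min(config$k, ncol(ds$areas[[a]]))))
      names(sels) <- names(ds$areas)
      sel_tab <- do.call(rbind, lapply(sels, function(s)
        data.frame(area = s$area, chosen_layer = s$chosen_layer,
                   rank = seq_along(s$voxel_ids), voxel_id = s$voxel_ids)))
      utils::write.table(sel_tab, file.path(out_dir, "selections.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      assemble_sequences(sels, ds)
    })
  } else {
    # no feature matrices available: all voxels feed the sequences directly
    stage("selection", {
      ks <- vapply(ds$areas, ncol, integer(1))
      K <- min(ks)
      x <- array(0, dim = c(nrow(ds$labels), length(ds$areas), K))
      for (a in seq_along(ds$areas)) x[, a, ] <- ds$areas[[a]][, seq_len(K)]
      full <- sequence_set(x, ds$labels, names(ds$areas))
      list(train = full[ds$split$train], val = full[ds$split$val])
    })
  }
  report <- stage("decoding", {
    runs <- list()
    confusions <- list()
    for (m in config$methods) {
      runs[[m]] <- list()
      for (lv in config$levels) {
        rr <- repeated_runs(function(s)
          train_one_method(m, seqs, lv, s, config$decoder),
          seeds = config$seeds)
        runs[[m]][[lv]] <- rr
        model <- train_one_method(m, seqs, lv, config$seeds[1L], config$decoder)
        pred <- predict(model, seqs$val)
        confusions[[paste(m, lv, sep = "_")]] <-
          normalized_confusion_matrix(pred, level_labels(seqs$val$labels, lv),
                                      n_classes_for(lv))
      }
    }
    build_report(runs, confusions = confusions)
  })
  stage("report", {
    write_report(report, file.path(out_dir, "report"))
    jsonlite::write_json(list(config_hash = hash, seeds = config$seeds,
                              methods = config$methods, levels = config$levels,
                              package_version = as.character(utils::packageVersion("visseq"))),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(out_dir)
}
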