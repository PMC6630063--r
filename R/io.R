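#' Write a decoding dataset to the package's text layout
#'
#' The on-disk container is a directory of delimited text tables plus JSON
#' metadata:
#' \preformatted{
#'   <dir>/areas/<name>.tsv   samples x voxels, voxel ids as header
#'   <dir>/labels.tsv         integer columns coarse, mid, fine (zero-based)
#'   <dir>/split.tsv          columns index, partition ("train"/"val")
#'   <dir>/meta.json          area order, sizes, config hash, provenance
#' }
#' The same layout is what [load_dataset()] reads back; a write-then-read
#' round trip is lossless up to numeric text precision (15 significant
#' digits).
#'
#' @param dataset a [decoding_dataset].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "decoding_dataset"))
  dir.create(file.path(dir, "areas"), recursive = TRUE, showWarnings = FALSE)
  for (a in names(dataset$areas)) {
    df <- as.data.frame(signif(dataset$areas[[a]], 15))
    utils::write.table(df, file.path(dir, "areas", paste0(a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n <- nrow(dataset$labels)
  part <- rep("train", n)
  part[dataset$split$val] <- "val"
  utils::write.table(data.frame(index = seq_len(n), partition = part),
                     file.path(dir, "split.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(dataset$meta,
            list(areas = names(dataset$areas), n_samples = n,
                 n_train = length(dataset$split$train),
                 n_val = length(dataset$split$val),
                 format = "visseq-delimited-v1"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a decoding dataset from disk
#'
#' Reads the layout documented in [write_dataset()] and validates it;
#' voxel columns containing non-finite values are dropped with a message.
#' Only the delimited text format is supported.
#'
#' @param path dataset directory.
#' @param format storage format; `"delimited"` is the supported container.
#' @return a [decoding_dataset].
#' @export
load_dataset <- function(path, format = c("delimited", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 containers are not supported by this build; ",
         "use the delimited text layout (see ?write_dataset)")
  if (!dir.exists(path)) stop("dataset directory not found: ", path)
  for (f in c("labels.tsv", "split.tsv", "meta.json"))
    if (!file.exists(file.path(path, f)))
      stop("malformed dataset layout: missing ", f, " in ", path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!dir.exists(file.path(path, "areas")))
    stop("malformed dataset layout: missing areas/ directory in ", path)
  areas <- list()
  for (a in meta$areas) {
    f <- file.path(path, "areas", paste0(a, ".tsv"))
    if (!file.exists(f)) stop("malformed dataset layout: missing area table ", f)
    m <- as.matrix(utils::read.delim(f, check.names = FALSE))
    bad <- !apply(is.finite(m), 2L, all)
    if (any(bad)) {
      message("load_dataset: dropping ", sum(bad),
              " voxel column(s) with non-finite values in ", a)
      m <- m[, !bad, drop = FALSE]
    }
    areas[[a]] <- m
  }
  labels <- utils::read.delim(file.path(path, "labels.tsv"))
  split_tab <- utils::read.delim(file.path(path, "split.tsv"))
  split <- list(train = split_tab$index[split_tab$partition == "train"],
                val = split_tab$index[split_tab$partition == "val"])
  decoding_dataset(areas, labels, split, meta = as.list(meta))
}

#' Load a converted copy of the vim-1 natural-image fMRI dataset
#'
#' The vim-1 release (1750 training / 120 validation natural-image stimuli,
#' per-area deconvolved voxel response amplitudes for areas V1, V2, V3, V4
#' and LO) is distributed by its authors as MATLAB containers from
#' \verb{http://crcns.org/data-sets/vc/vim-1} after registration; this
#' package never downloads it. This adapter loads a copy that the user has
#' converted to the package's text layout (for example with
#' `scipy.io`/`h5py` in Python, writing one `areas/<name>.tsv` per region
#' plus `labels.tsv` and `split.tsv` — see [write_dataset()] for the layout),
#' and additionally asserts the release's invariants: exactly the five areas
#' and the 1750/120 partition.
#'
#' @param path directory holding the converted dataset.
#' @return a [decoding_dataset].
#' @export
load_vim1 <- function(path) {
  if (!dir.exists(path))
    stop("vim-1 directory not found: ", path,
         "\nObtain the release from http://crcns.org/data-sets/vc/vim-1 ",
         "and convert it to the text layout described in ?load_vim1")
  ds <- load_dataset(path, format = "delimited")
  if (!identical(sort(names(ds$areas)), sort(DEFAULT_AREAS)))
    stop("vim-1 layout must contain exactly the areas ",
         paste(DEFAULT_AREAS, collapse = ", "))
  if (length(ds$split$train) != 1750L || length(ds$split$val) != 120L)
    stop("vim-1 partition must be 1750 training / 120 validation samples, got ",
         length(ds$split$train), "/", length(ds$split$val))
  ds$areas <- ds$areas[DEFAULT_AREAS]
  ds
}

#' Save a fitted decoder to a text checkpoint
#'
#' Serialises every parameter array and the training configuration to a JSON
#' file at full double precision; [load_decoder()] restores a model whose
#' predictions are identical to the original's.
#'
#' @param model a [brnn()] or [mlp_decoder()] model.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_decoder <- function(model, path) {
  stopifnot(inherits(model, c("brnn_model", "mlp_model")))
  obj <- list(class = class(model)[1L],
              config = model$config,
              theta = lapply(model$theta, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- lapply(obj$theta, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else p$data
  })
  cfg <- obj$config
  if (obj$class == "brnn_model") {
    bidir <- cfg$directions == "both"
    params <- list(fwd = as_lstm_params(theta$fwd_W, theta$fwd_b),
                   bwd = if (bidir) as_lstm_params(theta$bwd_W, theta$bwd_b),
                   head = list(W = theta$head_W, b = theta$head_b))
    structure(list(params = params, theta = theta, config = cfg,
                   history = NULL, val_accuracy = NA_real_),
              class = "brnn_model")
  } else {
    structure(list(theta = theta, config = cfg, history = NULL,
                   val_accuracy = NA_real_),
              class = "mlp_model")
  }
}
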