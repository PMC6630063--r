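#' Construct a decoding dataset
#'
#' The package's central data container: per-area voxel response matrices
#' (one amplitude per voxel per stimulus, time already removed by
#' deconvolution upstream), a three-column label table and a train/validation
#' split. This is the in-memory form of the on-disk layout written by
#' [write_dataset()].
#'
#' @param areas named list of numeric matrices, one per visual area in
#'   sequence order (default `V1, V2, V3, V4, LO`); each is samples x voxels
#'   with voxel identifiers as column names. All areas must have the same
#'   number of rows.
#' @param labels data frame with integer columns `coarse`, `mid`, `fine`
#'   (zero-based), one row per sample.
#' @param split list with integer index vectors `train` and `val`,
#'   a disjoint cover of the sample rows.
#' @param meta optional named list of provenance metadata.
#' @return an object of class `decoding_dataset`.
#' @export
decoding_dataset <- function(areas, labels, split, meta = list()) {
  stopifnot(is.list(areas), length(areas) >= 1L, !is.null(names(areas)))
  n <- nrow(areas[[1L]])
  for (a in names(areas)) {
    m <- areas[[a]]
    if (!is.matrix(m) || !is.numeric(m)) stop("area ", a, " is not a numeric matrix")
    if (nrow(m) != n) stop("area ", a, " has a different number of samples")
    if (is.null(colnames(m))) colnames(areas[[a]]) <- sprintf("%s_v%03d", a, seq_len(ncol(m)))
  }
  stopifnot(is.data.frame(labels), nrow(labels) == n,
            all(c("coarse", "mid", "fine") %in% names(labels)))
  labels <- labels[, c("coarse", "mid", "fine")]
  stopifnot(is.list(split), all(c("train", "val") %in% names(split)))
  idx <- sort(c(split$train, split$val))
  if (!identical(as.integer(idx), seq_len(n)))
    stop("split must partition the ", n, " samples")
  structure(list(areas = areas, labels = labels,
                 split = list(train = as.integer(split$train),
                              val = as.integer(split$val)),
                 meta = meta),
            class = "decoding_dataset")
}

#' @export
print.decoding_dataset <- function(x, ...) {
  cat("Decoding dataset:", nrow(x$labels), "samples (",
      length(x$split$train), "train /", length(x$split$val), "val )\n")
  for (a in names(x$areas)) cat("  ", a, ": ", ncol(x$areas[[a]]), " voxels\n", sep = "")
  invisible(x)
}

#' Construct a sequence sample set
#'
#' Holds the space-sequence form of the data: each sample is an ordered list
#' of per-area voxel vectors (V1 first, LO last), stored as an
#' `n x n_areas x K` array, together with its three-level labels.
#'
#' @param x numeric array `n x L x K` (samples x areas x voxels-per-area).
#' @param labels data frame with columns `coarse`, `mid`, `fine`.
#' @param areas character vector of area names, length `L`, in node order.
#' @return an object of class `sequence_set`.
#' @export
sequence_set <- function(x, labels, areas = DEFAULT_AREAS) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            dim(x)[2L] == length(areas),
            is.data.frame(labels), nrow(labels) == dim(x)[1L])
  structure(list(x = x, labels = labels[, c("coarse", "mid", "fine")],
                 areas = areas),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  d <- dim(x$x)
  cat("Sequence set:", d[1L], "samples x", d[2L], "areas x", d[3L],
      "voxels (", paste(x$areas, collapse = " -> "), ")\n")
  invisible(x)
}

#' Number of samples in a sequence set
#' @param object a `sequence_set`.
#' @param ... unused.
#' @export
nobs.sequence_set <- function(object, ...) dim(object$x)[1L]

#' Subset a sequence set by sample index
#' @param x a `sequence_set`.
#' @param i integer or logical sample index.
#' @param ... unused.
#' @export
`[.sequence_set` <- function(x, i, ...) {
  sequence_set(x$x[i, , , drop = FALSE], x$labels[i, , drop = FALSE], x$areas)
}

#' Reverse the node (area) order of every sequence
#'
#' Used by the top-down (backward) ablation: a forward recurrent pass over the
#' reversed sequence is by construction a backward pass over the original.
#'
#' @param s a `sequence_set`.
#' @return a `sequence_set` with areas in reversed order.
#' @export
reverse_sequences <- function(s) {
  stopifnot(inherits(s, "sequence_set"))
  L <- dim(s$x)[2L]
  sequence_set(s$x[, L:1, , drop = FALSE], s$labels, rev(s$areas))
}

#' Flatten a sequence set to a samples x (L*K) matrix
#'
#' Concatenates the per-area vectors in area order; this is the "entire visual
#' areas as a whole" input used by the classical and fully connected baselines.
#'
#' @param s a `sequence_set`.
#' @return numeric matrix `n x (L*K)`.
#' @export
flatten_sequences <- function(s) {
  stopifnot(inherits(s, "sequence_set"))
  d <- dim(s$x)
  out <- matrix(aperm(s$x, c(1L, 3L, 2L)), nrow = d[1L])
  colnames(out) <- as.vector(vapply(seq_len(d[2L]), function(a)
    sprintf("%s_%03d", s$areas[a], seq_len(d[3L])), character(d[3L])))
  out
}

# pull the label column for a decoding level
level_labels <- function(labels, level = c("coarse", "mid", "fine")) {
  level <- match.arg(level)
  as.integer(labels[[level]])
}

n_classes_for <- function(level) c(coarse = 5L, mid = 10L, fine = 23L)[[level]]
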