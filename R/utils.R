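#' Derive a child seed from a global seed
#'
#' One global seed fans out to per-component child seeds by fixed offsets so
#' that each stage (feature simulation, voxel synthesis, training, shuffling)
#' is independently reproducible. The result always fits in a 32-bit signed
#' integer.
#'
#' @param seed integer global seed.
#' @param offset integer component offset (each component uses a distinct one).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m) * 48271 + (abs(offset) + 1) * 16807
  as.integer(s %% (m - 1) + 1)
}

#' Numerically stable softmax over the rows of a matrix
#' @param z numeric matrix of logits (samples x classes) or a vector.
#' @return matrix (or vector) of probabilities; rows sum to 1.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) {
    z <- z - max(z)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical ordered visual-area names, primary to lateral occipital.
DEFAULT_AREAS <- c("V1", "V2", "V3", "V4", "LO")

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
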