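#' Initialize LSTM parameters for one direction
#'
#' Weights act on the concatenation `[h_prev, x_t]` (hidden state first), one
#' block of columns per gate in the order forget, input, output, candidate.
#' Entries are drawn uniformly in `±1/sqrt(H)`; biases start at zero except
#' the forget-gate block, which starts at +1 so early training does not
#' forget aggressively.
#'
#' @param input_dim K, the per-node voxel dimension.
#' @param hidden_dim H, the per-direction feature dimension (default 16).
#' @return an object of class `lstm_params`: `W` ((K+H) x 4H) and `b` (4H).
#' @export
init_lstm_params <- function(input_dim, hidden_dim = 16L) {
  K <- as.integer(input_dim); H <- as.integer(hidden_dim)
  stopifnot(K >= 1L, H >= 1L)
  s <- 1 / sqrt(H)
  W <- matrix(stats::runif((K + H) * 4L * H, -s, s), K + H, 4L * H)
  b <- numeric(4L * H)
  b[seq_len(H)] <- 1 # forget-gate block
  structure(list(W = W, b = b, input_dim = K, hidden_dim = H),
            class = "lstm_params")
}

#' Count of trainable parameters in one LSTM direction
#' @param params an `lstm_params`.
#' @return integer `4 * ((K + H) * H + H)`.
#' @export
n_params_lstm <- function(params) {
  length(params$W) + length(params$b)
}

# gate column blocks of the combined weight matrix
gate_block <- function(H, which) (which - 1L) * H + seq_len(H)

#' One LSTM cell step
#'
#' Computes the gate activations and the new cell/hidden state for a single
#' input vector: `f, i, o = sigmoid(W_g [h_prev, x_t] + b_g)`,
#' `g = tanh(W_c [h_prev, x_t] + b_c)`, `c_t = f*c_prev + i*g`,
#' `h_t = o * tanh(c_t)` (all elementwise).
#'
#' @param x_t numeric K-vector (one node's voxel pattern).
#' @param prev list with numeric H-vectors `h` and `c` (previous state).
#' @param params an `lstm_params`.
#' @return list with `state` (list `h`, `c`) and `gates`
#'   (list `f`, `i`, `o`, `candidate`).
#' @export
lstm_cell_step <- function(x_t, prev, params) {
  H <- params$hidden_dim
  stopifnot(length(x_t) == params$input_dim,
            length(prev$h) == H, length(prev$c) == H)
  assert_finite(x_t, "x_t")
  z <- as.numeric(crossprod(params$W, c(prev$h, x_t))) + params$b
  f <- sigmoid(z[gate_block(H, 1L)])
  i <- sigmoid(z[gate_block(H, 2L)])
  o <- sigmoid(z[gate_block(H, 3L)])
  g <- tanh(z[gate_block(H, 4L)])
  c_t <- f * prev$c + i * g
  h_t <- o * tanh(c_t)
  list(state = list(h = h_t, c = c_t),
       gates = list(f = f, i = i, o = o, candidate = g))
}

#' Run one LSTM direction over a space sequence
#'
#' Consumes the node vectors in area order (`forward`, V1 first) or reversed
#' (`backward`, LO first), starting from zero state, and returns the hidden
#' state after the last consumed node.
#'
#' @param sequence numeric matrix `L x K`, one row per node in area order.
#' @param params an `lstm_params`.
#' @param direction `"forward"` or `"backward"`.
#' @return numeric H-vector, the final hidden state.
#' @export
run_direction <- function(sequence, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  sequence <- as.matrix(sequence)
  if (!nrow(sequence)) stop("empty sequence")
  ord <- if (direction == "forward") seq_len(nrow(sequence)) else rev(seq_len(nrow(sequence)))
  st <- list(h = numeric(params$hidden_dim), c = numeric(params$hidden_dim))
  for (t in ord) st <- lstm_cell_step(sequence[t, ], st, params)$state
  st$h
}

# --- batched forward pass used by training ---------------------------------
# x: n x L x K array already in the order to be consumed.
# Returns caches needed for backprop.
lstm_forward_batch <- function(x, params) {
  d <- dim(x); n <- d[1L]; L <- d[2L]; H <- params$hidden_dim
  Hc <- matrix(0, n, H)   # h_{t-1}
  Cc <- matrix(0, n, H)
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    A <- cbind(Hc, matrix(x[, t, ], n))
    Z <- A %*% params$W + rep(params$b, each = n)
    Fg <- sigmoid(Z[, gate_block(H, 1L), drop = FALSE])
    Ig <- sigmoid(Z[, gate_block(H, 2L), drop = FALSE])
    Og <- sigmoid(Z[, gate_block(H, 3L), drop = FALSE])
    Gg <- tanh(Z[, gate_block(H, 4L), drop = FALSE])
    Cprev <- Cc
    Cc <- Fg * Cprev + Ig * Gg
    Tt <- tanh(Cc)
    Hc <- Og * Tt
    cache[[t]] <- list(A = A, F = Fg, I = Ig, O = Og, G = Gg,
                       Cprev = Cprev, C = Cc, T = Tt)
  }
  list(h = Hc, cache = cache)
}

# Backprop through time for one direction. dH: n x H gradient at final h.
# Returns list(dW, db).
lstm_backward_batch <- function(dH, params, fwd) {
  H <- params$hidden_dim
  L <- length(fwd$cache)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  db <- numeric(length(params$b))
  dC <- matrix(0, nrow(dH), H)
  for (t in L:1) {
    cc <- fwd$cache[[t]]
    dO <- dH * cc$T
    dC <- dC + dH * cc$O * (1 - cc$T^2)
    dF <- dC * cc$Cprev
    dI <- dC * cc$G
    dG <- dC * cc$I
    dZ <- cbind(dF * cc$F * (1 - cc$F),
                dI * cc$I * (1 - cc$I),
                dO * cc$O * (1 - cc$O),
                dG * (1 - cc$G^2))
    dW <- dW + crossprod(cc$A, dZ)
    db <- db + colSums(dZ)
    dA <- dZ %*% t(params$W)
    dH <- dA[, seq_len(H), drop = FALSE]
    dC <- dC * cc$F
  }
  list(dW = dW, db = db)
}

#' Encode a space sequence with both LSTM directions
#'
#' Concatenates the forward (V1 -> LO) and backward (LO -> V1) final hidden
#' states, forward half first: a 2H-dimensional feature (32-D at the default
#' H = 16) for the softmax head.
#'
#' @param sequence numeric matrix `L x K`.
#' @param model a fitted [brnn()] model (or any list with `params$fwd` and
#'   `params$bwd` `lstm_params`).
#' @return numeric 2H-vector.
#' @export
bidirectional_encode <- function(sequence, model) {
  p <- model$params
  if (is.null(p$bwd)) stop("model has no backward direction")
  c(run_direction(sequence, p$fwd, "forward"),
    run_direction(sequence, p$bwd, "backward"))
}

#' Multiclass focal loss
#'
#' Cross-entropy scaled by `(1 - p_y)^gamma`, where `p_y` is the predicted
#' probability of the true class; `gamma = 0` recovers plain cross-entropy
#' and larger `gamma` down-weights easy samples. `p_y` is clamped at 1e-12
#' (with a message) before the logarithm.
#'
#' @param probs numeric probability vector over classes, or an `n x C` matrix
#'   of per-sample probabilities.
#' @param label true class index (1-based), or an n-vector of them.
#' @param gamma focusing exponent, >= 0 (default 5).
#' @return scalar loss: the per-sample value for a vector input, the batch
#'   mean for a matrix input.
#' @examples
#' focal_loss(c(0.5, 0.5), 1, gamma = 5)  # 0.5^5 * log(2)
#' @export
focal_loss <- function(probs, label, gamma = 5) {
  stopifnot(gamma >= 0)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  stopifnot(length(label) == nrow(probs), all(label >= 1L), all(label <= ncol(probs)))
  p <- probs[cbind(seq_len(nrow(probs)), label)]
  if (any(p < 1e-12)) {
    message("focal_loss: clamping ", sum(p < 1e-12), " probabilit(ies) at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-(1 - p)^gamma * log(p))
}
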