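# Training engine shared by the recurrent and fully connected decoders:
# Adam with decoupled L2 weight decay over a flat named list of parameter
# arrays ("...W..." entries are decayed, biases are not).

adam_init <- function(theta) {
  list(m = lapply(theta, function(p) p * 0),
       v = lapply(theta, function(p) p * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    theta[[nm]] <- theta[[nm]] - lr * upd
    if (grepl("W", nm)) theta[[nm]] <- theta[[nm]] - lr * weight_decay * theta[[nm]]
  }
  list(theta = theta, state = state)
}

# gradient of the mean focal loss w.r.t. logits, given softmax probs P (n x C)
# and 1-based labels y.
focal_grad_logits <- function(P, y, gamma) {
  n <- nrow(P)
  p <- pmax(P[cbind(seq_len(n), y)], 1e-12)
  # d/dp of -(1-p)^g log p  (1-p clamped so the g<1 exponent stays finite)
  dLdp <- if (gamma == 0) -1 / p else
    gamma * pmax(1 - p, 1e-12)^(gamma - 1) * log(p) - (1 - p)^gamma / p
  D <- -P * (p * dLdp)            # term for j != y: dp/dz_j = -p * P_j
  D[cbind(seq_len(n), y)] <- p * dLdp * (1 - p) # j == y
  D / n
}

as_lstm_params <- function(W, b) {
  H <- length(b) / 4L
  structure(list(W = W, b = b, input_dim = nrow(W) - H, hidden_dim = as.integer(H)),
            class = "lstm_params")
}

# full forward + gradients for the recurrent decoder on one batch.
# x: n x L x K in area order; theta: flat parameter list; returns loss, grads.
brnn_loss_grad <- function(theta, x, y, gamma, bidirectional, drop_mask = NULL) {
  n <- dim(x)[1L]
  pf <- as_lstm_params(theta$fwd_W, theta$fwd_b)
  fb <- lstm_forward_batch(x, pf)
  if (bidirectional) {
    L <- dim(x)[2L]
    pb <- as_lstm_params(theta$bwd_W, theta$bwd_b)
    bb <- lstm_forward_batch(x[, L:1, , drop = FALSE], pb)
    U <- cbind(fb$h, bb$h)
  } else {
    U <- fb$h
  }
  if (is.null(drop_mask)) drop_mask <- matrix(1, n, ncol(U))
  Ud <- U * drop_mask
  logits <- Ud %*% theta$head_W + rep(theta$head_b, each = n)
  P <- softmax(logits)
  p_true <- pmax(P[cbind(seq_len(n), y)], 1e-12)
  loss <- mean(-(1 - p_true)^gamma * log(p_true))
  dlogits <- focal_grad_logits(P, y, gamma)
  grads <- list(head_W = crossprod(Ud, dlogits),
                head_b = colSums(dlogits))
  dU <- (dlogits %*% t(theta$head_W)) * drop_mask
  H <- pf$hidden_dim
  gf <- lstm_backward_batch(dU[, seq_len(H), drop = FALSE], pf, fb)
  grads$fwd_W <- gf$dW
  grads$fwd_b <- gf$db
  if (bidirectional) {
    gb <- lstm_backward_batch(dU[, H + seq_len(H), drop = FALSE], pb, bb)
    grads$bwd_W <- gb$dW
    grads$bwd_b <- gb$db
  }
  list(loss = loss, grads = grads, probs = P)
}

#' Fit the recurrent space-sequence category decoder
#'
#' Trains an LSTM classifier over the ordered visual-area sequence
#' (V1, V2, V3, V4, LO): each area's selected voxel vector is one node of a
#' length-5 "space sequence". With `directions = "both"` (the default, the
#' bidirectional model) the final hidden states of a forward (bottom-up,
#' V1 -> LO) and a backward (top-down, LO -> V1) LSTM are concatenated into a
#' 2H feature (32-D at the default H = 16), passed through dropout and a fully
#' connected softmax head. Training minimizes the multiclass focal loss
#' (gamma = 5 by default) with Adam and decoupled L2 weight decay, mini-batches
#' of 64, for a fixed epoch budget. Runs are reproducible per seed in
#' single-threaded mode.
#'
#' @param train a [sequence_set] of training samples.
#' @param val optional [sequence_set] scored after every epoch.
#' @param level label level to decode: `"coarse"` (5), `"mid"` (10) or
#'   `"fine"` (23 classes).
#' @param directions `"both"` for the bidirectional model, `"forward"`
#'   (V1 -> LO) or `"backward"` (LO -> V1) for the unidirectional ablations.
#' @param hidden_dim per-direction hidden size H (default 16).
#' @param dropout dropout rate on the combined feature, training only.
#' @param gamma focal-loss focusing exponent.
#' @param batch_size,learning_rate,weight_decay,epochs Adam training recipe
#'   (defaults 64, 0.001, 0.001, 200).
#' @param seed integer seed governing initialization, batch order and dropout.
#' @param verbose print progress every 25 epochs.
#' @return an object of class `brnn_model` with elements `params`
#'   (`fwd`/`bwd` [lstm_params][init_lstm_params] and softmax `head`),
#'   `config`, `history` (per-epoch train loss and validation accuracy) and
#'   `val_accuracy` (final, `NA` without `val`).
#' @seealso [predict.brnn_model()], [bidirectional_encode()], [focal_loss()]
#' @export
brnn <- function(train, val = NULL, level = c("coarse", "mid", "fine"),
                 directions = c("both", "forward", "backward"),
                 hidden_dim = 16L, dropout = 0.5, gamma = 5,
                 batch_size = 64L, learning_rate = 1e-3, weight_decay = 1e-3,
                 epochs = 200L, seed = 1L, verbose = FALSE) {
  level <- match.arg(level)
  directions <- match.arg(directions)
  stopifnot(inherits(train, "sequence_set"), nobs(train) > 0L,
            dropout >= 0, dropout < 1, gamma >= 0,
            batch_size >= 1L, learning_rate > 0, epochs >= 1L)
  d <- dim(train$x)
  K <- d[3L]; Lseq <- d[2L]; H <- as.integer(hidden_dim)
  C <- n_classes_for(level)
  x <- train$x
  if (directions == "backward") x <- x[, Lseq:1, , drop = FALSE]
  y <- level_labels(train$labels, level) + 1L
  bidir <- directions == "both"
  set.seed(child_seed(seed, 7L))
  pf <- init_lstm_params(K, H)
  theta <- list(fwd_W = pf$W, fwd_b = pf$b)
  if (bidir) {
    pb <- init_lstm_params(K, H)
    theta$bwd_W <- pb$W
    theta$bwd_b <- pb$b
  }
  Dfeat <- if (bidir) 2L * H else H
  s <- 1 / sqrt(H)
  theta$head_W <- matrix(stats::runif(Dfeat * C, -s, s), Dfeat, C)
  theta$head_b <- numeric(C)
  st <- adam_init(theta)
  n <- dim(x)[1L]
  hist_loss <- numeric(epochs)
  hist_acc <- rep(NA_real_, epochs)
  xv <- NULL; yv <- NULL
  if (!is.null(val)) {
    xv <- val$x
    if (directions == "backward") xv <- xv[, Lseq:1, , drop = FALSE]
    yv <- level_labels(val$labels, level) + 1L
  }
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- perm[b0:min(b0 + batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      mask <- if (dropout > 0) {
        matrix(stats::rbinom(length(idx) * Dfeat, 1L, 1 - dropout),
               length(idx), Dfeat) / (1 - dropout)
      } else NULL
      lg <- brnn_loss_grad(theta, xb, yb, gamma, bidir, mask)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      upd <- adam_step(theta, lg$grads, st, learning_rate, weight_decay)
      theta <- upd$theta
      st <- upd$state
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    hist_loss[ep] <- ep_loss / nb
    if (!is.null(xv)) {
      pv <- decoder_forward_probs(theta, xv, bidir)
      hist_acc[ep] <- mean(max.col(pv, ties.method = "first") == yv)
    }
    if (verbose && (ep %% 25L == 0L || ep == epochs))
      cat(sprintf("epoch %4d  loss %.4f  val acc %s\n", ep, hist_loss[ep],
                  ifelse(is.na(hist_acc[ep]), "-", sprintf("%.3f", hist_acc[ep]))))
  }
  params <- list(fwd = as_lstm_params(theta$fwd_W, theta$fwd_b),
                 bwd = if (bidir) as_lstm_params(theta$bwd_W, theta$bwd_b),
                 head = list(W = theta$head_W, b = theta$head_b))
  structure(list(params = params, theta = theta,
                 config = list(level = level, n_classes = C,
                               directions = directions, hidden_dim = H,
                               input_dim = K, seq_len = Lseq, dropout = dropout,
                               gamma = gamma, batch_size = batch_size,
                               learning_rate = learning_rate,
                               weight_decay = weight_decay, epochs = epochs,
                               seed = seed, areas = train$areas),
                 history = data.frame(epoch = seq_len(epochs),
                                      train_loss = hist_loss,
                                      val_accuracy = hist_acc),
                 val_accuracy = if (!is.null(xv)) hist_acc[epochs] else NA_real_),
            class = "brnn_model")
}

# probabilities for an n x L x K array under a flat theta (no dropout)
decoder_forward_probs <- function(theta, x, bidirectional) {
  n <- dim(x)[1L]
  pf <- as_lstm_params(theta$fwd_W, theta$fwd_b)
  U <- lstm_forward_batch(x, pf)$h
  if (bidirectional) {
    L <- dim(x)[2L]
    pb <- as_lstm_params(theta$bwd_W, theta$bwd_b)
    U <- cbind(U, lstm_forward_batch(x[, L:1, , drop = FALSE], pb)$h)
  }
  softmax(U %*% theta$head_W + rep(theta$head_b, each = n))
}

#' Predict categories, probabilities or features from a fitted decoder
#'
#' @param object a [brnn()] model.
#' @param newdata a [sequence_set] (or bare `n x L x K` array).
#' @param type `"class"` (zero-based predicted labels, the argmax of the
#'   softmax output), `"prob"` (n x C probability matrix) or `"feature"`
#'   (the 2H — or H for unidirectional models — recurrent feature).
#' @param ... unused.
#' @export
predict.brnn_model <- function(object, newdata, type = c("class", "prob", "feature"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sequence_set")) newdata$x else newdata
  stopifnot(length(dim(x)) == 3L, dim(x)[3L] == object$config$input_dim)
  if (object$config$directions == "backward")
    x <- x[, dim(x)[2L]:1, , drop = FALSE]
  bidir <- object$config$directions == "both"
  if (type == "feature") {
    pf <- object$params$fwd
    U <- lstm_forward_batch(x, pf)$h
    if (bidir)
      U <- cbind(U, lstm_forward_batch(x[, dim(x)[2L]:1, , drop = FALSE],
                                       object$params$bwd)$h)
    return(U)
  }
  P <- decoder_forward_probs(object$theta, x, bidir)
  if (type == "prob") return(P)
  max.col(P, ties.method = "first") - 1L
}

#' @export
print.brnn_model <- function(x, ...) {
  cfg <- x$config
  dir_lab <- switch(cfg$directions, both = "bidirectional",
                    forward = "forward (bottom-up)", backward = "backward (top-down)")
  cat("Recurrent space-sequence decoder (", dir_lab, " LSTM)\n", sep = "")
  cat("  sequence: ", paste(cfg$areas, collapse = " -> "),
      "  (K = ", cfg$input_dim, ", H = ", cfg$hidden_dim, ")\n", sep = "")
  cat("  classes: ", cfg$n_classes, " (", cfg$level, " level), ",
      n_params_decoder(x), " trainable parameters\n", sep = "")
  if (!is.na(x$val_accuracy))
    cat("  final validation accuracy:", sprintf("%.4f", x$val_accuracy), "\n")
  invisible(x)
}

#' @export
summary.brnn_model <- function(object, ...) {
  print(object)
  h <- object$history
  cat("  training loss: first", sprintf("%.4f", h$train_loss[1L]),
      "-> last", sprintf("%.4f", h$train_loss[nrow(h)]), "\n")
  if (!all(is.na(h$val_accuracy)))
    cat("  best validation accuracy:", sprintf("%.4f", max(h$val_accuracy, na.rm = TRUE)),
        "at epoch", which.max(h$val_accuracy), "\n")
  invisible(object)
}

#' Flat list of the decoder's trainable parameter arrays
#' @param object a `brnn_model`.
#' @param ... unused.
#' @export
coef.brnn_model <- function(object, ...) object$theta

n_params_decoder <- function(model) {
  sum(vapply(model$theta, length, integer(1)))
}

#' Plot the training history of a fitted decoder
#' @param x a `brnn_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.brnn_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (all(is.na(h$val_accuracy))) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training focal loss", ...)
  if (!all(is.na(h$val_accuracy)))
    graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                   ylab = "validation accuracy", ...)
  invisible(x)
}
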