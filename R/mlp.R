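# fully connected baseline: same focal-loss/Adam recipe as the recurrent
# decoder, but the five areas are concatenated into one flat vector, so no
# sequence structure is modelled.

mlp_loss_grad <- function(theta, X, y, gamma, drop_mask = NULL) {
  n <- nrow(X)
  Z1 <- X %*% theta$W1 + rep(theta$b1, each = n)
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% theta$W2 + rep(theta$b2, each = n)
  A2 <- pmax(Z2, 0)
  if (is.null(drop_mask)) drop_mask <- matrix(1, n, ncol(A2))
  A2d <- A2 * drop_mask
  logits <- A2d %*% theta$W3 + rep(theta$b3, each = n)
  P <- softmax(logits)
  p_true <- pmax(P[cbind(seq_len(n), y)], 1e-12)
  loss <- mean(-(1 - p_true)^gamma * log(p_true))
  dlog <- focal_grad_logits(P, y, gamma)
  dA2d <- dlog %*% t(theta$W3)
  dA2 <- dA2d * drop_mask
  dZ2 <- dA2 * (Z2 > 0)
  dA1 <- dZ2 %*% t(theta$W2)
  dZ1 <- dA1 * (Z1 > 0)
  list(loss = loss,
       grads = list(W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
                    W2 = crossprod(A1, dZ2), b2 = colSums(dZ2),
                    W3 = crossprod(A2d, dlog), b3 = colSums(dlog)),
       probs = P)
}

mlp_probs <- function(theta, X) {
  n <- nrow(X)
  A1 <- pmax(X %*% theta$W1 + rep(theta$b1, each = n), 0)
  A2 <- pmax(A1 %*% theta$W2 + rep(theta$b2, each = n), 0)
  softmax(A2 %*% theta$W3 + rep(theta$b3, each = n))
}

#' Fit the fully connected neural-network baseline
#'
#' The no-recurrence control for the sequence decoder: the five areas'
#' selected voxels are concatenated into one input vector (500-D at the
#' default 100 voxels per area) and passed through fully connected layers of
#' 64 and 32 ReLU units and a softmax head. Loss, optimizer, dropout
#' placement (on the last hidden layer) and the epoch budget follow the same
#' recipe as [brnn()], so the only difference is whether inter-area sequence
#' structure is modelled.
#'
#' @inheritParams brnn
#' @param hidden integer vector of hidden layer widths (default `c(64, 32)`).
#' @return an object of class `mlp_model` with `theta`, `config`, `history`
#'   and final `val_accuracy`.
#' @export
mlp_decoder <- function(train, val = NULL, level = c("coarse", "mid", "fine"),
                        hidden = c(64L, 32L), dropout = 0.5, gamma = 5,
                        batch_size = 64L, learning_rate = 1e-3,
                        weight_decay = 1e-3, epochs = 200L, seed = 1L,
                        verbose = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(train, "sequence_set"), length(hidden) == 2L)
  X <- flatten_sequences(train)
  y <- level_labels(train$labels, level) + 1L
  C <- n_classes_for(level)
  D0 <- ncol(X)
  set.seed(child_seed(seed, 8L))
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -1 / sqrt(nr), 1 / sqrt(nr)), nr, nc)
  theta <- list(W1 = u(D0, hidden[1L]), b1 = numeric(hidden[1L]),
                W2 = u(hidden[1L], hidden[2L]), b2 = numeric(hidden[2L]),
                W3 = u(hidden[2L], C), b3 = numeric(C))
  st <- adam_init(theta)
  n <- nrow(X)
  Xv <- NULL; yv <- NULL
  if (!is.null(val)) {
    Xv <- flatten_sequences(val)
    yv <- level_labels(val$labels, level) + 1L
  }
  hist_loss <- numeric(epochs)
  hist_acc <- rep(NA_real_, epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- perm[b0:min(b0 + batch_size - 1L, n)]
      mask <- if (dropout > 0) {
        matrix(stats::rbinom(length(idx) * hidden[2L], 1L, 1 - dropout),
               length(idx), hidden[2L]) / (1 - dropout)
      } else NULL
      lg <- mlp_loss_grad(theta, X[idx, , drop = FALSE], y[idx], gamma, mask)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      upd <- adam_step(theta, lg$grads, st, learning_rate, weight_decay)
      theta <- upd$theta; st <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    hist_loss[ep] <- ep_loss / nb
    if (!is.null(Xv))
      hist_acc[ep] <- mean(max.col(mlp_probs(theta, Xv), ties.method = "first") == yv)
    if (verbose && ep %% 25L == 0L)
      cat(sprintf("epoch %4d  loss %.4f\n", ep, hist_loss[ep]))
  }
  structure(list(theta = theta,
                 config = list(level = level, n_classes = C, hidden = hidden,
                               input_dim = D0, dropout = dropout, gamma = gamma,
                               batch_size = batch_size, learning_rate = learning_rate,
                               weight_decay = weight_decay, epochs = epochs,
                               seed = seed),
                 history = data.frame(epoch = seq_len(epochs),
                                      train_loss = hist_loss,
                                      val_accuracy = hist_acc),
                 val_accuracy = if (!is.null(Xv)) hist_acc[epochs] else NA_real_),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cfg <- x$config
  cat("Fully connected baseline: ", cfg$input_dim, " -> ",
      paste(cfg$hidden, collapse = " -> "), " -> ", cfg$n_classes,
      " (", sum(vapply(x$theta, length, integer(1))), " parameters)\n", sep = "")
  if (!is.na(x$val_accuracy))
    cat("  final validation accuracy:", sprintf("%.4f", x$val_accuracy), "\n")
  invisible(x)
}

#' @rdname predict.brnn_model
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "sequence_set")) flatten_sequences(newdata) else as.matrix(newdata)
  P <- mlp_probs(object$theta, X)
  if (type == "prob") return(P)
  max.col(P, ties.method = "first") - 1L
}

#' @export
coef.mlp_model <- function(object, ...) object$theta
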