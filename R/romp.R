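#' Fit a sparse linear encoding model by regularized orthogonal matching pursuit
#'
#' Greedy sparse regression for the voxel-wise encoding problem `y = X w`
#' with `w` constrained to few nonzeros. Each iteration (i) correlates the
#' current residual with every column, `u = X'r`; (ii) takes the
#' `max_nonzeros` largest `|u|` as candidates; (iii) regularizes the
#' candidates to the comparable-magnitude subset with maximal energy —
#' scanning the magnitude-sorted candidates for the window maximizing
#' `sum(u^2)` subject to every pair satisfying `|u_i| <= 2 |u_j|`; (iv) adds
#' that subset to the support and refits by orthogonal least squares on the
#' support. Iteration stops when the residual norm drops below
#' `residual_tol * ||y||`, the support reaches `max_nonzeros`, or the
#' residual stops decreasing; the residual norm is non-increasing across
#' iterations by construction.
#'
#' @param X numeric design matrix, m samples x n features; no all-zero
#'   columns among candidates are ever selected.
#' @param y numeric m-vector of one voxel's responses.
#' @param max_nonzeros sparsity budget (support never exceeds it).
#' @param residual_tol relative residual stopping tolerance.
#' @return an object of class `romp_fit`: `support` (1-based column indices),
#'   `values` (least-squares coefficients on the support), `n_iterations`,
#'   `residual_norm`, and the problem dimensions.
#' @examples
#' X <- diag(4)
#' fit_romp(X, c(0, 3, 0, 1), max_nonzeros = 2)
#' @export
fit_romp <- function(X, y, max_nonzeros = max(1L, min(floor(nrow(X) / 4), 100L)),
                     residual_tol = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L, max_nonzeros >= 1L,
            residual_tol >= 0)
  assert_finite(X, "X"); assert_finite(y, "y")
  n <- ncol(X)
  ynorm <- sqrt(sum(y^2))
  support <- integer(0)
  values <- numeric(0)
  r <- y
  rnorm_prev <- ynorm
  path <- ynorm
  iter <- 0L
  if (ynorm > 0) repeat {
    if (sqrt(sum(r^2)) <= residual_tol * ynorm) break
    if (length(support) >= max_nonzeros) break
    u <- as.numeric(crossprod(X, r))
    u[support] <- 0
    au <- abs(u)
    cand <- which(au > 1e-12)
    if (!length(cand)) break
    cand <- cand[order(au[cand], decreasing = TRUE)]
    if (length(cand) > max_nonzeros) cand <- cand[seq_len(max_nonzeros)]
    J0 <- regularize_candidates(cand, au[cand])
    room <- max_nonzeros - length(support)
    if (length(J0) > room) J0 <- J0[seq_len(room)]
    new_support <- sort(c(support, J0))
    ls <- stats::lsfit(X[, new_support, drop = FALSE], y, intercept = FALSE)
    w <- unname(ls$coefficients)
    r_new <- ls$residuals
    rnorm_new <- sqrt(sum(r_new^2))
    if (rnorm_new >= rnorm_prev - 1e-12 * max(1, rnorm_prev)) break
    support <- new_support
    values <- w
    r <- r_new
    rnorm_prev <- rnorm_new
    path <- c(path, rnorm_new)
    iter <- iter + 1L
  }
  structure(list(support = support, values = values,
                 n_iterations = iter,
                 residual_norm = sqrt(sum(r^2)),
                 residual_path = path,
                 n_features = n, n_samples = nrow(X)),
            class = "romp_fit")
}

# comparable-magnitude regularization: candidates sorted by decreasing |u|;
# return the contiguous window [i..j] with max(|u|) <= 2 min(|u|) that
# maximizes the energy sum(u^2), indices ordered by decreasing magnitude.
regularize_candidates <- function(cand, au_sorted) {
  k <- length(cand)
  best_e <- -Inf
  best <- integer(0)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && au_sorted[i] <= 2 * au_sorted[j + 1L]) j <- j + 1L
    e <- sum(au_sorted[i:j]^2)
    if (e > best_e + 1e-15) {
      best_e <- e
      best <- cand[i:j]
    }
  }
  best
}

#' @export
print.romp_fit <- function(x, ...) {
  cat("ROMP sparse fit: |support| =", length(x$support),
      "of", x$n_features, "features,",
      x$n_iterations, "iterations, residual norm",
      format(x$residual_norm, digits = 4), "\n")
  if (length(x$support)) {
    cat("support:", paste(x$support, collapse = " "), "\n")
  }
  invisible(x)
}

#' Coefficients of a ROMP fit as a dense n-vector
#' @param object a `romp_fit`.
#' @param ... unused.
#' @export
coef.romp_fit <- function(object, ...) {
  w <- numeric(object$n_features)
  w[object$support] <- object$values
  w
}

#' Predict voxel responses from a sparse encoding fit
#' @param object a `romp_fit`.
#' @param X design matrix with the same feature columns the fit was made on.
#' @param ... unused.
#' @return numeric vector `X[, support] %*% values` (zeros for empty support).
#' @export
predict.romp_fit <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!length(object$support)) return(numeric(nrow(X)))
  if (max(object$support) > ncol(X)) stop("support index out of range for X")
  as.numeric(X[, object$support, drop = FALSE] %*% object$values)
}

#' Residuals of a ROMP fit are summarised by the stored residual norm
#' @param object a `romp_fit`.
#' @param ... unused.
#' @export
residuals.romp_fit <- function(object, ...) object$residual_norm
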