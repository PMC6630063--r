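#' Fit a classical baseline classifier on concatenated area vectors
#'
#' The conventional comparison methods: decision tree, random forest,
#' AdaBoost, and linear / RBF support vector machines, all operating on the
#' flat concatenation of the five areas' voxel vectors. Trees come from
#' \pkg{rpart}, forests from \pkg{randomForest}, SVMs from \pkg{e1071};
#' AdaBoost is the multiclass SAMME scheme over depth-limited \pkg{rpart}
#' trees. AdaBoost and the SVMs are deterministic given fixed data; the
#' stochastic methods are seeded.
#'
#' @param train,val [sequence_set]s.
#' @param kind one of `"decision_tree"`, `"random_forest"`, `"adaboost"`,
#'   `"svm_linear"`, `"svm_rbf"`.
#' @param level label level to decode.
#' @param seed integer seed for the stochastic methods.
#' @return an object of class `classical_model` with the fitted model,
#'   `kind`, `level` and validation accuracy.
#' @export
classical_decoder <- function(train, val = NULL,
                              kind = c("decision_tree", "random_forest",
                                       "adaboost", "svm_linear", "svm_rbf"),
                              level = c("coarse", "mid", "fine"), seed = 1L) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  X <- flatten_sequences(train)
  y <- factor(level_labels(train$labels, level), levels = 0:(n_classes_for(level) - 1L))
  set.seed(child_seed(seed, 9L))
  fit <- switch(kind,
    decision_tree = rpart::rpart(y ~ ., data = data.frame(y = y, X),
                                 method = "class"),
    random_forest = randomForest::randomForest(X, y, ntree = 200L),
    adaboost = fit_samme(X, y, n_rounds = 50L, maxdepth = 3L),
    svm_linear = e1071::svm(X, y, kernel = "linear", scale = FALSE),
    svm_rbf = e1071::svm(X, y, kernel = "radial", scale = FALSE))
  model <- structure(list(fit = fit, kind = kind, level = level, seed = seed,
                          val_accuracy = NA_real_),
                     class = "classical_model")
  if (!is.null(val)) {
    pred <- predict(model, val)
    model$val_accuracy <- accuracy(pred, level_labels(val$labels, level))
  }
  model
}

#' @export
print.classical_model <- function(x, ...) {
  cat("Classical baseline:", x$kind, "(", x$level, "level )\n")
  if (!is.na(x$val_accuracy))
    cat("  validation accuracy:", sprintf("%.4f", x$val_accuracy), "\n")
  invisible(x)
}

#' @rdname predict.brnn_model
#' @export
predict.classical_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "sequence_set")) flatten_sequences(newdata) else as.matrix(newdata)
  pred <- switch(object$kind,
    decision_tree = {
      cls <- predict(object$fit, data.frame(X), type = "class")
      as.integer(as.character(cls))
    },
    random_forest = as.integer(as.character(predict(object$fit, X))),
    adaboost = predict_samme(object$fit, X),
    as.integer(as.character(predict(object$fit, X)))) # both SVMs
  pred
}

# --- SAMME multiclass AdaBoost over rpart trees ----------------------------
# Weighted multiclass exponential-loss boosting: each round fits a tree to the
# weighted sample, earns weight log((1-err)/err) + log(C-1), and sample
# weights are multiplied up on mistakes. Deterministic given fixed data.
fit_samme <- function(X, y, n_rounds = 50L, maxdepth = 3L) {
  n <- nrow(X)
  C <- nlevels(y)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  df <- data.frame(y = y, X)
  for (m in seq_len(n_rounds)) {
    tr <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = maxdepth,
                                                      cp = 0, xval = 0L))
    pred <- predict(tr, df, type = "class")
    miss <- pred != y
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / C) break            # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(C - 1)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err < 1e-10) break                 # perfect tree: done
  }
  list(trees = trees, alphas = alphas, levels = levels(y))
}

predict_samme <- function(model, X) {
  df <- data.frame(X)
  C <- length(model$levels)
  votes <- matrix(0, nrow(X), C)
  for (m in seq_along(model$trees)) {
    pred <- predict(model$trees[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(X)), as.integer(pred))] + model$alphas[m]
  }
  as.integer(model$levels[max.col(votes, ties.method = "first")])
}
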