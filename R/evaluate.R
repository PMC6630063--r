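#' Classification accuracy
#' @param predicted,true equal-length label vectors.
#' @return fraction of exact matches in `[0, 1]`.
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("length mismatch")
  if (!length(predicted)) stop("empty label vectors")
  mean(predicted == true)
}

#' Repeat a training run over several seeds and summarise accuracy
#'
#' The measurement protocol for the stochastic decoders: the same
#' configuration is trained once per seed and the validation accuracies are
#' summarised as mean and sample standard deviation in percent, formatted
#' `"mean ± std"`. Deterministic methods repeat to identical accuracies and
#' report a standard deviation of exactly zero.
#'
#' @param train_fn function taking a single integer seed and returning a
#'   validation accuracy in `[0, 1]` (or an object with `$val_accuracy`).
#' @param seeds integer vector of distinct seeds (default 5 runs).
#' @return object of class `repeated_runs`: `accuracies` (per-seed, percent),
#'   `mean`, `std` (percent), `formatted`, and `single_run` flag when only
#'   one seed was supplied.
#' @export
repeated_runs <- function(train_fn, seeds = 1:5) {
  stopifnot(length(seeds) >= 1L, !anyDuplicated(seeds))
  accs <- vapply(seeds, function(s) {
    out <- tryCatch(train_fn(s), error = function(e)
      stop("run with seed ", s, " failed: ", conditionMessage(e), call. = FALSE))
    a <- if (is.numeric(out)) out else out$val_accuracy
    stopifnot(is.finite(a), a >= 0, a <= 1)
    a
  }, numeric(1)) * 100
  single <- length(accs) == 1L
  std <- if (single) 0 else stats::sd(accs)
  structure(list(accuracies = accs, seeds = seeds,
                 mean = mean(accs), std = std,
                 formatted = sprintf("%.2f ± %.2f", mean(accs), std),
                 single_run = single),
            class = "repeated_runs")
}

#' @export
print.repeated_runs <- function(x, ...) {
  cat("Accuracy over", length(x$seeds), "repeat(s):", x$formatted, "%\n")
  if (x$single_run) cat("  (single run: std reported as 0)\n")
  invisible(x)
}

#' Significance of an accuracy difference between two methods
#'
#' Two-sided Welch two-sample t-test on per-seed accuracies. When one side is
#' deterministic (zero variance), a one-sample t-test of the other side
#' against that constant is used. If both sides are constant the comparison
#' is degenerate: p = 1 when they are equal, p = 0 otherwise, flagged.
#'
#' @param accs_a,accs_b numeric vectors of per-seed accuracies.
#' @return p-value in `[0, 1]`, with attribute `degenerate = TRUE` when no
#'   t-test was possible.
#' @export
significance_test <- function(accs_a, accs_b) {
  stopifnot(length(accs_a) >= 1L, length(accs_b) >= 1L)
  va <- if (length(accs_a) > 1L) stats::var(accs_a) else 0
  vb <- if (length(accs_b) > 1L) stats::var(accs_b) else 0
  if (va == 0 && vb == 0) {
    p <- if (isTRUE(all.equal(mean(accs_a), mean(accs_b)))) 1 else 0
    return(structure(p, degenerate = TRUE))
  }
  if (va == 0) return(stats::t.test(accs_b, mu = accs_a[1L])$p.value)
  if (vb == 0) return(stats::t.test(accs_a, mu = accs_b[1L])$p.value)
  stats::t.test(accs_a, accs_b, var.equal = FALSE)$p.value
}

#' Row-normalized confusion matrix
#'
#' Entry (i, j) estimates `P(predicted = j | true = i)`. Rows with at least
#' one sample sum to 1; rows of classes never observed are left at zero and
#' flagged in the `empty_rows` attribute.
#'
#' @param predicted,true zero-based label vectors.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` matrix with dimnames `true` x `predicted`.
#' @export
normalized_confusion_matrix <- function(predicted, true, n_classes) {
  stopifnot(length(predicted) == length(true),
            all(predicted >= 0), all(predicted < n_classes),
            all(true >= 0), all(true < n_classes))
  counts <- matrix(0, n_classes, n_classes,
                   dimnames = list(true = 0:(n_classes - 1L),
                                   predicted = 0:(n_classes - 1L)))
  for (i in seq_along(true))
    counts[true[i] + 1L, predicted[i] + 1L] <- counts[true[i] + 1L, predicted[i] + 1L] + 1
  support <- rowSums(counts)
  out <- counts
  nz <- support > 0
  out[nz, ] <- counts[nz, , drop = FALSE] / support[nz]
  attr(out, "support") <- support
  attr(out, "empty_rows") <- which(!nz)
  out
}

# canonical method order used in report tables
METHOD_ORDER <- c("decision_tree", "random_forest", "adaboost", "svm_linear",
                  "svm_rbf", "nn", "lstm_forward", "lstm_backward", "brnn")

#' Assemble an evaluation report from repeated-run results
#'
#' Builds the accuracy table (methods x label levels, `"mean ± std"` percent),
#' an optional pairwise significance table, and stores confusion matrices.
#' Methods are ordered decision tree, random forest, AdaBoost, SVMs, NN, then
#' the recurrent models.
#'
#' @param runs named list: `runs[[method]][[level]]` is a [repeated_runs()]
#'   object (levels `"coarse"`, `"mid"`, `"fine"`; any subset).
#' @param comparisons optional data frame with columns `method_a`, `method_b`,
#'   `level`; a Welch test is computed for each row.
#' @param confusions optional named list of confusion matrices.
#' @return object of class `evaluation_report` with `accuracy_table`
#'   (data frame), `significance` (data frame or NULL) and `confusions`.
#' @export
build_report <- function(runs, comparisons = NULL, confusions = NULL) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  methods <- names(runs)
  methods <- methods[order(match(methods, METHOD_ORDER, nomatch = length(METHOD_ORDER) + 1L))]
  levels_present <- unique(unlist(lapply(runs, names)))
  levels_present <- intersect(c("coarse", "mid", "fine"), levels_present)
  tab <- data.frame(method = methods, stringsAsFactors = FALSE)
  for (lv in levels_present)
    tab[[lv]] <- vapply(methods, function(m) {
      r <- runs[[m]][[lv]]
      if (is.null(r)) NA_character_ else r$formatted
    }, character(1))
  sig <- NULL
  if (!is.null(comparisons)) {
    stopifnot(all(c("method_a", "method_b", "level") %in% names(comparisons)))
    sig <- comparisons
    sig$p_value <- vapply(seq_len(nrow(comparisons)), function(i) {
      a <- runs[[comparisons$method_a[i]]][[comparisons$level[i]]]
      b <- runs[[comparisons$method_b[i]]][[comparisons$level[i]]]
      if (is.null(a) || is.null(b)) return(NA_real_)
      as.numeric(significance_test(a$accuracies, b$accuracies))
    }, numeric(1))
  }
  structure(list(accuracy_table = tab, significance = sig,
                 confusions = confusions, runs = runs),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Decoding accuracy (% , mean ± std over repeats):\n")
  print(x$accuracy_table, row.names = FALSE)
  if (!is.null(x$significance)) {
    cat("\nPairwise Welch tests:\n")
    print(x$significance, row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report as delimited text files
#'
#' Emits `accuracy.tsv`, optionally `significance.tsv`, and one plain matrix
#' file `confusion_<name>.tsv` per stored confusion matrix, suitable for
#' external plotting.
#'
#' @param report an [build_report()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$accuracy_table, file.path(dir, "accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$significance))
    utils::write.table(report$significance, file.path(dir, "significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$confusions))
    utils::write.table(report$confusions[[nm]],
                       file.path(dir, paste0("confusion_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read back an accuracy table written by [write_report()]
#' @param dir report directory.
#' @return data frame as written.
#' @export
read_report_table <- function(dir) {
  utils::read.delim(file.path(dir, "accuracy.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}
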