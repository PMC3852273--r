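#' Leave-one-out cross-validation of the promoter SVM
#'
#' Each row of the training matrix (positive and background promoters alike)
#' is held out once; an SVM is fitted on the remaining rows and predicts the
#' held-out promoter. Accuracy is the fraction of rows predicted correctly,
#' reported as a percentage. Defaults: RBF kernel, `C = 1`, kernel width
#' `gamma = 1 / (d * var(features))`.
#'
#' @param tm training-matrix tibble from [build_training_matrix()] (columns
#'   `gene`, `label`, then features)
#' @param kernel `"radial"` or `"linear"`
#' @param cost regularization parameter C (> 0)
#' @param gamma RBF kernel width; `NULL` for the default above
#' @return a `loocv_svm` object: per-row predictions, overall and per-class
#'   accuracy, parameters. See [tidy()] / [glance()].
#' @export
svm_loocv <- function(tm, kernel = c("radial", "linear"), cost = 1,
                      gamma = NULL) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  feats <- setdiff(names(tm), c("gene", "label"))
  X <- as.matrix(tm[feats])
  y <- factor(tm$label, levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2)
    stop("training matrix contains a single class")
  if (any(table(y) < 2))
    stop("need at least 2 rows per class for leave-one-out")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  n <- nrow(X)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- e1071::svm(x = X[-i, , drop = FALSE], y = y[-i], kernel = kernel,
                      cost = cost, gamma = gamma, scale = FALSE)
    pred[i] <- stats::predict(fit, X[i, , drop = FALSE])
  }
  correct <- pred == y
  per_class <- tibble::tibble(
    label = c(1L, 0L),
    n = c(sum(y == 1), sum(y == 0)),
    accuracy = c(100 * mean(correct[y == 1]), 100 * mean(correct[y == 0]))
  )
  structure(list(
    predictions = tibble::tibble(gene = tm$gene, label = as.integer(as.character(y)),
                                 predicted = as.integer(as.character(pred)),
                                 fold = seq_len(n)),
    accuracy = 100 * mean(correct),
    per_class = per_class,
    params = list(kernel = kernel, cost = cost, gamma = gamma)
  ), class = "loocv_svm")
}

#' @export
print.loocv_svm <- function(x, ...) {
  cat("<loocv_svm> n=", nrow(x$predictions), "  accuracy=",
      sprintf("%.1f%%", x$accuracy), "  (", x$params$kernel,
      " kernel, C=", x$params$cost, ")\n", sep = "")
  invisible(x)
}

#' True-positive promoters of a LOOCV run
#'
#' The gene ids of positive-labeled promoters that the cross-validated
#' classifier predicted positive; these are the promoters from which motif
#' patterns are built.
#'
#' @param result a `loocv_svm` object
#' @return character vector of gene ids
#' @export
true_positives <- function(result) {
  stopifnot(inherits(result, "loocv_svm"))
  p <- result$predictions
  p$gene[p$label == 1L & p$predicted == 1L]
}
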