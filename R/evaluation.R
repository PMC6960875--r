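# Leave-one-subject-out cross-validation and recognition/error rates.

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject (folds ordered by subject id): the held-out
#' subject's recordings never enter training — including any PCA fitting
#' or DBA averaging the trainer performs. The per-fold predictions are
#' aggregated into one confusion matrix.
#'
#' @param dataset List of labeled [orientation_sequence] objects with
#'   subject ids.
#' @param trainer Function taking a list of training recordings and
#'   returning a model.
#' @param predictor Function taking `(model, recording)` and returning a
#'   class label. Defaults to `predict(model, recording)`.
#' @return A `loso_report`: list with `confusion` (true class in rows),
#'   `per_class_error`, `per_class_recognition`, `total_error`,
#'   `total_recognition`, and `folds`.
#' @export
loso_cv <- function(dataset, trainer,
                    predictor = function(model, s) predict(model, s)) {
  subjects <- dataset_subjects(dataset)
  labels <- dataset_labels(dataset)
  classes <- sort(unique(labels))
  folds <- sort(unique(subjects))
  if (length(folds) < 2L) stop("LOSO needs at least 2 subjects")
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (fold in folds) {
    train_idx <- subjects != fold
    missing <- setdiff(classes, unique(labels[train_idx]))
    if (length(missing))
      stop(sprintf("training fold for held-out subject %s lacks class(es): %s",
                   fold, paste(missing, collapse = ", ")))
    model <- trainer(dataset[train_idx])
    for (i in which(!train_idx)) {
      pred <- predictor(model, dataset[[i]])
      confusion[labels[i], pred] <- confusion[labels[i], pred] + 1L
    }
  }
  out <- confusion_rates(confusion)
  structure(c(list(confusion = confusion, folds = length(folds)), out),
            class = "loso_report")
}

#' Recognition and error rates from a confusion matrix
#'
#' Per-class recognition is the diagonal entry divided by the row (true
#' class) sum; the error rate is its complement. Total recognition is the
#' trace divided by the grand sum.
#'
#' @param confusion Square numeric matrix, true classes in rows.
#' @return List with `per_class_recognition`, `per_class_error`,
#'   `total_recognition`, `total_error`.
#' @export
confusion_rates <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) < 1L)
    stop("'confusion' must be a non-empty square matrix")
  rs <- rowSums(confusion)
  if (any(rs == 0))
    stop(sprintf("true class '%s' has no observations (zero row sum)",
                 rownames(confusion)[which(rs == 0)[1L]] %||% which(rs == 0)[1L]))
  rec <- diag(confusion) / rs
  total_rec <- sum(diag(confusion)) / sum(confusion)
  list(per_class_recognition = rec,
       per_class_error = 1 - rec,
       total_recognition = total_rec,
       total_error = 1 - total_rec)
}

#' @export
print.loso_report <- function(x, digits = 3, ...) {
  cat(sprintf("<loso_report> %d folds, total recognition %.3f (error %.3f)\n",
              x$folds, x$total_recognition, x$total_error))
  cat("per-class error:\n")
  print(round(x$per_class_error, digits))
  invisible(x)
}

#' Ready-made LOSO benchmarks for the built-in classifiers
#'
#' Convenience wrappers running [loso_cv()] with the package's trainers:
#' `"dtw"` (single template set), `"dtwb"` (per-subject bagged voting),
#' `"pca"` (PCA features + 1-NN), `"pca2"` (two-stage PCA + 1-NN).
#'
#' @param dataset List of labeled [orientation_sequence] objects.
#' @param method One of `"dtw"`, `"dtwb"`, `"pca"`, `"pca2"`.
#' @param ... Extra arguments passed to the trainer (`k`, `L`, `k2`,
#'   `max_iter`, `tol`).
#' @return A `loso_report`.
#' @export
evaluate_loso <- function(dataset, method = c("dtw", "dtwb", "pca", "pca2"), ...) {
  method <- match.arg(method)
  trainer <- switch(method,
    dtw  = function(d) train_dtw(d, ...),
    dtwb = function(d) train_dtw_bagged(d, ...),
    pca  = function(d) train_pca(d, ...),
    pca2 = function(d) train_pca_two_stage(d, ...))
  loso_cv(dataset, trainer)
}
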