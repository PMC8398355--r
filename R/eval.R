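# Evaluation protocol: subject-wise splits, accuracy, confusion matrix,
# feature-mutation statistics (quartile difference, mean absolute deviation,
# sample standard deviation), Pearson correlation analysis, box-plot
# summaries. Quartiles use linear interpolation between order statistics
# (quantile type 7), declared in the report metadata.

#' Partition a dataset by subjects
#'
#' All trials of the listed subjects form the test set; every other
#' subject's trials form the training set, so no subject identity leaks
#' across the partition.
#'
#' @param dataset A `semg_dataset`.
#' @param test_subjects Integer vector of held-out subject ids.
#' @return List with `train` and `test` (both `semg_dataset`s).
#' @export
split_by_subjects <- function(dataset, test_subjects) {
  stopifnot(inherits(dataset, "semg_dataset"))
  subjects <- unique(dataset$trials$subject)
  if (length(test_subjects) == 0) stop("test subject set is empty", call. = FALSE)
  if (!all(test_subjects %in% subjects)) {
    stop("unknown subject id(s): ",
         paste(setdiff(test_subjects, subjects), collapse = ", "), call. = FALSE)
  }
  if (all(subjects %in% test_subjects)) {
    stop("training partition is empty", call. = FALSE)
  }
  take <- function(keep) {
    out <- dataset
    out$trials <- dataset$trials[keep, , drop = FALSE]
    out
  }
  in_test <- dataset$trials$subject %in% test_subjects
  list(train = take(!in_test), test = take(in_test))
}

#' Classification accuracy in percent
#'
#' @param predictions,labels Equal-length label vectors.
#' @return `100 * correct / total`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0) stop("empty input", call. = FALSE)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  100 * mean(predictions == labels)
}

#' Confusion matrix of true vs predicted classes
#'
#' Entry (i, j) counts samples of true class i predicted as class j, so
#' `sum(diag(cm)) / sum(cm)` equals `accuracy / 100`.
#'
#' @param predictions,labels Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return `[n_classes x n_classes]` integer matrix.
#' @export
confusion <- function(predictions, labels, n_classes = 12) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  if (any(c(predictions, labels) < 1) || any(c(predictions, labels) > n_classes)) {
    stop("labels out of range 1..", n_classes, call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels)) {
    cm[labels[i], predictions[i]] <- cm[labels[i], predictions[i]] + 1L
  }
  dimnames(cm) <- list(true = seq_len(n_classes), predicted = seq_len(n_classes))
  cm
}

#' Quartile difference (Q3 - Q1)
#'
#' @param x Numeric vector, `n >= 4`.
#' @return Interquartile range under the type-7 quantile convention.
#' @export
qd <- function(x) {
  if (length(x) < 4) stop("qd needs at least 4 values", call. = FALSE)
  unname(stats::quantile(x, 0.75, type = 7) - stats::quantile(x, 0.25, type = 7))
}

#' Mean absolute deviation from the mean
#'
#' @param x Numeric vector, `n >= 2`.
#' @return `sum(|x_i - mean(x)|) / n`.
#' @export
md <- function(x) {
  if (length(x) < 2) stop("md needs at least 2 values", call. = FALSE)
  mean(abs(x - mean(x)))
}

#' Sample standard deviation
#'
#' `sqrt(sum((x_i - mean(x))^2) / (n - 1))`, implemented as the formula is
#' written.
#'
#' @param x Numeric vector, `n >= 2`.
#' @return Scalar standard deviation.
#' @export
stdev <- function(x) {
  if (length(x) < 2) stop("stdev needs at least 2 values", call. = FALSE)
  sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}

#' Pearson correlation matrix of per-class feature vectors
#'
#' Computes `cov(X, Y) / (sd(X) sd(Y))` for every pair of class feature
#' vectors; symmetric, unit diagonal, entries in \[-1, 1\]. A constant vector
#' makes the correlation undefined and raises an error.
#'
#' @param class_features List of equal-length numeric vectors (one per
#'   class), or a matrix with one column per class.
#' @return `[K x K]` correlation matrix.
#' @export
correlation_matrix <- function(class_features) {
  m <- if (is.matrix(class_features)) class_features
       else do.call(cbind, class_features)
  if (nrow(m) < 2) stop("feature vectors need length >= 2", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("correlation undefined for constant feature vector(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  k <- ncol(m)
  centered <- sweep(m, 2, colMeans(m))
  cv <- crossprod(centered) / (nrow(m) - 1)
  rho <- cv / tcrossprod(sds)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

#' Tukey box-plot statistics with outlier flags
#'
#' @param x Numeric vector, `n >= 5`.
#' @return List with `min`, `q1`, `median`, `q3`, `max` (data extremes and
#'   type-7 quartiles) and `outliers` (values beyond the 1.5 x IQR fences).
#' @export
five_number_summary <- function(x) {
  if (length(x) < 5) stop("five_number_summary needs at least 5 values",
                          call. = FALSE)
  q1 <- unname(stats::quantile(x, 0.25, type = 7))
  q3 <- unname(stats::quantile(x, 0.75, type = 7))
  iqr <- q3 - q1
  list(min = min(x), q1 = q1, median = unname(stats::median(x)), q3 = q3,
       max = max(x), outliers = x[x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr])
}

#' The ten subject-pair test rosters used for head-to-head evaluation
#'
#' @return List of ten length-2 integer vectors of held-out subject pairs
#'   drawn from subjects 1--10.
#' @export
subject_pair_splits <- function() {
  list(c(1L, 2L), c(3L, 4L), c(5L, 9L), c(6L, 10L), c(3L, 9L),
       c(1L, 4L), c(7L, 10L), c(2L, 5L), c(6L, 7L), c(7L, 9L))
}
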