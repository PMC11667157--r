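#' Train/test split specification
#'
#' A seeded shuffle of the whole dataset followed by a 75-25 partition
#' (the training set gets `floor(train_fraction * n)` samples). The
#' shuffle is non-stratified by default; `stratified = TRUE` applies the
#' same fraction within each class.
#'
#' @param train_fraction fraction of samples assigned to training,
#'   in (0, 1).
#' @param shuffle_seed RNG seed of the shuffle (default 42).
#' @param stratified split within classes.
#' @return A `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.75, shuffle_seed = 42L,
                       stratified = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1")
  structure(list(train_fraction = train_fraction,
                 shuffle_seed = as.integer(shuffle_seed),
                 stratified = stratified),
            class = "split_spec")
}

#' Deterministic train/test partition
#'
#' @param y class labels (used for stratification and to check that no
#'   class is emptied); the split itself returns indices, so any data
#'   container can be subset with the result.
#' @param spec a [split_spec()].
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(y, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  y <- factor(y)
  n <- length(y)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$shuffle_seed)
  if (spec$stratified) {
    if (any(table(y) < 2)) stop("need >= 2 samples per class to stratify")
    train <- integer(0)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      train <- c(train, idx[seq_len(floor(spec$train_fraction *
                                          length(idx)))])
    }
    train <- sort(train)
  } else {
    ord <- sample.int(n)
    train <- sort(ord[seq_len(floor(spec$train_fraction * n))])
  }
  test <- setdiff(seq_len(n), train)
  if (length(unique(y[train])) < nlevels(y) ||
      length(unique(y[test])) < nlevels(y))
    stop("a class is absent from one side of the split")
  list(train = train, test = test)
}

#' Mean of per-subject accuracy rates
#'
#' The headline accuracy is the unweighted mean of per-subject rates
#' `R_i / S_i` (in percent), not the pooled rate; subjects with few
#' trials weigh as much as subjects with many. See
#' [pooled_accuracy()] for the pooled-count variant.
#'
#' @param per_subject data.frame (or 2-column matrix) with correct
#'   counts `R` and totals `S`, one row per subject.
#' @return Mean accuracy in percent.
#' @export
average_accuracy <- function(per_subject) {
  per_subject <- as.data.frame(per_subject)
  names(per_subject)[1:2] <- c("R", "S")
  if (nrow(per_subject) == 0) stop("empty per-subject table")
  if (any(per_subject$S <= 0)) stop("subject totals must be positive")
  mean(per_subject$R / per_subject$S) * 100
}

#' Pooled accuracy over subjects
#' @inheritParams average_accuracy
#' @return `sum(R) / sum(S)` in percent.
#' @export
pooled_accuracy <- function(per_subject) {
  per_subject <- as.data.frame(per_subject)
  names(per_subject)[1:2] <- c("R", "S")
  if (nrow(per_subject) == 0) stop("empty per-subject table")
  sum(per_subject$R) / sum(per_subject$S) * 100
}

#' Cohen's kappa against a fixed chance rate
#'
#' `kappa = (Po - Pe) / (1 - Pe)`. For the balanced binary imagery task
#' the chance rate Pe is fixed at 0.5, which makes
#' `kappa = 2 * accuracy - 1`.
#'
#' @param po observed accuracy, fraction in \[0, 1\].
#' @param pe chance rate, fraction below 1.
#' @return Kappa value.
#' @export
cohen_kappa <- function(po, pe = 0.5) {
  if (pe >= 1) stop("pe must be < 1")
  (po - pe) / (1 - pe)
}

#' Confusion matrix of labeled predictions
#'
#' Rows are the actual classes, columns the predicted classes.
#'
#' @param labels,predictions factors (or vectors coercible to factors
#'   with common levels), equal length.
#' @param normalize return row-normalized proportions instead of counts.
#' @return K x K matrix with class dimnames.
#' @export
confusion_matrix <- function(labels, predictions, normalize = FALSE) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  lev <- union(levels(factor(labels)), levels(factor(predictions)))
  cm <- table(actual = factor(labels, levels = lev),
              predicted = factor(predictions, levels = lev))
  cm <- unclass(cm)
  if (normalize) {
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    cm <- cm / rs
  }
  cm
}

#' Recall, precision and F1 from a confusion matrix
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F1 = 2 * precision * recall / (precision + recall)` for the given
#' positive class. F1 is defined as 0 when precision + recall = 0.
#' When the data contain no positive samples, recall (and F1) are
#' returned as `NaN` rather than silently zero.
#'
#' @param confusion K x K count matrix (rows actual, columns predicted).
#' @param positive_class row/column name or index of the positive class.
#' @return list with `recall`, `precision`, `f1`.
#' @export
recall_f1 <- function(confusion, positive_class = 1L) {
  confusion <- as.matrix(confusion)
  if (is.character(positive_class))
    positive_class <- match(positive_class, rownames(confusion))
  tp <- confusion[positive_class, positive_class]
  fn <- sum(confusion[positive_class, ]) - tp
  fp <- sum(confusion[, positive_class]) - tp
  recall <- if (tp + fn == 0) NaN else tp / (tp + fn)
  precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
  f1 <- if (is.nan(recall)) NaN
        else if (isTRUE(precision + recall == 0) || is.nan(precision)) 0
        else 2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f1 = f1)
}

#' Full metrics report for a labeled prediction set
#'
#' @param labels,predictions equal-length class vectors.
#' @param positive_class positive class for recall/precision/F1
#'   (default: the first factor level, i.e. `left_fist` for the default
#'   alphabetic ordering).
#' @param pe chance rate for kappa.
#' @param per_subject optional data.frame with columns `R`, `S` of
#'   per-subject correct counts and totals; adds the mean-of-rates
#'   accuracy and a mean per-subject kappa.
#' @return A `metrics_report` list: accuracy (fraction), kappa, recall,
#'   precision, f1, confusion (counts), and optionally
#'   `average_accuracy` / `mean_subject_kappa`.
#' @export
metrics_report <- function(labels, predictions, positive_class = NULL,
                           pe = 0.5, per_subject = NULL) {
  cm <- confusion_matrix(labels, predictions)
  acc <- sum(diag(cm)) / sum(cm)
  pos <- positive_class %||% rownames(cm)[1]
  rf <- recall_f1(cm, pos)
  rep_ <- list(accuracy = acc, kappa = cohen_kappa(acc, pe),
               recall = rf$recall, precision = rf$precision, f1 = rf$f1,
               confusion = cm, positive_class = pos)
  if (!is.null(per_subject)) {
    rep_$average_accuracy <- average_accuracy(per_subject)
    rep_$mean_subject_kappa <-
      mean(cohen_kappa(per_subject$R / per_subject$S, pe))
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.2f%%  kappa %.3f  ",
                     "recall %.3f  F1 %.3f (positive: %s)\n"),
              100 * x$accuracy, x$kappa, x$recall, x$f1, x$positive_class))
  print(x$confusion)
  invisible(x)
}
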