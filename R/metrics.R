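#' Rank-based AUC (Mann-Whitney, ties counted one half)
#'
#' @param labels Binary 0/1 labels with both classes present.
#' @param probabilities Numeric scores.
#' @return The area under the ROC curve.
#' @export
auc_score <- function(labels, probabilities) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("AUC is undefined: labels contain a single class")
  r <- rank(probabilities)  # average ranks implement the 0.5 tie convention
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from labels and predicted probabilities
#'
#' Thresholds the probabilities and computes precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, accuracy `(TN+TP)/n`, `F1 = 2TP/(2TP+FP+FN)` and
#' the rank-based AUC. A zero precision denominator yields 0 with a
#' warning; with a single label class the AUC is returned as `NA` with a
#' warning (the threshold metrics are still computed).
#'
#' @param labels Binary 0/1 labels.
#' @param probabilities Predicted probabilities in [0, 1].
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `precision`, `recall`, `accuracy`, `f1`, `auc`, and
#'   the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as.integer(labels)
  stopifnot(length(y) == length(probabilities), all(y %in% c(0L, 1L)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) {
    warning("precision undefined (no positive predictions); returning 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(y)) < 2L) {
    warning("AUC undefined: labels contain a single class")
    NA_real_
  } else auc_score(y, probabilities)
  list(precision = precision, recall = recall,
       accuracy = (tn + tp) / length(y), f1 = f1, auc = auc,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Confusion-count metrics
#'
#' Convenience wrapper computing the threshold metrics directly from a
#' confusion table.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return Named list `precision`, `recall`, `accuracy`, `f1`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  list(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn),
       accuracy = (tn + tp) / (tn + tp + fn + fp),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}
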