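#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC, equal to the probability that a
#' random positive outscores a random negative, with ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: test set has a single class")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over distinct score thresholds (precision at
#' each achieved recall level, recall-weighted sum), matching the
#' standard average-precision construction.
#'
#' @inheritParams auc_score
#' @return AUPR in `[0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("AUPR undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for a scored test set
#'
#' AUC, AUPR and thresholded accuracy / precision / recall / F1 for a
#' vector of pair scores with binary labels (held-out positives = 1,
#' held-out unknowns = 0).
#'
#' @param scores numeric scores in (0, 1).
#' @param labels 0/1 labels.
#' @param threshold classification threshold for the thresholded
#'   metrics (default 0.5).
#' @return one-row data frame with columns `auc`, `aupr`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1, length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(auc = auc_score(scores, labels),
             aupr = aupr_score(scores, labels),
             accuracy = (tp + tn) / length(labels),
             precision = precision, recall = recall, f1 = f1)
}
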