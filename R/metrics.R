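#' @include AllClasses.R
NULL

#' Ranking and threshold metrics for binary prediction
#'
#' AUROC is computed from the rank statistic (equivalent to the normalized
#' Mann-Whitney U; tied scores count 1/2).  AUPR integrates the
#' precision-recall step curve over distinct score thresholds.  Accuracy,
#' precision, recall and F1 use the classification threshold (default 0.5);
#' precision and F1 are defined as 0 when their denominators vanish.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @param threshold classification threshold for the confusion metrics.
#' @return named list: `auroc`, `aupr`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @examples
#' evaluateScores(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores and labels must align")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("labels must contain both classes")
  r <- rank(scores)                      # midranks handle ties as 1/2
  auroc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  last <- !duplicated(s, fromLast = TRUE) # last row of each tied-score block
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= threshold)
  tp2 <- sum(pred == 1L & labels == 1L)
  fp2 <- sum(pred == 1L & labels == 0L)
  fn2 <- sum(pred == 0L & labels == 1L)
  accuracy <- mean(pred == labels)
  precision <- if (tp2 + fp2 > 0) tp2 / (tp2 + fp2) else 0
  recall <- tp2 / nPos
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(auroc = auroc, aupr = aupr, accuracy = accuracy,
       precision = precision, recall = recall, f1 = f1)
}
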