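#' @include metrics.R
NULL

#' Train a pair classifier on refined features
#'
#' Random forest (the default: 500 trees, sqrt-features per split, Gini
#' impurity splitting), logistic regression and RBF-kernel SVM with
#' probability calibration are provided behind one interface; all expose
#' probability scores in \[0, 1\] via [predictScores()].
#'
#' @param X numeric feature matrix (one row per pair node).
#' @param y 0/1 labels; both classes must be present.
#' @param kind `"rf"` (default), `"lr"` or `"svm"`.
#' @param seed RNG seed (tree growing / SVM cross-validation folds).
#' @param ntree random forest size (default 500).
#' @return an object of class `"dtiClassifier"`.
#' @export
trainClassifier <- function(X, y, kind = c("rf", "lr", "svm"), seed = 1,
                            ntree = 500) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("labels must contain both classes")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- withSeed(seed, switch(
    kind,
    rf = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = ntree),
    lr = {
      df <- data.frame(y = y, X)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                     probability = TRUE)
  ))
  structure(list(kind = kind, fit = fit, seed = seed),
            class = "dtiClassifier")
}

#' Probability scores from a trained pair classifier
#'
#' @param model a `"dtiClassifier"` from [trainClassifier()].
#' @param X feature matrix.
#' @return numeric vector of interaction probabilities in \[0, 1\].
#' @export
predictScores <- function(model, X) {
  stopifnot(inherits(model, "dtiClassifier"))
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(model$kind,
    rf = unname(predict(model$fit, X, type = "prob")[, "1"]),
    lr = unname(predict(model$fit, data.frame(X), type = "response")),
    svm = {
      p <- predict(model$fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    })
}

#' Rank candidate pairs by predicted interaction score
#'
#' Orders candidates by descending score with a stable lexicographic
#' tie-break on (drug id, target id).
#'
#' @param model a `"dtiClassifier"`.
#' @param X feature matrix aligned with `pairs`.
#' @param pairs data.frame with columns `drug` and `target` (and optionally
#'   `label` for a known-interaction flag).
#' @param topK keep only the first `topK` rows (default all; a request
#'   larger than the candidate set returns the full list).
#' @return data.frame with `rank`, `drug`, `target`, `score` and, when
#'   available, `known`.
#' @export
rankPredictions <- function(model, X, pairs, topK = Inf) {
  scores <- predictScores(model, X)
  ord <- order(-scores, pairs$drug, pairs$target)
  out <- data.frame(rank = seq_along(ord), drug = pairs$drug[ord],
                    target = pairs$target[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(pairs$label)) out$known <- as.integer(pairs$label[ord])
  head(out, n = min(topK, nrow(out)))
}
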