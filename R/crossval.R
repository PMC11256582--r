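#' @include classify.R graphsage.R
NULL

#' Stratified fold plan
#'
#' Positives and negatives are each divided into `nFolds` near-equal parts
#' (sizes differ by at most one within each class), so every fold's
#' positive:negative ratio is within one sample of the global ratio.  The
#' assignment is keyed by node id: permuting the input order under the same
#' seed yields the same id-to-fold mapping.
#'
#' @param ids node identifiers (unique).
#' @param labels 0/1 labels aligned with `ids`.
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer fold assignment (1..nFolds) aligned with `ids`.
#' @export
foldPlan <- function(ids, labels, nFolds = 5, seed = 1) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(ids) != length(labels)) stop("ids and labels must align")
  assign <- integer(length(ids))
  ord <- order(ids)
  withSeed(seed, {
    for (cls in c(1L, 0L)) {
      members <- ord[labels[ord] == cls]
      if (length(members) < nFolds)
        stop("class ", cls, " has fewer members than folds")
      shuffled <- members[sample(length(members))]
      q <- length(members) %/% nFolds
      r <- length(members) %% nFolds
      sizes <- rep(q, nFolds) + c(rep(1L, r), rep(0L, nFolds - r))
      assign[shuffled] <- rep(seq_len(nFolds), sizes)
    }
  })
  assign
}

.foldMetricsRow <- function(metrics, fold) {
  data.frame(fold = fold, auroc = metrics$auroc, aupr = metrics$aupr,
             accuracy = metrics$accuracy, precision = metrics$precision,
             recall = metrics$recall, f1 = metrics$f1)
}

#' Cross-validated pair classification on the implicit pair network
#'
#' Fivefold (by default) stratified cross-validation of the
#' GraphSAGE-plus-classifier stage.  In `"per-fold"` mode (default) the
#' GraphSAGE is retrained inside every fold on the training nodes only, so
#' no test label can leak into the refined representation; `"shared"` mode
#' trains it once on all sampled nodes (faster, transductive, closer to
#' common practice but optimistic) before cross-validating the classifier.
#' The mean over folds is the reported metric.
#'
#' @param index a [DTPIndex-class].
#' @param drugEmbeddings,targetEmbeddings [EmbeddingMatrix-class] objects.
#' @param sample balanced node sample from [sampleBalanced()] (columns
#'   `pairId`, `drug`, `target`, `label`).
#' @param sageCfg a [SageConfig-class].
#' @param classifier `"rf"`, `"lr"` or `"svm"`.
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed for fold planning and per-fold child seeds.
#' @param sageMode `"per-fold"` or `"shared"`.
#' @param permuteLabels permute the sample labels before fold planning
#'   (label-permutation null control; default FALSE).
#' @return list with `report` (an [EvalReport-class]), `folds` (assignment)
#'   and `scores` (out-of-fold scores aligned with `sample`).
#' @export
crossValidate <- function(index, drugEmbeddings, targetEmbeddings, sample,
                          sageCfg = sageConfig(), classifier = "rf",
                          nFolds = 5, seed = 1,
                          sageMode = c("per-fold", "shared"),
                          permuteLabels = FALSE) {
  sageMode <- match.arg(sageMode)
  ids <- sample$pairId
  labels <- as.integer(sample$label)
  if (permuteLabels)
    labels <- withSeed(childSeed(seed, 99), base::sample(labels))
  folds <- foldPlan(ids, labels, nFolds = nFolds, seed = seed)
  oof <- numeric(length(ids))
  rows <- vector("list", nFolds)

  sharedFeats <- NULL
  if (sageMode == "shared") {
    cfg <- sageCfg
    cfg@seed <- childSeed(seed, 1)
    model <- sageTrain(index, drugEmbeddings, targetEmbeddings, ids, labels,
                       cfg, neighborUniverse = ids)
    sharedFeats <- sageRefine(model, index, drugEmbeddings, targetEmbeddings,
                              ids, seed = childSeed(seed, 2),
                              neighborUniverse = ids)$features
  }

  for (f in seq_len(nFolds)) {
    isTest <- folds == f
    if (length(unique(labels[!isTest])) < 2L ||
        length(unique(labels[isTest])) < 2L)
      stop("fold ", f, " does not contain both classes")
    if (sageMode == "per-fold") {
      cfg <- sageCfg
      cfg@seed <- childSeed(seed, 10 + f)
      model <- sageTrain(index, drugEmbeddings, targetEmbeddings,
                         ids[!isTest], labels[!isTest], cfg,
                         neighborUniverse = ids[!isTest])
      feats <- sageRefine(model, index, drugEmbeddings, targetEmbeddings,
                          ids, seed = childSeed(seed, 30 + f),
                          neighborUniverse = ids)$features
    } else {
      feats <- sharedFeats
    }
    clf <- trainClassifier(feats[!isTest, , drop = FALSE], labels[!isTest],
                           kind = classifier, seed = childSeed(seed, 50 + f))
    sc <- predictScores(clf, feats[isTest, , drop = FALSE])
    oof[isTest] <- sc
    rows[[f]] <- .foldMetricsRow(evaluateScores(sc, labels[isTest]), f)
  }
  foldDf <- do.call(rbind, rows)
  report <- new("EvalReport", folds = foldDf, classifier = classifier,
                configHash = rlang::hash(list(sageCfg, classifier, nFolds,
                                              seed, sageMode, permuteLabels)))
  list(report = report, folds = folds, scores = oof, labels = labels)
}

#' Repeated random-split evaluation of classifiers on fixed features
#'
#' Randomly splits the data `nRepeats` times into a training fraction
#' (default 75%) and a validation remainder, stratified by class, and
#' averages the metrics over repeats.  Used to compare classifiers on the
#' same refined pair features.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param classifier `"rf"`, `"lr"` or `"svm"`.
#' @param nRepeats number of random splits (default 50).
#' @param trainFrac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return an [EvalReport-class] with one row per repeat.
#' @export
repeatedSplitEval <- function(X, y, classifier = "rf", nRepeats = 50,
                              trainFrac = 0.75, seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  rows <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    isTrain <- withSeed(childSeed(seed, r), {
      tr <- logical(length(y))
      for (cls in c(0L, 1L)) {
        members <- which(y == cls)
        nTr <- max(1L, round(trainFrac * length(members)))
        tr[base::sample(members, nTr)] <- TRUE
      }
      tr
    })
    clf <- trainClassifier(X[isTrain, , drop = FALSE], y[isTrain],
                           kind = classifier, seed = childSeed(seed, 1000 + r))
    sc <- predictScores(clf, X[!isTrain, , drop = FALSE])
    rows[[r]] <- .foldMetricsRow(evaluateScores(sc, y[!isTrain]), r)
  }
  new("EvalReport", folds = do.call(rbind, rows), classifier = classifier,
      configHash = rlang::hash(list(classifier, nRepeats, trainFrac, seed)))
}
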