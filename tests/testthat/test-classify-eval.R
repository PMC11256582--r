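test_that("all three classifiers fit a separable toy perfectly", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, mean = 3), 30, 2),
             matrix(rnorm(60, mean = -3), 30, 2))
  y <- rep(c(1, 0), each = 30)
  for (kind in c("rf", "lr", "svm")) {
    m <- trainClassifier(X, y, kind = kind, seed = 2)
    sc <- predictScores(m, X)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(mean((sc > 0.5) == (y == 1)), 1)
  }
  expect_error(trainClassifier(X, rep(1, 60), "rf"), "both classes")
})

test_that("seeded random forests are reproducible", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, 0.5)
  m1 <- trainClassifier(X, y, "rf", seed = 5)
  m2 <- trainClassifier(X, y, "rf", seed = 5)
  expect_identical(predictScores(m1, X), predictScores(m2, X))
})

test_that("random forest beats logistic regression on XOR structure", {
  set.seed(13)
  n <- 240
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- as.integer(X[, 1] * X[, 2] > 0)          # non-linear parity labels
  half <- seq_len(n / 2)
  rf <- trainClassifier(X[half, ], y[half], "rf", seed = 1)
  lr <- trainClassifier(X[half, ], y[half], "lr", seed = 1)
  aucRf <- evaluateScores(predictScores(rf, X[-half, ]), y[-half])$auroc
  aucLr <- evaluateScores(predictScores(lr, X[-half, ]), y[-half])$auroc
  expect_gt(aucRf, aucLr)
  expect_gt(aucRf, 0.9)
})

test_that("ranking metrics match their oracles and edge cases", {
  perfect <- evaluateScores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)
  reversed <- evaluateScores(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(reversed$auroc, 0)
  ex <- evaluateScores(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(ex$auroc, 3 / 4)
  expect_equal(ex$auroc, aurocOracle(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)))
  expect_error(evaluateScores(c(1, 0), c(1, 1)), "both classes")
})

test_that("AUROC equals Mann-Whitney pair counting on random inputs", {
  set.seed(29)
  for (rep in 1:6) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    got <- evaluateScores(scores, y)$auroc
    expect_equal(got, aurocOracle(scores, y), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(got,
                   as.numeric(pROC::auc(y, scores, direction = "<",
                                        quiet = TRUE)),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold metrics handle degenerate predictions", {
  m <- evaluateScores(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1), threshold = 0.9)
  expect_equal(m$precision, 0)    # no positive predictions
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$accuracy, 0.5)
})

test_that("fold plans stratify both classes to within one sample", {
  ids <- seq_len(1923 + 1923)
  labels <- rep(c(1, 0), c(1923, 1923))
  f <- foldPlan(ids, labels, nFolds = 5, seed = 3)
  posSizes <- table(f[labels == 1])
  expect_identical(sort(as.integer(posSizes)), c(384L, 384L, 385L, 385L, 385L))
  ratio <- table(f, labels)
  expect_true(all(abs(ratio[, "0"] - ratio[, "1"]) <= 1))

  # assignment is keyed by id: shuffling the input order changes nothing
  perm <- sample(length(ids))
  f2 <- foldPlan(ids[perm], labels[perm], nFolds = 5, seed = 3)
  expect_identical(f2[order(ids[perm])], f[order(ids)])
})

test_that("repeated random splits report one row per repeat", {
  set.seed(6)
  X <- rbind(matrix(rnorm(80, 2), 40, 2), matrix(rnorm(80, -2), 40, 2))
  y <- rep(c(1, 0), each = 40)
  rep5 <- repeatedSplitEval(X, y, classifier = "lr", nRepeats = 5, seed = 2)
  expect_equal(nrow(reportFolds(rep5)), 5)
  expect_true(all(reportMeans(rep5) >= 0 & reportMeans(rep5) <= 1))
  expect_gt(reportMeans(rep5)["auroc"], 0.95)
})

test_that("prediction ranking is score-descending with lexicographic ties", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- rep(c(1, 0), each = 20)
  m <- trainClassifier(X, y, "rf", seed = 1)
  pairs <- data.frame(drug = rep(paste0("D", 1:8), 5),
                      target = rep(paste0("T", 1:5), each = 8),
                      label = y)
  rk <- rankPredictions(m, X, pairs)
  expect_true(all(diff(rk$score) <= 0))
  # known positives dominate the top of the list on a fitted toy
  expect_gte(mean(rk$known[1:10]), 0.9)
  expect_equal(nrow(rankPredictions(m, X, pairs, topK = 1e6)), 40)

  flat <- structure(list(kind = "lr",
                         fit = suppressWarnings(glm(y ~ 1, family = binomial(),
                                                    data = data.frame(y = y))),
                         seed = 1), class = "dtiClassifier")
  rkFlat <- rankPredictions(flat, X, pairs)
  expect_identical(rkFlat$drug, pairs$drug[order(pairs$drug, pairs$target)])
})

test_that("test-fold labels cannot leak into training-fold scores", {
  b <- generateSyntheticData(synthConfig(nDrugs = 15, nTargets = 18,
                                         seqLength = 40, seed = 9))
  idx <- DTPIndex(b$drugIds, b$targetIds)
  lab <- dtpLabelsFromInteractions(idx, b$interactions)
  smp <- sampleBalanced(lab, idx, seed = 3)
  de <- randomEmbedding(b$drugIds, 6, seed = 1)
  te <- randomEmbedding(b$targetIds, 6, seed = 2)
  folds <- foldPlan(smp$pairId, smp$label, nFolds = 3, seed = 5)
  isTest <- folds == 1
  cfg <- sageConfig(fanouts = c(5, 3), epochs = 2, seed = 7)

  runTrainScores <- function(labels) {
    m <- sageTrain(idx, de, te, smp$pairId[!isTest], labels[!isTest], cfg)
    r <- sageRefine(m, idx, de, te, smp$pairId, seed = 11)
    clf <- trainClassifier(r$features[!isTest, ], labels[!isTest], "rf",
                           seed = 13)
    predictScores(clf, r$features[!isTest, ])
  }
  base <- smp$label
  permuted <- base
  set.seed(99)
  permuted[isTest] <- sample(base[isTest])
  expect_identical(runTrainScores(base), runTrainScores(permuted))
})

test_that("cross-validation isolates folds and averages their metrics", {
  b <- generateSyntheticData(synthConfig(nDrugs = 16, nTargets = 20,
                                         seqLength = 40, seed = 12))
  idx <- DTPIndex(b$drugIds, b$targetIds)
  lab <- dtpLabelsFromInteractions(idx, b$interactions)
  smp <- sampleBalanced(lab, idx, seed = 4)
  de <- randomEmbedding(b$drugIds, 6, seed = 3)
  dm <- as.matrix(de) + 2 * b$clusters$drug[b$drugIds]
  de <- new("EmbeddingMatrix", vectors = dm)
  te <- randomEmbedding(b$targetIds, 6, seed = 4)
  tm <- as.matrix(te) + 2 * b$clusters$target[b$targetIds]
  te <- new("EmbeddingMatrix", vectors = tm)
  cfg <- sageConfig(fanouts = c(8, 4), epochs = 2, seed = 6)
  cv <- crossValidate(idx, de, te, smp, cfg, classifier = "rf", nFolds = 3,
                      seed = 8)
  f <- reportFolds(cv$report)
  expect_equal(nrow(f), 3)
  expect_equal(unname(reportMeans(cv$report)["auroc"]), mean(f$auroc))
  expect_gt(reportMeans(cv$report)["auroc"], 0.7)   # planted signal recovered
  # shared-embedding mode runs and reports the same shape
  cvS <- crossValidate(idx, de, te, smp, cfg, nFolds = 3, seed = 8,
                       sageMode = "shared")
  expect_equal(nrow(reportFolds(cvS$report)), 3)
})
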