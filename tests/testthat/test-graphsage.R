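test_that("neighborhood sampling builds valid layered trees", {
  idx <- DTPIndex(paste0("D", 1:3), paste0("T", 1:3))
  tree <- sampleNeighborhood(idx, u = 4, fanouts = c(2, 1), seed = 3)
  expect_length(tree$layers[[1]], 2)
  expect_equal(dim(tree$layers[[2]]), c(2L, 1L))
  # 1 root + 2 + 2 nodes, every parent-child link an edge of the pair network
  expect_true(all(dtpAdjacent(idx, 4, as.vector(tree$layers[[1]])) == 1))
  for (r in 1:2)
    expect_true(all(dtpAdjacent(idx, tree$layers[[1]][r],
                                tree$layers[[2]][r, ]) == 1))
  # degree (= 4) >= fanout: sampling is without replacement, all distinct
  t2 <- sampleNeighborhood(idx, 0, fanouts = c(4, 2), seed = 5)
  expect_length(unique(as.vector(t2$layers[[1]])), 4)
  expect_identical(sampleNeighborhood(idx, 4, c(2, 1), seed = 3), tree)
})

test_that("mean aggregation is an arithmetic mean, order-invariant", {
  expect_equal(aggregateMean(list(c(1, 3), c(3, 5))), c(2, 4))
  expect_equal(aggregateMean(list(c(7, 1))), c(7, 1))
  set.seed(12)
  m <- matrix(rnorm(400), 50, 8)
  expect_equal(aggregateMean(m), colSums(m) / 50, tolerance = 1e-12)
  perm <- m[sample(50), ]
  expect_equal(aggregateMean(perm), aggregateMean(m), tolerance = 1e-12)
  expect_error(aggregateMean(list()), "at least one")
})

test_that("the layer update is a nonlinear transform of the concatenation", {
  W <- cbind(diag(2), matrix(0, 2, 2))
  expect_equal(layerUpdate(c(1, 2), c(3, 4), W), c(1, 2))
  expect_equal(layerUpdate(c(0, 0), c(0, 0), W), c(0, 0))
  set.seed(9)
  W2 <- matrix(rnorm(12), 3, 4)
  hs <- rnorm(2); hn <- rnorm(2)
  expect_equal(layerUpdate(hs, hn, W2, "identity"),
               as.vector(W2 %*% c(hs, hn)), tolerance = 1e-10)
  expect_equal(layerUpdate(hs, hn, W2),
               pmax(as.vector(W2 %*% c(hs, hn)), 0), tolerance = 1e-10)
  expect_error(layerUpdate(c(1, 2), c(3), W2), "columns")
})

test_that("cross-entropy matches its closed form and a scalar-loop oracle", {
  expect_lt(crossEntropy(1, 1 - 1e-9), 1e-8)
  expect_equal(crossEntropy(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  # each term improves as its prediction moves toward the label
  expect_lt(crossEntropy(c(1, 0), c(0.7, 0.5)), crossEntropy(c(1, 0), c(0.6, 0.5)))
  set.seed(14)
  y <- rbinom(40, 1, 0.5)
  p <- runif(40, 0.01, 0.99)
  loop <- 0
  for (i in seq_along(y)) loop <- loop - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(crossEntropy(y, p), loop / 40, tolerance = 1e-12)
  expect_error(crossEntropy(c(1, 0), 0.5), "length")
})

test_that("batched forward equals naive recursion under full fanout", {
  idx <- DTPIndex(paste0("D", 1:3), paste0("T", 1:4))   # 12 nodes, degree 5
  de <- randomEmbedding(drugIds(idx), 4, seed = 1)
  te <- randomEmbedding(targetIds(idx), 3, seed = 2)
  cfg <- sageConfig(K = 2, fanouts = c(5, 5), hiddenDim = 6, epochs = 0,
                    seed = 11)
  model <- sageTrain(idx, de, te, trainIds = 0:11,
                     trainLabels = rep(c(0, 1), 6), config = cfg)
  got <- sageRefine(model, idx, de, te, ids = 0:11, seed = 3)$features
  F0 <- pairFeatures(idx, de, te, 0:11)
  want <- naiveSageForwardOracle(idx, F0, model@params, K = 2)
  expect_equal(unname(got), unname(want), tolerance = 1e-8)
})

test_that("analytic gradients agree with finite differences (all aggregators)", {
  idx <- DTPIndex(paste0("D", 1:3), paste0("T", 1:4))
  de <- randomEmbedding(drugIds(idx), 3, seed = 4)
  te <- randomEmbedding(targetIds(idx), 2, seed = 5)
  y <- rep(c(1, 0), 6)
  for (agg in c("mean", "pooling", "lstm")) {
    cfg <- sageConfig(K = 2, fanouts = c(3, 2), aggregator = agg,
                      hiddenDim = 4, epochs = 0, seed = 21,
                      nonlinearity = "tanh")
    model <- sageTrain(idx, de, te, 0:11, y, cfg)
    params <- model@params
    graph <- sageDTI:::.sageGraphFull(idx)
    featFn <- sageDTI:::.makeFeatFn(idx, de, te)
    lossAt <- function(p) {
      set.seed(42)
      fwd <- sageDTI:::.sageForward(p, cfg, graph, featFn, 0:11)
      crossEntropy(y, plogis(fwd$scores))
    }
    set.seed(42)
    fwd <- sageDTI:::.sageForward(params, cfg, graph, featFn, 0:11,
                                  keepCache = TRUE)
    grads <- sageDTI:::.sageBackward(params, cfg, fwd, y)
    h <- 1e-6
    checkEntry <- function(get, set, analytic) {
      p1 <- set(params, get(params) + h)
      p2 <- set(params, get(params) - h)
      numeric <- (lossAt(p1) - lossAt(p2)) / (2 * h)
      expect_equal(analytic, numeric, tolerance = 1e-4)
    }
    for (k in 1:2) {
      ij <- c(2, 3)
      checkEntry(function(p) p$W[[k]][ij[1], ij[2]],
                 function(p, v) { p$W[[k]][ij[1], ij[2]] <- v; p },
                 grads$W[[k]][ij[1], ij[2]])
      if (agg != "mean") {
        checkEntry(function(p) p$agg[[k]]$W[1, 2],
                   function(p, v) { p$agg[[k]]$W[1, 2] <- v; p },
                   grads$agg[[k]]$W[1, 2])
        checkEntry(function(p) p$agg[[k]]$b[1],
                   function(p, v) { p$agg[[k]]$b[1] <- v; p },
                   grads$agg[[k]]$b[1])
      }
    }
    checkEntry(function(p) p$headW[2, 1],
               function(p, v) { p$headW[2, 1] <- v; p },
               grads$headW[2, 1])
  }
})

test_that("untrained models are reproducible and training reduces the loss", {
  b <- generateSyntheticData(synthConfig(nDrugs = 20, nTargets = 24,
                                         seqLength = 40, seed = 5))
  idx <- DTPIndex(b$drugIds, b$targetIds)
  lab <- dtpLabelsFromInteractions(idx, b$interactions)
  smp <- sampleBalanced(lab, idx, seed = 2)
  set.seed(6)
  dm <- matrix(rnorm(20 * 8, sd = 0.3), 20, 8,
               dimnames = list(b$drugIds, NULL)) + 0.5 * b$clusters$drug
  de <- new("EmbeddingMatrix", vectors = dm)
  set.seed(7)
  tm <- matrix(rnorm(24 * 8, sd = 0.3), 24, 8,
               dimnames = list(b$targetIds, NULL)) + 0.5 * b$clusters$target
  te <- new("EmbeddingMatrix", vectors = tm)

  drops <- vapply(1:5, function(sd) {
    cfg <- sageConfig(fanouts = c(10, 5), epochs = 5, batchSize = 64,
                      seed = sd)
    m <- sageTrain(idx, de, te, smp$pairId, smp$label, cfg)
    all(diff(m@losses) < 0)
  }, logical(1))
  expect_gte(sum(drops), 4)

  cfg0 <- sageConfig(fanouts = c(5, 3), epochs = 0, seed = 31)
  m1 <- sageTrain(idx, de, te, smp$pairId, smp$label, cfg0)
  m2 <- sageTrain(idx, de, te, smp$pairId, smp$label, cfg0)
  expect_identical(m1@params, m2@params)
  r1 <- sageRefine(m1, idx, de, te, smp$pairId[1:10], seed = 8)
  r2 <- sageRefine(m2, idx, de, te, smp$pairId[1:10], seed = 8)
  expect_identical(r1, r2)
})

test_that("a separable toy problem is learned to high training AUROC", {
  idx <- DTPIndex(paste0("D", 1:10), paste0("T", 1:10))
  de <- randomEmbedding(drugIds(idx), 4, seed = 41)
  te <- randomEmbedding(targetIds(idx), 4, seed = 42)
  ids <- 0:99
  labels <- as.integer(as.matrix(de)[ids %/% 10 + 1, 1] > 0)
  cfg <- sageConfig(fanouts = c(5, 3), hiddenDim = 16, epochs = 30,
                    batchSize = 64, learningRate = 0.01, seed = 43)
  model <- sageTrain(idx, de, te, ids, labels, cfg)
  sc <- sageRefine(model, idx, de, te, ids, seed = 44)$scores
  expect_gte(evaluateScores(sc, labels)$auroc, 0.95)
})

test_that("pooling and LSTM aggregators train behind the same interface", {
  idx <- DTPIndex(paste0("D", 1:8), paste0("T", 1:8))
  de <- randomEmbedding(drugIds(idx), 6, seed = 51)
  te <- randomEmbedding(targetIds(idx), 6, seed = 52)
  ids <- 0:63
  labels <- rep(c(1, 0), 32)
  for (agg in c("pooling", "lstm")) {
    cfg <- sageConfig(fanouts = c(6, 3), hiddenDim = 8, epochs = 2,
                      batchSize = 64, aggregator = agg, seed = 53)
    m <- sageTrain(idx, de, te, ids, labels, cfg)
    expect_true(all(is.finite(m@losses)))
    r <- sageRefine(m, idx, de, te, ids[1:5], seed = 54)
    expect_identical(r, sageRefine(m, idx, de, te, ids[1:5], seed = 54))
    expect_equal(dim(r$features), c(5L, 8L))
  }
})

test_that("configuration contracts are enforced", {
  expect_warning(sageConfig(fanouts = c(60, 10)), "500")
  expect_error(sageConfig(K = 3, fanouts = c(5, 5)), "length")
  expect_error(sageConfig(learningRate = 0), "positive")
  expect_error(sageConfig(aggregator = "median"), "aggregator")
})
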