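test_that("Jaccard similarity matches set-counting on the worked examples", {
  a <- AssociationMatrix(rbind(d1 = c(1, 1, 0), d2 = c(1, 1, 0)),
                         attributeIds = c("x", "y", "z"))
  expect_equal(as.matrix(jaccardSimilarity(a))["d1", "d2"], 1)

  b <- AssociationMatrix(rbind(d1 = c(1, 0, 0), d2 = c(0, 1, 0)),
                         attributeIds = c("x", "y", "z"))
  expect_equal(as.matrix(jaccardSimilarity(b))["d1", "d2"], 0)

  c2 <- AssociationMatrix(rbind(d1 = c(1, 1, 1, 0), d2 = c(0, 1, 1, 1)),
                          attributeIds = letters[1:4])
  expect_equal(as.matrix(jaccardSimilarity(c2))["d1", "d2"],
               overlapOracle(c(1, 1, 1, 0), c(0, 1, 1, 1)))
})

test_that("Jaccard equals brute-force set counting on random binary matrices", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rbinom(80, 1, 0.4), 10, 8,
                dimnames = list(paste0("e", 1:10), paste0("a", 1:8)))
    s <- as.matrix(jaccardSimilarity(AssociationMatrix(m)))
    expect_equal(unname(s), overlapMatrixOracle(m), tolerance = 1e-12)
  }
})

test_that("two all-zero profiles have similarity zero, not NaN", {
  m <- rbind(e1 = c(0, 0, 0), e2 = c(0, 0, 0), e3 = c(1, 1, 0))
  colnames(m) <- c("x", "y", "z")
  s <- as.matrix(jaccardSimilarity(AssociationMatrix(m)))
  expect_equal(s["e1", "e2"], 0)
  expect_equal(s["e1", "e1"], 0)   # degenerate diagonal
  expect_equal(s["e3", "e3"], 1)
})

test_that("Tanimoto matches bit counting, flags all-zero fingerprints", {
  fp <- AssociationMatrix(rbind(d1 = c(1, 1, 0, 0), d2 = c(1, 0, 1, 0),
                                d3 = c(1, 1, 0, 0), d4 = c(0, 0, 0, 1)),
                          attributeIds = paste0("bit", 1:4))
  s <- as.matrix(tanimotoSimilarity(fp))
  expect_equal(s["d1", "d3"], 1)             # identical fingerprints
  expect_equal(s["d1", "d4"], 0)             # disjoint fingerprints
  expect_equal(s["d1", "d2"], 1 / 3)         # a=2, b=2, c=1 -> c/(a+b-c)
  z <- AssociationMatrix(rbind(d1 = c(0, 0), d2 = c(1, 0)),
                         attributeIds = c("b1", "b2"))
  expect_message(tanimotoSimilarity(z), "all-zero")
})

test_that("Smith-Waterman raw scores match the independent DP oracle", {
  sw <- smithWatermanSimilarity(
    c(s1 = "HEAGAWGHEE", s2 = "PAWHEAE"), normalize = FALSE)
  raw <- as.matrix(sw)
  selfs <- c(swOracle("HEAGAWGHEE", "HEAGAWGHEE", blosum62),
             swOracle("PAWHEAE", "PAWHEAE", blosum62))
  cross <- swOracle("HEAGAWGHEE", "PAWHEAE", blosum62)
  # raw mode is rescaled by the maximum score to stay within [0, 1]
  expect_equal(raw["s1", "s2"], cross / max(selfs, cross))
  expect_equal(cross, 17.5)                  # frozen from the DP oracle

  set.seed(7)
  seqs <- setNames(vapply(1:6, function(i) randomPeptide(sample(8:30, 1)),
                          character(1)), paste0("p", 1:6))
  s <- smithWatermanSimilarity(seqs, normalize = FALSE)
  m <- as.matrix(s)
  selfRaw <- vapply(seqs, function(x) swOracle(x, x, blosum62), numeric(1))
  scale <- max(outer(seq_along(seqs), seq_along(seqs), Vectorize(
    function(i, j) swOracle(seqs[i], seqs[j], blosum62))))
  for (i in 1:5) for (j in (i + 1):6) {
    o <- swOracle(seqs[i], seqs[j], blosum62)
    expect_equal(m[i, j] * scale, o, tolerance = 1e-9)
    expect_gte(o, 0)
    expect_lte(o, min(selfRaw[i], selfRaw[j]) + 1e-9)
  }
})

test_that("Smith-Waterman self-normalization yields a unit diagonal", {
  set.seed(3)
  seqs <- setNames(vapply(1:5, function(i) randomPeptide(20), character(1)),
                   paste0("p", 1:5))
  s <- as.matrix(smithWatermanSimilarity(seqs))
  expect_equal(unname(diag(s)), rep(1, 5))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s), tolerance = 1e-12)
  # no positively scoring residue pair -> empty local alignment, score 0
  g <- smithWatermanSimilarity(c(a = "GGGG", b = "WWWW"), normalize = FALSE)
  expect_equal(as.matrix(g)["a", "b"], 0)
})

test_that("sequence validation rejects empty and unknown residues", {
  expect_error(smithWatermanSimilarity(c(a = "", b = "AA")), "empty")
  expect_error(smithWatermanSimilarity(c(a = "AB", b = "AA")), "unknown")
  expect_silent(smithWatermanSimilarity(c(a = "AXA", b = "AAA")))
  expect_error(smithWatermanSimilarity(c(a = "AXA", b = "AAA"),
                                       allowX = FALSE), "unknown")
})

test_that("binarization is strict, zero-diagonal, and nested in alpha", {
  s <- new("SimilarityMatrix", kind = "jaccard",
           sim = matrix(c(1, .6, .2, .6, 1, .4, .2, .4, 1), 3, 3,
                        dimnames = list(letters[1:3], letters[1:3])))
  b <- as.matrix(binarize(s, 0.5))
  expect_equal(sum(b), 2)                    # exactly the (1,2) edge pair
  expect_equal(b["a", "b"], 1)
  # threshold is strict: similarity equal to alpha is not an edge
  expect_equal(as.matrix(binarize(s, 0.6))["a", "b"], 0)
  # alpha = 0 on strictly positive off-diagonals gives the complete graph
  expect_equal(sum(as.matrix(binarize(s, 0))), 6)
  expect_true(all(diag(as.matrix(binarize(s, 0))) == 0))

  set.seed(5)
  r <- matrix(runif(49), 7, 7)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(paste0("e", 1:7), paste0("e", 1:7))
  rs <- new("SimilarityMatrix", sim = r, kind = "jaccard")
  for (alphas in list(c(0.2, 0.5), c(0.3, 0.8))) {
    lo <- as.matrix(binarize(rs, min(alphas)))
    hi <- as.matrix(binarize(rs, max(alphas)))
    expect_true(all(hi <= lo))               # higher alpha: edge subset
  }
  expect_error(binarize(s, 1), "alpha")
})

test_that("fusion is an element-wise OR with id checking", {
  ids <- paste0("e", 1:5)
  mk <- function(m) {
    dimnames(m) <- list(ids, ids)
    new("BinaryNetwork", adj = m, alpha = 0.5)
  }
  set.seed(9)
  nets <- lapply(1:4, function(k) {
    m <- matrix(rbinom(25, 1, 0.3), 5, 5)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    mk(m)
  })
  fused <- as.matrix(fuseNetworks(nets))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(fused[i, j],
                 max(vapply(nets, function(n) as.matrix(n)[i, j], numeric(1))))
  }
  # identity, idempotence, commutativity, monotonicity
  expect_equal(as.matrix(fuseNetworks(nets[1])), as.matrix(nets[[1]]))
  expect_equal(as.matrix(fuseNetworks(c(nets, nets))), fused)
  expect_equal(as.matrix(fuseNetworks(rev(nets))), fused)
  expect_true(all(as.matrix(fuseNetworks(nets[1:2])) <= fused))

  other <- nets[[1]]
  rownames(other@adj) <- colnames(other@adj) <- rev(ids)
  expect_error(fuseNetworks(list(nets[[2]], other)), "mismatched")
})

test_that("similarity outputs are symmetric with values in [0, 1]", {
  set.seed(21)
  m <- matrix(rbinom(120, 1, 0.35), 12, 10,
              dimnames = list(paste0("e", 1:12), paste0("a", 1:10)))
  for (s in list(jaccardSimilarity(AssociationMatrix(m)),
                 suppressMessages(tanimotoSimilarity(AssociationMatrix(m))))) {
    v <- as.matrix(s)
    expect_lte(max(abs(v - t(v))), 1e-12)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(AssociationMatrix(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(AssociationMatrix(matrix(c(0, 2), 1, 2), entityIds = "e",
                                 attributeIds = c("a", "b")), "0 or 1")
})
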