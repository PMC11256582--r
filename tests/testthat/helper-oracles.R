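# Independent brute-force oracles used to pin down expected values.  These
# deliberately share no code with the package implementation.

# Jaccard/Tanimoto by explicit set/bit counting on two binary vectors.
overlapOracle <- function(x, y) {
  a <- sum(x == 1)
  b <- sum(y == 1)
  c <- sum(x == 1 & y == 1)
  if (a + b - c == 0) 0 else c / (a + b - c)
}

# Full pairwise similarity matrix by looping the scalar oracle.
overlapMatrixOracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- overlapOracle(m[i, ], m[j, ])
  diag(out)[rowSums(m) > 0] <- 1
  out
}

# Smith-Waterman with affine gaps (Gotoh three-state recursion); a gap of
# length L costs gapOpening + L * gapExtension.  Quadratic, scalar, slow.
swOracle <- function(a, b, sub, gapOpening = 10, gapExtension = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - (gapOpening + gapExtension),
                      Ix[i - 1, j] - gapExtension)
      Iy[i, j] <- max(M[i, j - 1] - (gapOpening + gapExtension),
                      Iy[i, j - 1] - gapExtension)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + sub[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

randomPeptide <- function(len) {
  paste(sample(rownames(blosum62)[1:20], len, replace = TRUE), collapse = "")
}

# Dense pair-network adjacency built by a double loop over all pair pairs
# from the literal shared-drug-or-shared-target rule (diagonal included).
denseDtpAdjacencyOracle <- function(nd, nt) {
  n <- nd * nt
  A <- matrix(0L, n, n)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      i <- u %/% nt; j <- u %% nt
      p <- v %/% nt; q <- v %% nt
      if (i == p || j == q) A[u + 1, v + 1] <- 1L
    }
  }
  A
}

# AUROC by exhaustive Mann-Whitney pair counting (ties count 1/2).
aurocOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Naive per-node recursive evaluation of the K-layer sample-and-aggregate
# update with FULL neighborhoods and the mean aggregator: the reference for
# the batched implementation when fanouts equal the node degree.
naiveSageForwardOracle <- function(index, F0, params, K, nonlinearity = "relu") {
  act <- switch(nonlinearity, relu = function(z) pmax(z, 0),
                tanh = tanh, identity = identity)
  h <- function(u, k) {
    if (k == 0) return(F0[u + 1, ])
    nbr <- dtpNeighbors(index, u)
    agg <- colMeans(do.call(rbind, lapply(nbr, h, k = k - 1)))
    as.vector(act(params$W[[k]] %*% c(h(u, k - 1), agg)))
  }
  t(vapply(0:(nPairs(index) - 1), function(u) h(u, K),
           numeric(nrow(params$W[[K]]))))
}

# Small random embedding matrix helper.
randomEmbedding <- function(ids, dim, seed) {
  withr_seed <- function(expr) expr
  set.seed(seed)
  m <- matrix(rnorm(length(ids) * dim), length(ids), dim)
  rownames(m) <- ids
  new("EmbeddingMatrix", vectors = m)
}

# Tiny fused network from one similarity matrix, for DeepWalk tests.
networkFromAdjacency <- function(adj, ids = NULL) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(ids, ids)
  new("HomogeneousNetwork", adj = adj, sources = "test")
}
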