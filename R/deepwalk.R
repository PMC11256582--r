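#' @include AllClasses.R
NULL

#' Generate truncated random walks over a homogeneous network
#'
#' Starts `walksPerNode` walks at every node.  At each step the next node is
#' drawn uniformly from the current node's neighbors.  A walk starting at an
#' isolated node is the singleton walk of that node (in an undirected network
#' a walk can only stall at its start).  The same seed yields an identical
#' corpus.
#'
#' @param net a [HomogeneousNetwork-class].
#' @param walksPerNode walks started per node (default 10).
#' @param walkLength maximum walk length in nodes (default 40).
#' @param seed RNG seed.
#' @return a [WalkCorpus-class].
#' @export
generateWalks <- function(net, walksPerNode = 10, walkLength = 40, seed = 1) {
  stopifnot(is(net, "HomogeneousNetwork"))
  if (walksPerNode < 1 || walkLength < 1)
    stop("walksPerNode and walkLength must be >= 1")
  adj <- as.matrix(net)
  n <- nrow(adj)
  if (n == 0L) stop("empty network")
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  deg <- lengths(nbrs)
  walks <- withSeed(seed, {
    out <- vector("list", n * walksPerNode)
    k <- 0L
    for (r in seq_len(walksPerNode)) {
      for (v in seq_len(n)) {
        w <- integer(walkLength)
        w[1L] <- v
        len <- 1L
        cur <- v
        while (len < walkLength && deg[cur] > 0L) {
          nb <- nbrs[[cur]]
          cur <- nb[sample.int(deg[cur], 1L)]
          len <- len + 1L
          w[len] <- cur
        }
        k <- k + 1L
        out[[k]] <- w[seq_len(len)]
      }
    }
    out
  })
  new("WalkCorpus", walks = walks, entityIds = entityIds(net),
      walkLength = as.integer(walkLength),
      walksPerNode = as.integer(walksPerNode), seed = as.numeric(seed))
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling, trained by single-threaded stochastic
#' gradient descent with a linearly decaying learning rate (deterministic
#' given the seed).  Nodes that never occur in a walk of length at least two
#' contribute no training pairs; they receive a zero vector and a warning so
#' that downstream feature concatenation never fails.
#'
#' @param corpus a [WalkCorpus-class].
#' @param dim embedding dimension (default 64).
#' @param window one-sided context window (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param learningRate initial SGD step size (default 0.025).
#' @param seed RNG seed for initialization and sampling.
#' @return an [EmbeddingMatrix-class] with one row per network node.
#' @export
trainSkipgram <- function(corpus, dim = 64, window = 5, epochs = 5,
                          negative = 5, learningRate = 0.025, seed = 1) {
  stopifnot(is(corpus, "WalkCorpus"))
  if (dim <= 0) stop("dim must be positive")
  n <- length(corpus@entityIds)
  vec <- .skipgramSGNS(corpus@walks, n, as.integer(dim), as.integer(window),
                       as.integer(epochs), as.integer(negative),
                       learningRate, learningRate * 1e-4, as.numeric(seed))
  trained <- unique(unlist(corpus@walks[lengths(corpus@walks) >= 2L]))
  untrained <- setdiff(seq_len(n), trained)
  if (length(untrained)) {
    vec[untrained, ] <- 0
    warning(length(untrained),
            " node(s) had no walk context; their embeddings are zero vectors")
  }
  rownames(vec) <- corpus@entityIds
  new("EmbeddingMatrix", vectors = vec)
}

#' DeepWalk embedding of a homogeneous network
#'
#' Composition of [generateWalks()] and [trainSkipgram()]: truncated random
#' walks provide the "sentences" on which skip-gram learns one vector per
#' network node.
#'
#' @param net a [HomogeneousNetwork-class].
#' @param dim embedding dimension (default 64).
#' @param walkLength,walksPerNode,window,epochs,negative,learningRate
#'   DeepWalk/skip-gram hyperparameters; see [generateWalks()] and
#'   [trainSkipgram()].
#' @param seed RNG seed (walk generation and training derive child seeds).
#' @return an [EmbeddingMatrix-class].
#' @export
embedNetwork <- function(net, dim = 64, walkLength = 40, walksPerNode = 10,
                         window = 5, epochs = 5, negative = 5,
                         learningRate = 0.025, seed = 1) {
  corpus <- generateWalks(net, walksPerNode = walksPerNode,
                          walkLength = walkLength,
                          seed = childSeed(seed, 1))
  trainSkipgram(corpus, dim = dim, window = window, epochs = epochs,
                negative = negative, learningRate = learningRate,
                seed = childSeed(seed, 2))
}
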