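#' @include AllClasses.R
NULL

.checkPairIds <- function(index, ids) {
  n <- nPairs(index)
  if (length(ids) == 0L) stop("no pair ids given")
  if (any(!is.finite(ids)) || any(ids < 0) || any(ids >= n) ||
      any(ids != floor(ids)))
    stop("pair id out of range [0, ", n, ")")
  invisible(ids)
}

#' Map (drug, target) indices to pair-node ids and back
#'
#' Pair ids are 0-based row-major: `pairId = (i - 1) * nTargets + (j - 1)`
#' for 1-based drug index `i` and target index `j`.  `pairFromId` is the
#' exact O(1) inverse.
#'
#' @param index a [DTPIndex-class].
#' @param i,j 1-based drug and target indices (vectorized, recycled).
#' @return `pairId`: numeric vector of 0-based pair ids.
#' @export
pairId <- function(index, i, j) {
  stopifnot(is(index, "DTPIndex"))
  if (any(i < 1 | i > nDrugs(index)) || any(j < 1 | j > nTargets(index)))
    stop("drug or target index out of range")
  (as.numeric(i) - 1) * nTargets(index) + (as.numeric(j) - 1)
}

#' @param id numeric vector of 0-based pair ids.
#' @return `pairFromId`: data.frame with columns `i`, `j` (1-based indices)
#'   and `drug`, `target` (identifiers).
#' @rdname pairId
#' @export
pairFromId <- function(index, id) {
  stopifnot(is(index, "DTPIndex"))
  .checkPairIds(index, id)
  nt <- nTargets(index)
  i <- id %/% nt + 1
  j <- id %% nt + 1
  data.frame(i = i, j = j, drug = drugIds(index)[i],
             target = targetIds(index)[j], stringsAsFactors = FALSE)
}

#' Adjacency between two pair nodes
#'
#' Two drug-target pairs are adjacent iff they share the drug or the target.
#' The relation is symmetric, and under the definition a node is adjacent to
#' itself; neighbor enumeration ([dtpNeighbors()]) nevertheless excludes the
#' node itself, since the self feature enters the GraphSAGE update through
#' its own concatenation slot.
#'
#' @param index a [DTPIndex-class].
#' @param u,v 0-based pair-node ids (vectorized, recycled).
#' @return integer 0/1 vector.
#' @export
dtpAdjacent <- function(index, u, v) {
  stopifnot(is(index, "DTPIndex"))
  .checkPairIds(index, u)
  .checkPairIds(index, v)
  nt <- nTargets(index)
  as.integer((u %/% nt == v %/% nt) | (u %% nt == v %% nt))
}

#' Neighbors of a pair node in the implicit pair network
#'
#' Enumerates, without materializing any adjacency matrix, the
#' `nTargets - 1` pairs sharing the drug and the `nDrugs - 1` pairs sharing
#' the target of `u` (excluding `u` itself, no duplicates), so every node has
#' degree `nDrugs + nTargets - 2`.  Storage is O(nDrugs + nTargets).
#'
#' @param index a [DTPIndex-class].
#' @param u a single 0-based pair-node id.
#' @return sorted numeric vector of neighbor pair ids.
#' @export
dtpNeighbors <- function(index, u) {
  stopifnot(is(index, "DTPIndex"), length(u) == 1L)
  .checkPairIds(index, u)
  nt <- nTargets(index)
  nd <- nDrugs(index)
  i0 <- u %/% nt
  j0 <- u %% nt
  sameDrug <- i0 * nt + setdiff(seq_len(nt) - 1, j0)
  sameTarget <- (setdiff(seq_len(nd) - 1, i0)) * nt + j0
  sort(c(sameDrug, sameTarget))
}

#' Degree of every node in the implicit pair network
#'
#' @param index a [DTPIndex-class].
#' @return the common node degree `nDrugs + nTargets - 2`.
#' @export
dtpDegree <- function(index) {
  stopifnot(is(index, "DTPIndex"))
  nDrugs(index) + nTargets(index) - 2L
}

#' Construct pair labels from known interactions
#'
#' @param index a [DTPIndex-class].
#' @param interactions two-column data.frame (or matrix) of known
#'   drug-target interactions, either identifiers (`drug`, `target`) or
#'   1-based indices (`i`, `j`).
#' @return a [DTPLabels-class].
#' @export
dtpLabelsFromInteractions <- function(index, interactions) {
  stopifnot(is(index, "DTPIndex"))
  interactions <- as.data.frame(interactions)
  if (nrow(interactions) == 0L) {
    pos <- numeric(0)
  } else if (is.numeric(interactions[[1]])) {
    pos <- pairId(index, interactions[[1]], interactions[[2]])
  } else {
    i <- match(as.character(interactions[[1]]), drugIds(index))
    j <- match(as.character(interactions[[2]]), targetIds(index))
    if (anyNA(i) || anyNA(j))
      stop("interaction refers to unknown drug or target id")
    pos <- pairId(index, i, j)
  }
  new("DTPLabels", positives = sort(unique(pos)),
      nDrugs = nDrugs(index), nTargets = nTargets(index))
}

#' Label of pair nodes
#'
#' Label 1 iff the (drug, target) combination is a known interaction.
#'
#' @param labels a [DTPLabels-class].
#' @param ids 0-based pair-node ids.
#' @return integer 0/1 vector.
#' @export
dtpLabel <- function(labels, ids) {
  stopifnot(is(labels, "DTPLabels"))
  as.integer(ids %in% labels@positives)
}

#' Concatenated pair features
#'
#' The feature of pair (i, j) is the concatenation of the drug embedding row
#' `i` and the target embedding row `j`; the first block recovers the drug
#' vector exactly and the remainder the target vector.
#'
#' @param drugEmbeddings,targetEmbeddings [EmbeddingMatrix-class] objects.
#' @param index a [DTPIndex-class] whose ids match the embedding rownames.
#' @param ids 0-based pair-node ids.
#' @return numeric matrix, one row per requested pair, `dimD + dimT` columns.
#' @export
pairFeatures <- function(index, drugEmbeddings, targetEmbeddings, ids) {
  stopifnot(is(index, "DTPIndex"),
            is(drugEmbeddings, "EmbeddingMatrix"),
            is(targetEmbeddings, "EmbeddingMatrix"))
  .checkPairIds(index, ids)
  dmat <- as.matrix(drugEmbeddings)
  tmat <- as.matrix(targetEmbeddings)
  di <- match(drugIds(index), rownames(dmat))
  tj <- match(targetIds(index), rownames(tmat))
  if (anyNA(di)) stop("missing drug embedding row(s)")
  if (anyNA(tj)) stop("missing target embedding row(s)")
  nt <- nTargets(index)
  cbind(dmat[di[ids %/% nt + 1], , drop = FALSE],
        tmat[tj[ids %% nt + 1], , drop = FALSE])
}

#' Balanced positive/negative node sample
#'
#' Returns all positive pair nodes plus an equal-count subset of zero-labeled
#' nodes sampled uniformly without replacement from the full complement.
#' Deterministic given the seed.
#'
#' @param labels a [DTPLabels-class].
#' @param index the matching [DTPIndex-class].
#' @param seed RNG seed.
#' @return data.frame with columns `pairId`, `drug`, `target`, `label`,
#'   positives first.
#' @export
sampleBalanced <- function(labels, index, seed = 1) {
  stopifnot(is(labels, "DTPLabels"), is(index, "DTPIndex"))
  pos <- labels@positives
  if (length(pos) < 1L) stop("need at least one positive pair")
  total <- nPairs(index)
  nNeg <- total - length(pos)
  if (nNeg < length(pos))
    stop("not enough zero-labeled pairs to balance the positives")
  neg <- withSeed(seed, {
    if (total <= 1e6) {
      sample(setdiff(seq_len(total) - 1, pos), length(pos))
    } else {
      # rejection sampling keeps memory O(sample size) for huge indexes
      got <- numeric(0)
      while (length(got) < length(pos)) {
        cand <- floor(runif(2L * (length(pos) - length(got)) + 16L) * total)
        cand <- cand[!(cand %in% pos) & !(cand %in% got)]
        got <- c(got, unique(cand))
      }
      got[seq_along(pos)]
    }
  })
  ids <- c(pos, neg)
  info <- pairFromId(index, ids)
  data.frame(pairId = ids, drug = info$drug, target = info$target,
             label = rep(c(1L, 0L), c(length(pos), length(neg))),
             stringsAsFactors = FALSE)
}
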