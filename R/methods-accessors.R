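#' @include AllGenerics.R
NULL

## ---- entityIds -------------------------------------------------------------

#' @rdname entityIds
setMethod("entityIds", "AssociationMatrix", function(x) rownames(x@assoc))
#' @rdname entityIds
setMethod("entityIds", "SimilarityMatrix", function(x) rownames(x@sim))
#' @rdname entityIds
setMethod("entityIds", "BinaryNetwork", function(x) rownames(x@adj))
#' @rdname entityIds
setMethod("entityIds", "HomogeneousNetwork", function(x) rownames(x@adj))
#' @rdname entityIds
setMethod("entityIds", "WalkCorpus", function(x) x@entityIds)
#' @rdname entityIds
setMethod("entityIds", "EmbeddingMatrix", function(x) rownames(x@vectors))

## ---- simple accessors ------------------------------------------------------

#' @rdname attributeIds
setMethod("attributeIds", "AssociationMatrix", function(x) colnames(x@assoc))

#' @rdname similarityKind
setMethod("similarityKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname alphaThreshold
setMethod("alphaThreshold", "BinaryNetwork", function(x) x@alpha)

#' @rdname fusedSources
setMethod("fusedSources", "HomogeneousNetwork", function(x) x@sources)

#' @rdname embeddingDim
setMethod("embeddingDim", "EmbeddingMatrix", function(x) ncol(x@vectors))

#' @rdname nDrugs
setMethod("nDrugs", "DTPIndex", function(x) length(x@drugIds))
#' @rdname nDrugs
setMethod("nTargets", "DTPIndex", function(x) length(x@targetIds))
#' @rdname nDrugs
setMethod("nPairs", "DTPIndex",
          function(x) as.numeric(length(x@drugIds)) * length(x@targetIds))

#' @rdname drugIds
setMethod("drugIds", "DTPIndex", function(x) x@drugIds)
#' @rdname drugIds
setMethod("targetIds", "DTPIndex", function(x) x@targetIds)

#' @rdname positivePairs
setMethod("positivePairs", "DTPLabels", function(x) x@positives)

## ---- as.matrix -------------------------------------------------------------

#' Matrix views of sageDTI objects
#'
#' `as.matrix` returns the underlying numeric matrix (incidence, similarity,
#' adjacency or embedding) with its dimnames.
#'
#' @param x the object.
#' @param ... ignored.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@sim)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "BinaryNetwork", function(x, ...) x@adj)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "HomogeneousNetwork", function(x, ...) x@adj)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "EmbeddingMatrix", function(x, ...) x@vectors)

## ---- show ------------------------------------------------------------------

.edgeDensity <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  sum(adj) / (n * (n - 1))
}

setMethod("show", "AssociationMatrix", function(object) {
  m <- object@assoc
  cat(sprintf("AssociationMatrix: %d entities x %d attributes, %d associations\n",
              nrow(m), ncol(m), sum(m)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d entities, mean off-diagonal %.4f\n",
              object@kind, nrow(object@sim),
              mean(object@sim[row(object@sim) != col(object@sim)])))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork (alpha = %g): %d nodes, %d edges (density %.4f)\n",
              object@alpha, nrow(object@adj), sum(object@adj) / 2,
              .edgeDensity(object@adj)))
})

setMethod("show", "HomogeneousNetwork", function(object) {
  cat(sprintf("HomogeneousNetwork [%s]: %d nodes, %d edges (density %.4f)\n",
              paste(object@sources, collapse = " | "), nrow(object@adj),
              sum(object@adj) / 2, .edgeDensity(object@adj)))
})

setMethod("show", "WalkCorpus", function(object) {
  cat(sprintf("WalkCorpus: %d walks over %d nodes (walkLength %d, walksPerNode %d)\n",
              length(object@walks), length(object@entityIds),
              object@walkLength, object@walksPerNode))
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix: %d entities x %d dimensions\n",
              nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "DTPIndex", function(object) {
  cat(sprintf("DTPIndex: %d drugs x %d targets = %s pair nodes (degree %d each)\n",
              nDrugs(object), nTargets(object),
              format(nPairs(object), big.mark = ","),
              nDrugs(object) + nTargets(object) - 2L))
})

setMethod("show", "DTPLabels", function(object) {
  cat(sprintf("DTPLabels: %d positive pairs of %s pair nodes\n",
              length(object@positives),
              format(as.numeric(object@nDrugs) * object@nTargets,
                     big.mark = ",")))
})

setMethod("show", "SageConfig", function(object) {
  cat(sprintf(
    "SageConfig: K = %d, fanouts = [%s], aggregator = %s, hiddenDim = %d\n",
    object@K, paste(object@fanouts, collapse = ", "), object@aggregator,
    object@hiddenDim))
  cat(sprintf("  lr = %g, epochs = %d, batchSize = %d, nonlinearity = %s%s\n",
              object@learningRate, object@epochs, object@batchSize,
              object@nonlinearity,
              if (object@subgraphOnly) ", subgraph-only" else ""))
})

setMethod("show", "SageModel", function(object) {
  cat(sprintf("SageModel: %d-layer %s-aggregator GraphSAGE (input dim %d)\n",
              object@config@K, object@config@aggregator, object@inputDim))
  if (length(object@losses))
    cat(sprintf("  final training loss %.4f after %d epochs\n",
                object@losses[length(object@losses)], length(object@losses)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s, %d folds):\n", object@classifier,
              nrow(object@folds)))
  m <- reportMeans(object)
  cat(sprintf("  mean AUROC %.4f, AUPR %.4f, accuracy %.4f, F1 %.4f\n",
              m["auroc"], m["aupr"], m["accuracy"], m["f1"]))
})

#' Mean metrics of an evaluation report
#'
#' @param report an [EvalReport-class].
#' @return named numeric vector with the arithmetic mean over folds of
#'   auroc, aupr, accuracy, precision, recall and f1.
#' @export
reportMeans <- function(report) {
  stopifnot(is(report, "EvalReport"))
  cols <- c("auroc", "aupr", "accuracy", "precision", "recall", "f1")
  colMeans(as.matrix(report@folds[, cols]))
}

#' Per-fold metrics of an evaluation report
#'
#' @param report an [EvalReport-class].
#' @return the fold-level data.frame.
#' @export
reportFolds <- function(report) {
  stopifnot(is(report, "EvalReport"))
  report@folds
}
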