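#' @include AllClasses.R
NULL

#' Entity identifiers of a network-like object
#' @param x an object carrying entity ids.
#' @return character vector of ids.
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' Attribute identifiers of an association matrix
#' @param x an [AssociationMatrix-class].
#' @export
setGeneric("attributeIds", function(x) standardGeneric("attributeIds"))

#' Similarity kind
#' @param x a [SimilarityMatrix-class].
#' @export
setGeneric("similarityKind", function(x) standardGeneric("similarityKind"))

#' Binarization threshold
#' @param x a [BinaryNetwork-class].
#' @export
setGeneric("alphaThreshold", function(x) standardGeneric("alphaThreshold"))

#' Names of the networks fused into a homogeneous network
#' @param x a [HomogeneousNetwork-class].
#' @export
setGeneric("fusedSources", function(x) standardGeneric("fusedSources"))

#' Embedding dimension
#' @param x an [EmbeddingMatrix-class].
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Drug / target / pair counts of a pair-network index
#' @param x a [DTPIndex-class].
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))

#' @rdname nDrugs
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))

#' @rdname nDrugs
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Drug / target identifiers of a pair-network index
#' @param x a [DTPIndex-class].
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname drugIds
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' Positive pair ids of a label set
#' @param x a [DTPLabels-class].
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))
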