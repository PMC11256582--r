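#' @include sageDTI-package.R
NULL

.isBinary <- function(x) all(x == 0 | x == 1)

.isSymmetric <- function(x, tol = 1e-12) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

#' AssociationMatrix: binary entity-by-attribute incidence
#'
#' Raw input to similarity computation: a binary matrix whose rows are
#' entities (drugs or proteins) and whose columns are attributes (diseases,
#' side effects, interaction partners, fingerprint bits).
#'
#' @slot assoc binary matrix with unique row (entity) and column (attribute)
#'   dimnames.
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", slots = c(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  m <- object@assoc
  if (!is.numeric(m)) return("'assoc' must be numeric")
  if (nrow(m) < 1L) return("association matrix must have at least one entity")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("'assoc' must carry entity and attribute ids as dimnames")
  if (anyDuplicated(rownames(m))) return("entity ids must be unique")
  if (anyDuplicated(colnames(m))) return("attribute ids must be unique")
  if (!.isBinary(m)) return("association values must all be 0 or 1")
  TRUE
})

#' @param values binary matrix (rows = entities, cols = attributes).
#' @param entityIds,attributeIds optional ids; taken from `dimnames(values)`
#'   when missing.
#' @rdname AssociationMatrix-class
#' @export
AssociationMatrix <- function(values, entityIds = rownames(values),
                              attributeIds = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("association matrix must be non-empty")
  dimnames(values) <- list(entityIds, attributeIds)
  new("AssociationMatrix", assoc = values)
}

#' SimilarityMatrix: square entity-by-entity similarity in [0, 1]
#'
#' @slot sim symmetric numeric matrix with values in \[0, 1\]; diagonal 1 for
#'   non-degenerate entities.
#' @slot kind one of `"jaccard"`, `"tanimoto"`, `"smith_waterman"`.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", slots = c(sim = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  s <- object@sim
  if (!.isSymmetric(s)) return("similarity matrix must be square and symmetric")
  if (is.null(rownames(s))) return("similarity matrix must carry entity ids")
  if (min(s) < -1e-12 || max(s) > 1 + 1e-12)
    return("similarity values must lie in [0, 1]")
  if (!object@kind %in% c("jaccard", "tanimoto", "smith_waterman"))
    return("unknown similarity kind")
  TRUE
})

#' BinaryNetwork: alpha-thresholded similarity network
#'
#' @slot adj symmetric binary adjacency with zero diagonal.
#' @slot alpha threshold used (edges where similarity strictly exceeds alpha).
#' @exportClass BinaryNetwork
setClass("BinaryNetwork", slots = c(adj = "matrix", alpha = "numeric"))

setValidity("BinaryNetwork", function(object) {
  a <- object@adj
  if (!.isSymmetric(a)) return("adjacency must be square and symmetric")
  if (!.isBinary(a)) return("adjacency values must all be 0 or 1")
  if (any(diag(a) != 0)) return("binary networks are simple graphs: zero diagonal")
  if (object@alpha < 0 || object@alpha >= 1) return("alpha must lie in [0, 1)")
  TRUE
})

#' HomogeneousNetwork: OR-fusion of binary networks
#'
#' An edge is present iff at least one source binary network has it
#' ("see one, get one").
#'
#' @slot adj symmetric binary adjacency with zero diagonal.
#' @slot sources names of the fused binary networks.
#' @exportClass HomogeneousNetwork
setClass("HomogeneousNetwork", slots = c(adj = "matrix", sources = "character"))

setValidity("HomogeneousNetwork", function(object) {
  a <- object@adj
  if (!.isSymmetric(a)) return("adjacency must be square and symmetric")
  if (!.isBinary(a)) return("adjacency values must all be 0 or 1")
  if (any(diag(a) != 0)) return("homogeneous networks are simple graphs: zero diagonal")
  TRUE
})

#' WalkCorpus: truncated random walks over a homogeneous network
#'
#' @slot walks list of integer vectors of node indices (1-based into
#'   `entityIds`); every consecutive pair is an edge of the source network.
#' @slot entityIds node identifiers of the source network.
#' @slot walkLength,walksPerNode,seed walk parameters.
#' @exportClass WalkCorpus
setClass("WalkCorpus", slots = c(
  walks = "list", entityIds = "character",
  walkLength = "integer", walksPerNode = "integer", seed = "numeric"
))

setValidity("WalkCorpus", function(object) {
  if (length(object@walks) == 0L) return("corpus must contain at least one walk")
  lens <- lengths(object@walks)
  if (any(lens < 1L) || any(lens > object@walkLength))
    return("walk lengths must lie in [1, walkLength]")
  TRUE
})

#' EmbeddingMatrix: entity-by-dimension embedding
#'
#' @slot vectors numeric matrix, one row per entity (rownames = entity ids).
#' @exportClass EmbeddingMatrix
setClass("EmbeddingMatrix", slots = c(vectors = "matrix"))

setValidity("EmbeddingMatrix", function(object) {
  v <- object@vectors
  if (ncol(v) < 1L) return("embedding dimension must be positive")
  if (is.null(rownames(v))) return("embedding rows must be named by entity id")
  if (!all(is.finite(v))) return("embedding values must be finite")
  TRUE
})

#' DTPIndex: implicit drug-target pair network
#'
#' Indexes all `nDrugs * nTargets` drug-target pairs without materializing
#' the pair-pair adjacency matrix.  Pair ids are 0-based:
#' `pairId = (i - 1) * nTargets + (j - 1)` for drug `i` and target `j`
#' (1-based), so the inverse mapping is an O(1) divmod and storage is
#' O(nDrugs + nTargets).
#'
#' @slot drugIds,targetIds entity identifiers.
#' @exportClass DTPIndex
setClass("DTPIndex", slots = c(drugIds = "character", targetIds = "character"))

setValidity("DTPIndex", function(object) {
  if (length(object@drugIds) < 1L || length(object@targetIds) < 1L)
    return("need at least one drug and one target")
  if (anyDuplicated(object@drugIds) || anyDuplicated(object@targetIds))
    return("drug and target ids must be unique")
  TRUE
})

#' @param drugIds,targetIds character vectors of unique identifiers.
#' @rdname DTPIndex-class
#' @export
DTPIndex <- function(drugIds, targetIds) {
  new("DTPIndex", drugIds = as.character(drugIds),
      targetIds = as.character(targetIds))
}

#' DTPLabels: known-interaction labels on the pair network
#'
#' A pair node has label 1 iff its (drug, target) combination is a known
#' interaction; all other pairs are labeled 0.
#'
#' @slot positives sorted numeric vector of 0-based pair ids with label 1.
#' @slot nDrugs,nTargets dimensions of the index the labels refer to.
#' @exportClass DTPLabels
setClass("DTPLabels",
         slots = c(positives = "numeric", nDrugs = "integer", nTargets = "integer"))

setValidity("DTPLabels", function(object) {
  n <- as.numeric(object@nDrugs) * as.numeric(object@nTargets)
  p <- object@positives
  if (length(p) && (min(p) < 0 || max(p) >= n))
    return("positive pair ids out of index bounds")
  if (anyDuplicated(p)) return("positive pair ids must be unique")
  TRUE
})

#' SageConfig: GraphSAGE hyperparameters
#'
#' @slot K number of layers; must equal `length(fanouts)`.
#' @slot fanouts neighbors sampled per layer, e.g. `c(50, 10)`.
#' @slot aggregator `"mean"`, `"pooling"` or `"lstm"`.
#' @slot hiddenDim,learningRate,epochs,batchSize,seed training parameters.
#' @slot nonlinearity `"relu"`, `"tanh"` or `"identity"`.
#' @slot subgraphOnly when TRUE, neighbor sampling is restricted to the
#'   labeled sample instead of the full implicit pair network.
#' @exportClass SageConfig
setClass("SageConfig", slots = c(
  K = "integer", fanouts = "integer", aggregator = "character",
  hiddenDim = "integer", learningRate = "numeric", epochs = "integer",
  batchSize = "integer", seed = "numeric", nonlinearity = "character",
  subgraphOnly = "logical"
))

setValidity("SageConfig", function(object) {
  if (object@K != length(object@fanouts))
    return("K must equal length(fanouts)")
  if (any(object@fanouts < 1L)) return("fanouts must be positive")
  if (!object@aggregator %in% c("mean", "pooling", "lstm"))
    return("aggregator must be one of mean, pooling, lstm")
  if (object@learningRate <= 0) return("learning rate must be positive")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (!object@nonlinearity %in% c("relu", "tanh", "identity"))
    return("nonlinearity must be one of relu, tanh, identity")
  TRUE
})

#' SageModel: trained GraphSAGE parameters
#'
#' Holds the layer weight matrices, any aggregator state (pooling MLP or
#' LSTM weights) and the sigmoid scoring head, together with the
#' configuration used for training.
#'
#' @slot params named list of parameter matrices.
#' @slot config the [SageConfig-class] used.
#' @slot inputDim feature dimension fed to layer 1.
#' @slot losses mean training loss per epoch.
#' @exportClass SageModel
setClass("SageModel", slots = c(
  params = "list", config = "SageConfig", inputDim = "integer",
  losses = "numeric"
))

#' EvalReport: per-fold and mean evaluation metrics
#'
#' @slot folds data.frame with one row per fold/repeat and columns
#'   `auroc`, `aupr`, `accuracy`, `precision`, `recall`, `f1`.
#' @slot classifier classifier name.
#' @slot configHash hash of the evaluation configuration.
#' @exportClass EvalReport
setClass("EvalReport", slots = c(
  folds = "data.frame", classifier = "character", configHash = "character"
))

setValidity("EvalReport", function(object) {
  need <- c("auroc", "aupr", "accuracy", "precision", "recall", "f1")
  if (!all(need %in% colnames(object@folds)))
    return("fold table must contain all six metrics")
  vals <- as.matrix(object@folds[, need])
  if (any(vals < -1e-9 | vals > 1 + 1e-9, na.rm = TRUE))
    return("metrics must lie in [0, 1]")
  TRUE
})
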