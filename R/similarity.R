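#' @include AllClasses.R
NULL

# Shared engine for Jaccard/Tanimoto: both are |A ∩ B| / |A ∪ B| on binary
# profiles, computed with one cross-product.  Pairs whose union is empty get
# similarity 0 (no shared evidence), including the diagonal of all-zero rows.
.binaryOverlapSimilarity <- function(m, kind) {
  common <- tcrossprod(m)                      # c_ij = |row_i ∩ row_j|
  nset <- rowSums(m)                           # a_i = |row_i|
  union <- outer(nset, nset, "+") - common     # a + b - c
  s <- ifelse(union > 0, common / union, 0)
  diag(s)[nset > 0] <- 1                       # exact 1 on non-degenerate diag
  dimnames(s) <- list(rownames(m), rownames(m))
  new("SimilarityMatrix", sim = s, kind = kind)
}

#' Jaccard similarity between binary association profiles
#'
#' For entities `i` and `j` with binary attribute profiles, the similarity is
#' `|row_i ∩ row_j| / |row_i ∪ row_j|`.  Two all-zero profiles are defined to
#' have similarity 0 (no shared evidence implies no similarity).
#'
#' @param assoc an [AssociationMatrix-class].
#' @return a [SimilarityMatrix-class] of kind `"jaccard"`.
#' @examples
#' a <- AssociationMatrix(rbind(d1 = c(1, 1, 0), d2 = c(1, 0, 1)),
#'                        attributeIds = c("x", "y", "z"))
#' as.matrix(jaccardSimilarity(a))
#' @export
jaccardSimilarity <- function(assoc) {
  stopifnot(is(assoc, "AssociationMatrix"))
  .binaryOverlapSimilarity(as.matrix(assoc), "jaccard")
}

#' Tanimoto similarity between binary chemical fingerprints
#'
#' For fingerprints with `a` and `b` set bits and `c` bits in common, the
#' Tanimoto coefficient is `c / (a + b - c)`.  Pairs of all-zero fingerprints
#' are defined as 0 and flagged with a message.
#'
#' @param fingerprints an [AssociationMatrix-class] whose rows are drugs and
#'   whose columns are fingerprint bits.
#' @return a [SimilarityMatrix-class] of kind `"tanimoto"`.
#' @export
tanimotoSimilarity <- function(fingerprints) {
  stopifnot(is(fingerprints, "AssociationMatrix"))
  m <- as.matrix(fingerprints)
  empty <- sum(rowSums(m) == 0)
  if (empty > 0)
    message(empty, " all-zero fingerprint(s): their similarities are defined as 0")
  .binaryOverlapSimilarity(m, "tanimoto")
}

.AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V")

#' Smith-Waterman sequence similarity
#'
#' Computes all pairwise optimal local-alignment (Smith-Waterman) scores with
#' an affine gap penalty, then normalizes score `SW(i, j)` by
#' `sqrt(SW(i, i) * SW(j, j))` so that self-similarity is 1 and all values lie
#' in \[0, 1\] alongside the Jaccard and Tanimoto matrices.  Raw scores are
#' available with `normalize = FALSE` (returned matrix then rescaled by the
#' maximum raw score to stay a valid similarity object).
#'
#' Alignment is delegated to [Biostrings::pairwiseAlignment()] with
#' `type = "local"`; a gap of length L costs `gapOpening + L * gapExtension`.
#'
#' @param sequences a named [Biostrings::AAStringSet] or named character
#'   vector of amino-acid sequences (20-letter alphabet; `X` tolerated when
#'   `allowX = TRUE`).
#' @param substitutionMatrix scoring matrix name or matrix (default BLOSUM62).
#' @param gapOpening,gapExtension affine gap penalties (default 10 and 0.5).
#' @param normalize normalize by sqrt of self-scores (default TRUE).
#' @param allowX tolerate the ambiguity code `X` (default TRUE).
#' @return a [SimilarityMatrix-class] of kind `"smith_waterman"`.
#' @export
smithWatermanSimilarity <- function(sequences, substitutionMatrix = "BLOSUM62",
                                    gapOpening = 10, gapExtension = 0.5,
                                    normalize = TRUE, allowX = TRUE) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  stopifnot(is(sequences, "AAStringSet"))
  n <- length(sequences)
  ids <- names(sequences)
  if (n < 1L) stop("need at least one sequence")
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must carry unique names")
  chars <- as.character(sequences)
  if (any(nchar(chars) == 0L)) stop("empty sequence(s) present")
  ok <- .AA_ALPHABET20
  if (allowX) ok <- c(ok, "X")
  letters <- unique(unlist(strsplit(chars, "", fixed = TRUE)))
  if (!all(letters %in% ok))
    stop("unknown residue(s): ", paste(setdiff(letters, ok), collapse = ", "))
  if (is.character(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    substitutionMatrix <- get(substitutionMatrix, envir = e)
  }
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      sequences[j:n], sequences[[j]], type = "local",
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension,
      scoreOnly = TRUE)
    sc <- pmax(sc, 0)      # empty local alignment scores 0
    raw[j:n, j] <- sc
    raw[j, j:n] <- sc
  }
  if (normalize) {
    self <- diag(raw)
    if (any(self <= 0))
      stop("non-positive self-alignment score; cannot normalize")
    s <- raw / sqrt(outer(self, self))
    s <- pmin(pmax(s, 0), 1)
  } else {
    s <- if (max(raw) > 0) raw / max(raw) else raw
  }
  new("SimilarityMatrix", sim = s, kind = "smith_waterman")
}

#' Binarize a similarity matrix at threshold alpha
#'
#' An edge is placed between entities `i` and `j` iff `S_ij > alpha`
#' (strict inequality).  The diagonal is forced to 0 so that the resulting
#' network is a simple graph: self-similarity is not an edge.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param alpha threshold in \[0, 1).
#' @return a [BinaryNetwork-class].
#' @export
binarize <- function(sim, alpha) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("alpha must be a single value in [0, 1)")
  b <- (as.matrix(sim) > alpha) + 0
  diag(b) <- 0
  new("BinaryNetwork", adj = b, alpha = alpha)
}

#' Fuse binary networks into a homogeneous network
#'
#' Element-wise logical OR over the input networks ("see one, get one"):
#' the fused network has an edge wherever at least one source network does.
#' All inputs must share the same entities in the same order.
#'
#' @param nets non-empty (optionally named) list of [BinaryNetwork-class]
#'   objects over identical entity ids.
#' @return a [HomogeneousNetwork-class].
#' @export
fuseNetworks <- function(nets) {
  if (is(nets, "BinaryNetwork")) nets <- list(nets)
  if (!is.list(nets) || length(nets) == 0L)
    stop("'nets' must be a non-empty list of BinaryNetwork objects")
  if (!all(vapply(nets, is, logical(1), "BinaryNetwork")))
    stop("all elements must be BinaryNetwork objects")
  ids <- entityIds(nets[[1]])
  for (k in seq_along(nets)) {
    if (!identical(entityIds(nets[[k]]), ids))
      stop("network ", k, " has mismatched entity ids/ordering")
  }
  fused <- Reduce(pmax, lapply(nets, as.matrix))
  src <- names(nets)
  if (is.null(src)) src <- paste0("network", seq_along(nets))
  new("HomogeneousNetwork", adj = fused, sources = src)
}
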