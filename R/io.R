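#' @include AllClasses.R
NULL

#' Read a two-column edge list as a binary association matrix
#'
#' The file holds one `entity<TAB>attribute` association per line (no
#' header).  Entities or attributes absent from the file can be supplied
#' through `entityIds` / `attributeIds` so that all-zero rows are preserved.
#'
#' @param path TSV file path.
#' @param entityIds,attributeIds optional id universes (default: ids seen in
#'   the file, in order of first appearance).
#' @return an [AssociationMatrix-class].
#' @export
readAssociationTSV <- function(path, entityIds = NULL, attributeIds = NULL) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  if (is.null(entityIds)) entityIds <- unique(df[[1]])
  if (is.null(attributeIds)) attributeIds <- unique(df[[2]])
  i <- match(df[[1]], entityIds)
  j <- match(df[[2]], attributeIds)
  if (anyNA(i)) stop("entity id outside the given universe in ", path)
  if (anyNA(j)) stop("attribute id outside the given universe in ", path)
  m <- matrix(0, length(entityIds), length(attributeIds),
              dimnames = list(entityIds, attributeIds))
  m[cbind(i, j)] <- 1
  AssociationMatrix(m)
}

#' Write an association matrix as a two-column edge list
#'
#' @param assoc an [AssociationMatrix-class].
#' @param path output TSV path.
#' @export
writeAssociationTSV <- function(assoc, path) {
  m <- as.matrix(assoc)
  idx <- which(m == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read binary fingerprints (id TAB bitstring) as an association matrix
#'
#' @param path TSV file with one `id<TAB>bitstring` row per drug.
#' @return an [AssociationMatrix-class] with columns `bit1..bitB`.
#' @export
readFingerprintTSV <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  bits <- strsplit(df[[2]], "", fixed = TRUE)
  if (length(unique(lengths(bits))) != 1L)
    stop("fingerprint bitstrings must share one length")
  m <- do.call(rbind, lapply(bits, as.integer)) + 0
  dimnames(m) <- list(df[[1]], paste0("bit", seq_len(ncol(m))))
  AssociationMatrix(m)
}

#' Write fingerprints as id TAB bitstring
#'
#' @param fingerprints an [AssociationMatrix-class] of fingerprint bits.
#' @param path output path.
#' @export
writeFingerprintTSV <- function(fingerprints, path) {
  m <- as.matrix(fingerprints)
  df <- data.frame(rownames(m), apply(m, 1, paste, collapse = ""))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return a named [Biostrings::AAStringSet].
#' @export
readSequencesFASTA <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' Read a known drug-target interaction edge list
#'
#' @param path TSV with `drug<TAB>target` rows.
#' @return data.frame with columns `drug`, `target`.
#' @export
readInteractionTSV <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  setNames(df[, 1:2], c("drug", "target"))
}

#' Write / read a square matrix as TSV with id header row and column
#'
#' @param x matrix-like object (a similarity/adjacency S4 object or matrix).
#' @param path file path.
#' @export
writeMatrixTSV <- function(x, path) {
  m <- as.matrix(x)
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an embedding matrix as TSV (id plus d floats)
#'
#' @param embedding an [EmbeddingMatrix-class] (for writing).
#' @param path file path.
#' @export
writeEmbeddingTSV <- function(embedding, path) {
  m <- as.matrix(embedding)
  write.table(data.frame(id = rownames(m), m),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingTSV
#' @export
readEmbeddingTSV <- function(path) {
  df <- read.delim(path, header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  new("EmbeddingMatrix", vectors = m)
}
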