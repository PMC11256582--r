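#' @include io.R dtp.R
NULL

#' Configuration for the synthetic heterogeneous benchmark
#'
#' The generator partitions drugs and targets into clusters and makes every
#' data modality cluster-correlated: association profiles share attribute
#' blocks, fingerprints share bit blocks, sequences share an implanted
#' cluster motif, and interactions are planted between matched
#' (drug-cluster, target-cluster) pairs on top of a uniform background -
#' so similar drugs interact with similar targets, the assumption the
#' prediction method exploits.
#'
#' @param nDrugs,nTargets,nDiseases,nSideEffects entity counts
#'   (defaults 60, 90, 40, 30).
#' @param nDrugClusters,nTargetClusters planted cluster counts (default 4, 4).
#' @param fingerprintBits fingerprint length (default 128).
#' @param seqLength protein sequence length; the cluster motif has length
#'   `seqLength %/% 4` (default 120).
#' @param assocNoise bit-flip noise on drug-side association/fingerprint
#'   blocks (default 0.05).
#' @param targetAssocNoise flip noise for the target-side association
#'   networks (PPI, protein-disease); defaults to `assocNoise`.  Raising it
#'   towards 0.5 while keeping sequences clean yields a benchmark whose
#'   target-side signal is carried by the sequences alone.
#' @param interactionDensity probability of a planted interaction inside a
#'   matched cluster pair (default 0.7; the vignette derives the
#'   block-information ceiling on AUROC that motivates this choice).
#' @param backgroundDensity probability of a background interaction outside
#'   matched cluster pairs (default 0.002).
#' @param seed root seed; every artifact derives its own child seed so
#'   individual files are independently reproducible.
#' @return a list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nDrugs = 60, nTargets = 90, nDiseases = 40,
                        nSideEffects = 30, nDrugClusters = 4,
                        nTargetClusters = 4, fingerprintBits = 128,
                        seqLength = 120, assocNoise = 0.05,
                        targetAssocNoise = assocNoise,
                        interactionDensity = 0.7, backgroundDensity = 0.002,
                        seed = 1) {
  cfg <- list(nDrugs = nDrugs, nTargets = nTargets, nDiseases = nDiseases,
              nSideEffects = nSideEffects, nDrugClusters = nDrugClusters,
              nTargetClusters = nTargetClusters,
              fingerprintBits = fingerprintBits, seqLength = seqLength,
              assocNoise = assocNoise, targetAssocNoise = targetAssocNoise,
              interactionDensity = interactionDensity,
              backgroundDensity = backgroundDensity, seed = seed)
  if (nDrugClusters > nDrugs || nTargetClusters > nTargets)
    stop("cluster counts must not exceed entity counts")
  probs <- c(assocNoise, targetAssocNoise, interactionDensity,
             backgroundDensity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (nDiseases < max(nDrugClusters, nTargetClusters) ||
      nSideEffects < nDrugClusters || fingerprintBits < nDrugClusters)
    stop("need at least one attribute per cluster block")
  structure(cfg, class = "SynthConfig")
}

# Contiguous near-equal cluster assignment of n entities into k clusters.
.clusterAssign <- function(n, k) sort(rep_len(seq_len(k), n))

# Block-structured binary matrix: cell probability 1 - noise when the row
# cluster matches the column block, noise otherwise.
.blockAssoc <- function(rowCluster, colBlock, noise, seed) {
  p <- matrix(noise, length(rowCluster), length(colBlock))
  p[outer(rowCluster, colBlock, "==")] <- 1 - noise
  withSeed(seed, matrix(rbinom(length(p), 1L, p) + 0, nrow(p), ncol(p)))
}

.randomSeq <- function(n) paste(sample(.AA_ALPHABET20, n, TRUE), collapse = "")

#' Generate the synthetic heterogeneous drug-target benchmark
#'
#' Produces the full input bundle consumed by the pipeline: five association
#' edge lists (drug-drug, drug-side-effect, drug-disease, protein-protein,
#' protein-disease), binary fingerprints, protein sequences, the planted
#' known-interaction list and the ground-truth cluster map.  When `dir` is
#' given, everything is also written in the formats the pipeline reads (TSV
#' edge lists, fingerprint TSV, FASTA, interaction TSV, id lists and a
#' ground-truth JSON); a fixed seed yields byte-identical files.
#'
#' @param config a `"SynthConfig"` from [synthConfig()].
#' @param dir optional output directory.
#' @return invisible list with the association matrices, sequences,
#'   interactions, entity ids, cluster assignments and `config`.
#' @export
generateSyntheticData <- function(config = synthConfig(), dir = NULL) {
  stopifnot(inherits(config, "SynthConfig"))
  cfg <- config
  drugs <- sprintf("D%03d", seq_len(cfg$nDrugs))
  targets <- sprintf("T%03d", seq_len(cfg$nTargets))
  diseases <- sprintf("dis%03d", seq_len(cfg$nDiseases))
  sideEffects <- sprintf("se%03d", seq_len(cfg$nSideEffects))
  dc <- .clusterAssign(cfg$nDrugs, cfg$nDrugClusters)
  tc <- .clusterAssign(cfg$nTargets, cfg$nTargetClusters)

  # drug-drug interactions: denser within a cluster, symmetric, no self loops
  dd <- .blockAssoc(dc, dc, cfg$assocNoise, childSeed(cfg$seed, 1))
  dd[lower.tri(dd)] <- t(dd)[lower.tri(dd)]
  diag(dd) <- 0
  dimnames(dd) <- list(drugs, drugs)

  dse <- .blockAssoc(dc, .clusterAssign(cfg$nSideEffects, cfg$nDrugClusters),
                     cfg$assocNoise, childSeed(cfg$seed, 2))
  dimnames(dse) <- list(drugs, sideEffects)
  ddis <- .blockAssoc(dc, .clusterAssign(cfg$nDiseases, cfg$nDrugClusters),
                      cfg$assocNoise, childSeed(cfg$seed, 3))
  dimnames(ddis) <- list(drugs, diseases)
  fp <- .blockAssoc(dc, .clusterAssign(cfg$fingerprintBits, cfg$nDrugClusters),
                    cfg$assocNoise, childSeed(cfg$seed, 4))
  dimnames(fp) <- list(drugs, paste0("bit", seq_len(cfg$fingerprintBits)))

  ppi <- .blockAssoc(tc, tc, cfg$targetAssocNoise, childSeed(cfg$seed, 5))
  ppi[lower.tri(ppi)] <- t(ppi)[lower.tri(ppi)]
  diag(ppi) <- 0
  dimnames(ppi) <- list(targets, targets)
  pdis <- .blockAssoc(tc, .clusterAssign(cfg$nDiseases, cfg$nTargetClusters),
                      cfg$targetAssocNoise, childSeed(cfg$seed, 6))
  dimnames(pdis) <- list(targets, diseases)

  # sequences: random backbone with one cluster motif implanted per protein
  seqs <- withSeed(childSeed(cfg$seed, 7), {
    motifLen <- max(1L, cfg$seqLength %/% 4L)
    motifs <- vapply(seq_len(cfg$nTargetClusters),
                     function(k) .randomSeq(motifLen), character(1))
    vapply(seq_len(cfg$nTargets), function(t) {
      backbone <- .randomSeq(cfg$seqLength)
      pos <- sample.int(cfg$seqLength - motifLen + 1L, 1L)
      paste0(substr(backbone, 1, pos - 1), motifs[tc[t]],
             substr(backbone, pos + motifLen, cfg$seqLength))
    }, character(1))
  })
  sequences <- Biostrings::AAStringSet(setNames(seqs, targets))

  # planted interactions: drug cluster k binds target cluster k (mod), plus
  # a uniform background
  matched <- outer((dc - 1) %% cfg$nTargetClusters + 1, tc, "==")
  pInt <- ifelse(matched, cfg$interactionDensity, cfg$backgroundDensity)
  intMat <- withSeed(childSeed(cfg$seed, 8),
                     matrix(rbinom(length(pInt), 1L, pInt), nrow(pInt)))
  idx <- which(intMat == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  interactions <- data.frame(drug = drugs[idx[, 1]], target = targets[idx[, 2]],
                             stringsAsFactors = FALSE)

  bundle <- list(
    drugDrug = AssociationMatrix(dd),
    drugSideEffect = AssociationMatrix(dse),
    drugDisease = AssociationMatrix(ddis),
    fingerprints = AssociationMatrix(fp),
    ppi = AssociationMatrix(ppi),
    proteinDisease = AssociationMatrix(pdis),
    sequences = sequences,
    interactions = interactions,
    drugIds = drugs, targetIds = targets,
    clusters = list(drug = setNames(dc, drugs), target = setNames(tc, targets)),
    config = cfg
  )
  class(bundle) <- "SynthBundle"

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeAssociationTSV(bundle$drugDrug, file.path(dir, "drug_drug.tsv"))
    writeAssociationTSV(bundle$drugSideEffect,
                        file.path(dir, "drug_side_effect.tsv"))
    writeAssociationTSV(bundle$drugDisease, file.path(dir, "drug_disease.tsv"))
    writeFingerprintTSV(bundle$fingerprints, file.path(dir, "fingerprints.tsv"))
    writeAssociationTSV(bundle$ppi, file.path(dir, "ppi.tsv"))
    writeAssociationTSV(bundle$proteinDisease,
                        file.path(dir, "protein_disease.tsv"))
    Biostrings::writeXStringSet(sequences, file.path(dir, "sequences.fasta"))
    write.table(interactions, file.path(dir, "interactions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(drugs, file.path(dir, "drug_ids.txt"))
    writeLines(targets, file.path(dir, "target_ids.txt"))
    jsonlite::write_json(
      list(drugClusters = as.list(bundle$clusters$drug),
           targetClusters = as.list(bundle$clusters$target),
           config = unclass(cfg)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  invisible(bundle)
}
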