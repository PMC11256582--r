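#' @include synthetic.R crossval.R
NULL

.NETWORK_NAMES <- c("drugDrug", "drugSideEffect", "drugDisease",
                    "drugStructure", "ppi", "proteinDisease",
                    "proteinSequence")
.DRUG_NETWORKS <- c("drugDrug", "drugSideEffect", "drugDisease",
                    "drugStructure")
.TARGET_NETWORKS <- c("ppi", "proteinDisease", "proteinSequence")

#' End-to-end pipeline configuration
#'
#' Every hyperparameter carries the name used in the method: `alpha` for the
#' similarity binarization threshold, `K`/`fanouts` (S1, S2) for GraphSAGE,
#' `learningRate` for its Adam step.  Network-inclusion flags drive the
#' ablation modes: switching one off removes that similarity matrix from
#' the corresponding homogeneous-network fusion.
#'
#' @param inputDir directory with the input files (`drug_drug.tsv`,
#'   `drug_side_effect.tsv`, `drug_disease.tsv`, `fingerprints.tsv`,
#'   `ppi.tsv`, `protein_disease.tsv`, `sequences.fasta`,
#'   `interactions.tsv`, optional `drug_ids.txt` / `target_ids.txt`);
#'   may be NULL when an in-memory bundle is passed to [runPipeline()].
#' @param networks named logical vector of inclusion flags over
#'   `r paste(.NETWORK_NAMES, collapse = ", ")`; at least one drug-side and
#'   one target-side network must stay enabled.
#' @param alpha default binarization threshold in \[0, 1).
#' @param alphaOverrides named list of per-network alpha values.  The default
#'   lowers the sequence-network threshold to 0.15: self-score-normalized
#'   local-alignment similarities live on a much smaller scale than Jaccard
#'   profile overlaps, and a shared 0.5 would leave the sequence network
#'   empty (the logged edge densities are there to support this calibration).
#' @param deepwalk list of DeepWalk parameters (`dim`, `walkLength`,
#'   `walksPerNode`, `window`, `epochs`).
#' @param sage list of GraphSAGE parameters passed to [sageConfig()].
#' @param classifier `"rf"`, `"lr"` or `"svm"`.
#' @param eval list: `nFolds`, `sageMode` (`"per-fold"`/`"shared"`),
#'   `permuteLabels`.
#' @param topK length of the ranked prediction list (default 100).
#' @param seed root seed; stages derive child seeds.
#' @param outDir output/cache directory (default: none, no caching).
#' @param verbose emit stage log messages (default TRUE).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(inputDir = NULL,
                           networks = setNames(rep(TRUE, 7), .NETWORK_NAMES),
                           alpha = 0.5,
                           alphaOverrides = list(proteinSequence = 0.15),
                           deepwalk = list(), sage = list(),
                           classifier = "rf", eval = list(), topK = 100,
                           seed = 1, outDir = NULL, verbose = TRUE) {
  net <- setNames(rep(TRUE, length(.NETWORK_NAMES)), .NETWORK_NAMES)
  net[names(networks)] <- unlist(networks)
  if (!any(net[.DRUG_NETWORKS]))
    stop("at least one drug network must be enabled")
  if (!any(net[.TARGET_NETWORKS]))
    stop("at least one target network must be enabled")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  dw <- utils::modifyList(list(dim = 64, walkLength = 40, walksPerNode = 10,
                               window = 5, epochs = 5), deepwalk)
  sg <- utils::modifyList(list(K = 2, fanouts = c(50, 10),
                               aggregator = "mean", hiddenDim = 64,
                               learningRate = 0.001, epochs = 5,
                               batchSize = 256, subgraphOnly = FALSE), sage)
  ev <- utils::modifyList(list(nFolds = 5, sageMode = "per-fold",
                               permuteLabels = FALSE), eval)
  structure(list(inputDir = inputDir, networks = net, alpha = alpha,
                 alphaOverrides = alphaOverrides, deepwalk = dw, sage = sg,
                 classifier = classifier, eval = ev, topK = topK,
                 seed = seed, outDir = outDir, verbose = verbose),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the [pipelineConfig()] arguments (`networks`,
#' `alpha`, `deepwalk`, `graphsage`, `classifier`, `eval`, ...); the
#' `graphsage` block maps to the `sage` argument.
#'
#' @param path YAML file.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$graphsage)) {
    y$sage <- y$graphsage
    y$graphsage <- NULL
  }
  if (!is.null(y$networks)) y$networks <- unlist(y$networks)
  do.call(pipelineConfig, y)
}

# Load the on-disk input layout into the in-memory bundle shape.
.loadInputs <- function(config) {
  dir <- config$inputDir
  if (is.null(dir)) stop("no input directory and no in-memory data given")
  p <- function(f) file.path(dir, f)
  drugs <- if (file.exists(p("drug_ids.txt"))) readLines(p("drug_ids.txt"))
  targets <- if (file.exists(p("target_ids.txt"))) readLines(p("target_ids.txt"))
  net <- config$networks
  out <- list(drugIds = drugs, targetIds = targets)
  if (net[["drugDrug"]])
    out$drugDrug <- readAssociationTSV(p("drug_drug.tsv"), drugs, drugs)
  if (net[["drugSideEffect"]])
    out$drugSideEffect <- readAssociationTSV(p("drug_side_effect.tsv"), drugs)
  if (net[["drugDisease"]])
    out$drugDisease <- readAssociationTSV(p("drug_disease.tsv"), drugs)
  if (net[["drugStructure"]])
    out$fingerprints <- readFingerprintTSV(p("fingerprints.tsv"))
  if (net[["ppi"]])
    out$ppi <- readAssociationTSV(p("ppi.tsv"), targets, targets)
  if (net[["proteinDisease"]])
    out$proteinDisease <- readAssociationTSV(p("protein_disease.tsv"), targets)
  if (net[["proteinSequence"]])
    out$sequences <- readSequencesFASTA(p("sequences.fasta"))
  out$interactions <- readInteractionTSV(p("interactions.tsv"))
  if (is.null(out$drugIds))
    out$drugIds <- unique(c(unlist(lapply(out[.DRUG_NETWORKS], entityIds)),
                            rownames(as.matrix(out$fingerprints))))
  if (is.null(out$targetIds))
    out$targetIds <- unique(c(entityIds(out$ppi), entityIds(out$proteinDisease),
                              names(out$sequences)))
  out
}

# Stage runner with config-hash cache keys.  A stage whose key is unchanged
# is served from the RDS cache under outDir/cache.
.makeStageRunner <- function(config, log) {
  cacheDir <- if (!is.null(config$outDir)) {
    d <- file.path(config$outDir, "cache")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  run <- function(stage, key, compute, info = "") {
    t0 <- proc.time()[["elapsed"]]
    cached <- FALSE
    file <- if (!is.null(cacheDir))
      file.path(cacheDir, paste0(stage, "-", key, ".rds"))
    if (!is.null(file) && file.exists(file)) {
      value <- readRDS(file)
      cached <- TRUE
    } else {
      value <- tryCatch(compute(), error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
      if (!is.null(file)) saveRDS(value, file)
    }
    dt <- proc.time()[["elapsed"]] - t0
    log$rows[[length(log$rows) + 1L]] <- data.frame(
      stage = stage, seconds = round(dt, 2), cached = cached, info = info)
    if (isTRUE(config$verbose))
      message(sprintf("[%s] %.1fs%s %s", stage, dt,
                      if (cached) " (cached)" else "", info))
    value
  }
  run
}

#' Run the full prediction pipeline
#'
#' Executes similarity computation, binarization, fusion, DeepWalk
#' embedding, pair-network construction, balanced negative sampling,
#' cross-validated GraphSAGE + classifier evaluation and candidate ranking,
#' in that order.  Each stage's output is cached under `outDir/cache` with a
#' key hashing exactly its upstream inputs and parameters, so re-running
#' with (say) a different `alpha` reuses the similarity matrices but
#' recomputes everything downstream.
#'
#' @param config a `"PipelineConfig"`.
#' @param data optional in-memory bundle (as produced by
#'   [generateSyntheticData()]); when NULL, inputs are read from
#'   `config$inputDir`.
#' @return list of class `"PipelineResult"`: `report` (an
#'   [EvalReport-class]), `rankings`, `stageLog`, `homDrug`, `homTarget`,
#'   `drugEmbeddings`, `targetEmbeddings`, `index`, `sample`, `config`.
#' @export
runPipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(data)) data <- .loadInputs(config)
  log <- new.env()
  log$rows <- list()
  stage <- .makeStageRunner(config, log)
  net <- config$networks

  simSpecs <- list(
    drugDrug = list(side = "drug", fn = function(d) jaccardSimilarity(d$drugDrug)),
    drugSideEffect = list(side = "drug", fn = function(d) jaccardSimilarity(d$drugSideEffect)),
    drugDisease = list(side = "drug", fn = function(d) jaccardSimilarity(d$drugDisease)),
    drugStructure = list(side = "drug", fn = function(d) tanimotoSimilarity(d$fingerprints)),
    ppi = list(side = "target", fn = function(d) jaccardSimilarity(d$ppi)),
    proteinDisease = list(side = "target", fn = function(d) jaccardSimilarity(d$proteinDisease)),
    proteinSequence = list(side = "target", fn = function(d) smithWatermanSimilarity(d$sequences))
  )

  inputHash <- rlang::hash(list(data[intersect(names(data), .NETWORK_NAMES)],
                                data$fingerprints, data$sequences,
                                data$interactions, net))
  sims <- stage("similarity", inputHash, function() {
    out <- list()
    for (nm in .NETWORK_NAMES) {
      if (!net[[nm]]) next
      out[[nm]] <- simSpecs[[nm]]$fn(data)
    }
    out
  }, info = paste(sum(net), "networks"))

  alphaOf <- function(nm) {
    a <- config$alphaOverrides[[nm]]
    if (is.null(a)) config$alpha else a
  }
  bins <- stage("binarize",
                rlang::hash(list(inputHash, config$alpha, config$alphaOverrides)),
                function() {
    out <- lapply(names(sims), function(nm) binarize(sims[[nm]], alphaOf(nm)))
    names(out) <- names(sims)
    out
  }, info = paste0("alpha=", config$alpha))
  dens <- vapply(bins, function(b) .edgeDensity(as.matrix(b)), numeric(1))
  if (isTRUE(config$verbose))
    message("  edge densities: ",
            paste(sprintf("%s=%.3f", names(dens), dens), collapse = " "))

  fuseKey <- rlang::hash(list(inputHash, config$alpha, config$alphaOverrides))
  homDrug <- stage("fuseDrug", fuseKey, function()
    fuseNetworks(bins[intersect(names(bins), .DRUG_NETWORKS)]))
  homTarget <- stage("fuseTarget", fuseKey, function()
    fuseNetworks(bins[intersect(names(bins), .TARGET_NETWORKS)]))

  dw <- config$deepwalk
  embKey <- rlang::hash(list(fuseKey, dw, config$seed))
  drugEmb <- stage("embedDrug", embKey, function()
    do.call(embedNetwork, c(list(homDrug, seed = childSeed(config$seed, 11)), dw)))
  targetEmb <- stage("embedTarget", embKey, function()
    do.call(embedNetwork, c(list(homTarget, seed = childSeed(config$seed, 12)), dw)))

  index <- DTPIndex(entityIds(homDrug), entityIds(homTarget))
  labels <- dtpLabelsFromInteractions(index, data$interactions)
  samp <- stage("sampleBalanced",
                rlang::hash(list(rlang::hash(data$interactions), config$seed,
                                 inputHash)),
                function() sampleBalanced(labels, index,
                                          seed = childSeed(config$seed, 13)),
                info = paste(length(positivePairs(labels)), "positives"))

  sg <- config$sage
  sageCfg <- sageConfig(K = sg$K, fanouts = sg$fanouts,
                        aggregator = sg$aggregator, hiddenDim = sg$hiddenDim,
                        learningRate = sg$learningRate, epochs = sg$epochs,
                        batchSize = sg$batchSize,
                        seed = childSeed(config$seed, 14),
                        subgraphOnly = isTRUE(sg$subgraphOnly))
  cv <- stage("crossValidate",
              rlang::hash(list(embKey, sg, config$classifier, config$eval,
                               config$seed)),
              function() crossValidate(index, drugEmb, targetEmb, samp,
                                       sageCfg = sageCfg,
                                       classifier = config$classifier,
                                       nFolds = config$eval$nFolds,
                                       seed = childSeed(config$seed, 15),
                                       sageMode = config$eval$sageMode,
                                       permuteLabels = isTRUE(config$eval$permuteLabels)),
              info = paste0(config$eval$nFolds, "-fold ", config$classifier))

  rankings <- stage("rankPredictions",
                    rlang::hash(list(embKey, sg, config$classifier,
                                     config$seed, config$topK)),
                    function() {
    model <- sageTrain(index, drugEmb, targetEmb, samp$pairId, cv$labels,
                       sageCfg, neighborUniverse = samp$pairId)
    refined <- sageRefine(model, index, drugEmb, targetEmb, samp$pairId,
                          seed = childSeed(config$seed, 16),
                          neighborUniverse = samp$pairId)
    clf <- trainClassifier(refined$features, cv$labels,
                           kind = config$classifier,
                           seed = childSeed(config$seed, 17))
    candIds <- if (nPairs(index) <= 50000) {
      seq_len(nPairs(index)) - 1
    } else {
      samp$pairId
    }
    candFeats <- sageRefine(model, index, drugEmb, targetEmb, candIds,
                            seed = childSeed(config$seed, 18),
                            neighborUniverse =
                              if (sageCfg@subgraphOnly) samp$pairId)$features
    cand <- pairFromId(index, candIds)
    cand$label <- dtpLabel(labels, candIds)
    rankPredictions(clf, candFeats, cand, topK = config$topK)
  })

  result <- list(report = cv$report, rankings = rankings,
                 stageLog = do.call(rbind, log$rows),
                 homDrug = homDrug, homTarget = homTarget,
                 drugEmbeddings = drugEmb, targetEmbeddings = targetEmb,
                 index = index, sample = samp, cvScores = cv$scores,
                 cvLabels = cv$labels, config = config)
  class(result) <- "PipelineResult"

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    m <- reportMeans(cv$report)
    jsonlite::write_json(
      list(classifier = config$classifier, mean = as.list(m),
           folds = reportFolds(cv$report)),
      file.path(config$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.table(reportFolds(cv$report), file.path(config$outDir, "folds.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    write.table(rankings, file.path(config$outDir, "rankings.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeEmbeddingTSV(drugEmb, file.path(config$outDir, "drug_embeddings.tsv"))
    writeEmbeddingTSV(targetEmb,
                      file.path(config$outDir, "target_embeddings.tsv"))
  }
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  show(x$report)
  cat(sprintf("  %d ranked candidates; stage log:\n", nrow(x$rankings)))
  print(x$stageLog, row.names = FALSE)
  invisible(x)
}

#' Grid sweep over learning rate, aggregator and classifier
#'
#' Runs the pipeline once per distinct grid point (duplicates are removed by
#' configuration hash) and returns a tidy table with one row per grid point
#' per fold.  Upstream stages (similarity, fusion, embedding) are shared
#' through the cache when `outDir` is set, since the swept parameters only
#' affect downstream stages.
#'
#' @param config base `"PipelineConfig"`.
#' @param grid named list with any of `learningRate`, `aggregator`,
#'   `classifier` (vectors of values to cross).
#' @param data optional in-memory bundle, see [runPipeline()].
#' @return data.frame with columns `learningRate`, `aggregator`,
#'   `classifier`, `fold` and the six metrics.
#' @export
sweepPipeline <- function(config, grid, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  allowed <- c("learningRate", "aggregator", "classifier")
  if (!all(names(grid) %in% allowed))
    stop("grid entries must be among: ", paste(allowed, collapse = ", "))
  pts <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  seen <- character(0)
  rows <- list()
  for (r in seq_len(nrow(pts))) {
    cfg <- config
    if (!is.null(pts$learningRate))
      cfg$sage$learningRate <- pts$learningRate[r]
    if (!is.null(pts$aggregator)) cfg$sage$aggregator <- pts$aggregator[r]
    if (!is.null(pts$classifier)) cfg$classifier <- pts$classifier[r]
    key <- rlang::hash(list(cfg$sage, cfg$classifier))
    if (key %in% seen) next
    seen <- c(seen, key)
    res <- runPipeline(cfg, data = data)
    f <- reportFolds(res$report)
    f$learningRate <- cfg$sage$learningRate
    f$aggregator <- cfg$sage$aggregator
    f$classifier <- cfg$classifier
    rows[[length(rows) + 1L]] <- f
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("learningRate", "aggregator", "classifier", "fold",
          "auroc", "aupr", "accuracy", "precision", "recall", "f1")]
}
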