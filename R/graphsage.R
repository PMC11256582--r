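#' @include dtp.R
NULL

#' GraphSAGE configuration
#'
#' Defaults follow the two-layer design with fanouts `S1 = 50`, `S2 = 10`
#' (keeping `S1 * S2 <= 500`, beyond which a warning is emitted) and the mean
#' aggregator; the learning rate default is 0.001.  Hidden width, batch size
#' and epoch defaults are desk-scale choices discussed in the vignette.
#'
#' @param K number of layers (default 2).
#' @param fanouts neighbors sampled per layer, length `K` (default `c(50, 10)`).
#' @param aggregator `"mean"` (default), `"pooling"` or `"lstm"`.
#' @param hiddenDim hidden layer width (default 64).
#' @param learningRate Adam step size (default 0.001).
#' @param epochs training epochs (default 5).
#' @param batchSize minibatch size (default 256).
#' @param seed RNG seed for initialization, shuffling and neighbor sampling.
#' @param nonlinearity hidden nonlinearity: `"relu"` (default), `"tanh"`,
#'   `"identity"`.
#' @param subgraphOnly restrict neighbor sampling to a provided node universe
#'   instead of the full implicit pair network (default FALSE).
#' @return a [SageConfig-class].
#' @export
sageConfig <- function(K = 2, fanouts = c(50, 10), aggregator = "mean",
                       hiddenDim = 64, learningRate = 0.001, epochs = 5,
                       batchSize = 256, seed = 1, nonlinearity = "relu",
                       subgraphOnly = FALSE) {
  cfg <- new("SageConfig", K = as.integer(K), fanouts = as.integer(fanouts),
             aggregator = aggregator, hiddenDim = as.integer(hiddenDim),
             learningRate = learningRate, epochs = as.integer(epochs),
             batchSize = as.integer(batchSize), seed = as.numeric(seed),
             nonlinearity = nonlinearity, subgraphOnly = subgraphOnly)
  if (prod(cfg@fanouts) > 500)
    warning("prod(fanouts) > 500; two layers with S1*S2 <= 500 usually suffice")
  cfg
}

## ---- neighbor sampling -----------------------------------------------------

# Internal graph handle: either the full implicit pair network or a
# restricted universe (adjacency lists over a sampled node subset).
.sageGraphFull <- function(index) {
  list(type = "full", nd = nDrugs(index), nt = nTargets(index))
}

.sageGraphSubset <- function(index, universe) {
  nt <- nTargets(index)
  i0 <- universe %/% nt
  j0 <- universe %% nt
  byDrug <- split(seq_along(universe), i0)
  byTarget <- split(seq_along(universe), j0)
  nbrs <- vector("list", length(universe))
  for (k in seq_along(universe)) {
    cand <- c(byDrug[[as.character(i0[k])]], byTarget[[as.character(j0[k])]])
    nbrs[[k]] <- universe[setdiff(unique(cand), k)]
  }
  list(type = "subset", ids = universe, nbrs = nbrs,
       lookup = setNames(seq_along(universe), format(universe, scientific = FALSE, trim = TRUE)))
}

# Sample a fixed-size neighbor matrix (length(ids) x fanout) of pair ids.
# Without replacement when degree >= fanout, with replacement otherwise;
# an isolated node is padded with itself.  Uses R's RNG (caller seeds).
.sampleNbrMat <- function(graph, ids, fanout) {
  n <- length(ids)
  out <- matrix(0, n, fanout)
  if (graph$type == "full") {
    nd <- graph$nd
    nt <- graph$nt
    deg <- nd + nt - 2L
    i0 <- ids %/% nt
    j0 <- ids %% nt
    if (deg == 0L) return(matrix(rep(ids, fanout), n, fanout))
    r <- if (deg >= fanout) {
      t(vapply(seq_len(n), function(k) sample.int(deg, fanout),
               integer(fanout)))
    } else {
      matrix(sample.int(deg, n * fanout, replace = TRUE), n, fanout)
    }
    if (fanout == 1L) r <- matrix(r, n, 1L)
    i0m <- matrix(i0, n, fanout)
    j0m <- matrix(j0, n, fanout)
    sameDrug <- r <= (nt - 1L)
    jp <- r - 1
    jp[jp >= j0m] <- jp[jp >= j0m] + 1      # skip own target slot
    r2 <- r - (nt - 1L)
    ip <- r2 - 1
    ip[ip >= i0m] <- ip[ip >= i0m] + 1      # skip own drug slot
    out[sameDrug] <- (i0m * nt + jp)[sameDrug]
    out[!sameDrug] <- (ip * nt + j0m)[!sameDrug]
  } else {
    pos <- graph$lookup[format(ids, scientific = FALSE, trim = TRUE)]
    for (k in seq_len(n)) {
      nb <- graph$nbrs[[pos[k]]]
      d <- length(nb)
      out[k, ] <- if (d == 0L) rep(ids[k], fanout)
      else if (d >= fanout) nb[sample.int(d, fanout)]
      else nb[sample.int(d, fanout, replace = TRUE)]
    }
  }
  out
}

#' Sample a layered neighborhood tree for one pair node
#'
#' Layer 1 holds `fanouts[1]` neighbors of `u`; layer `k` holds `fanouts[k]`
#' neighbors of each layer `k-1` node.  Sampling is uniform without
#' replacement when the degree allows, with replacement otherwise, and an
#' isolated node is padded with itself.  The same seed yields the same tree.
#'
#' @param index a [DTPIndex-class].
#' @param u a single 0-based pair-node id.
#' @param fanouts per-layer sample sizes.
#' @param seed RNG seed.
#' @return list with elements `root` and `layers` (layer `k` is a matrix with
#'   one row per layer `k-1` node).
#' @export
sampleNeighborhood <- function(index, u, fanouts = c(50, 10), seed = 1) {
  stopifnot(is(index, "DTPIndex"), length(u) == 1L)
  .checkPairIds(index, u)
  graph <- .sageGraphFull(index)
  withSeed(seed, {
    layers <- vector("list", length(fanouts))
    cur <- u
    for (k in seq_along(fanouts)) {
      layers[[k]] <- .sampleNbrMat(graph, cur, fanouts[k])
      cur <- as.vector(t(layers[[k]]))
    }
    list(root = u, layers = layers)
  })
}

## ---- aggregators -----------------------------------------------------------

#' Mean aggregation of neighbor features
#'
#' @param neighborFeats matrix with one neighbor feature per row, or a list
#'   of equal-length numeric vectors.
#' @return element-wise arithmetic mean vector.
#' @export
aggregateMean <- function(neighborFeats) {
  if (is.list(neighborFeats)) neighborFeats <- do.call(rbind, neighborFeats)
  if (is.null(dim(neighborFeats)) || nrow(neighborFeats) == 0L)
    stop("need at least one neighbor feature")
  colMeans(neighborFeats)
}

# Grouped aggregator forward/backward.  F is (m * S) x d, node-major (the S
# rows of group g are contiguous).  Returns an m x d aggregate.
.aggForward <- function(aggregator, F, m, S, par) {
  if (aggregator == "mean") {
    out <- rowsum(F, rep(seq_len(m), each = S), reorder = FALSE) / S
    list(out = out, cache = list(m = m, S = S))
  } else if (aggregator == "pooling") {
    P <- sweep(F %*% t(par$W), 2, par$b, "+")
    A <- pmax(P, 0)
    d <- ncol(A)
    out <- matrix(-Inf, m, d)
    amax <- matrix(1L, m, d)
    base <- (seq_len(m) - 1L) * S
    for (s in seq_len(S)) {
      As <- A[base + s, , drop = FALSE]
      upd <- As > out
      out[upd] <- As[upd]
      amax[upd] <- s
    }
    list(out = out, cache = list(m = m, S = S, F = F, P = P, amax = amax))
  } else {  # lstm over the (already randomly ordered) neighbor sequence
    d <- ncol(F)
    dh <- d
    h <- matrix(0, m, dh)
    cs <- matrix(0, m, dh)
    steps <- vector("list", S)
    base <- (seq_len(m) - 1L) * S
    for (s in seq_len(S)) {
      xs <- F[base + s, , drop = FALSE]
      A <- sweep(cbind(xs, h) %*% t(par$W), 2, par$b, "+")
      ig <- stats::plogis(A[, seq_len(dh), drop = FALSE])
      fg <- stats::plogis(A[, dh + seq_len(dh), drop = FALSE])
      og <- stats::plogis(A[, 2 * dh + seq_len(dh), drop = FALSE])
      gg <- tanh(A[, 3 * dh + seq_len(dh), drop = FALSE])
      cNew <- fg * cs + ig * gg
      steps[[s]] <- list(xs = xs, hPrev = h, cPrev = cs,
                         i = ig, f = fg, o = og, g = gg, c = cNew)
      cs <- cNew
      h <- og * tanh(cNew)
    }
    list(out = h, cache = list(m = m, S = S, d = d, steps = steps))
  }
}

.aggBackward <- function(aggregator, dOut, cache, par, needInput = TRUE) {
  m <- cache$m
  S <- cache$S
  if (aggregator == "mean") {
    if (!needInput) return(list(dF = NULL, dPar = NULL))
    dF <- dOut[rep(seq_len(m), each = S), , drop = FALSE] / S
    list(dF = dF, dPar = NULL)
  } else if (aggregator == "pooling") {
    d <- ncol(dOut)
    dA <- matrix(0, m * S, d)
    rowIdx <- (row(cache$amax) - 1L) * S + cache$amax
    dA[cbind(as.vector(rowIdx), as.vector(col(cache$amax)))] <- as.vector(dOut)
    dP <- dA * (cache$P > 0)
    list(dF = dP %*% par$W,
         dPar = list(W = crossprod(dP, cache$F), b = colSums(dP)))
  } else {
    d <- cache$d
    dh <- d
    dW <- matrix(0, nrow(par$W), ncol(par$W))
    db <- numeric(length(par$b))
    dF <- matrix(0, m * S, d)
    dhAcc <- dOut
    dcAcc <- matrix(0, m, dh)
    base <- (seq_len(m) - 1L) * S
    for (s in rev(seq_len(S))) {
      st <- cache$steps[[s]]
      tc <- tanh(st$c)
      dog <- dhAcc * tc
      dc <- dcAcc + dhAcc * st$o * (1 - tc^2)
      dig <- dc * st$g
      dgg <- dc * st$i
      dfg <- dc * st$cPrev
      dcAcc <- dc * st$f
      dA <- cbind(dig * st$i * (1 - st$i), dfg * st$f * (1 - st$f),
                  dog * st$o * (1 - st$o), dgg * (1 - st$g^2))
      dW <- dW + crossprod(dA, cbind(st$xs, st$hPrev))
      db <- db + colSums(dA)
      dXH <- dA %*% par$W
      dF[base + s, ] <- dXH[, seq_len(d), drop = FALSE]
      dhAcc <- dXH[, d + seq_len(dh), drop = FALSE]
    }
    list(dF = dF, dPar = list(W = dW, b = db))
  }
}

## ---- elementary ops --------------------------------------------------------

.act <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), tanh = tanh(z), identity = z)
}

.actGrad <- function(z, kind) {
  switch(kind, relu = (z > 0) + 0, tanh = 1 - tanh(z)^2,
         identity = array(1, dim(z)))
}

#' Single-node GraphSAGE layer update
#'
#' Computes `sigma(W %*% c(hSelf, hNbr))`: the concatenation of a node's own
#' previous-layer feature with its aggregated neighbor feature, linearly
#' transformed and passed through the nonlinearity.  No per-layer L2
#' normalization is applied.
#'
#' @param hSelf,hNbr numeric vectors (previous-layer self and aggregated
#'   neighbor features).
#' @param W weight matrix with `length(hSelf) + length(hNbr)` columns.
#' @param nonlinearity `"relu"` (default), `"tanh"` or `"identity"`.
#' @return numeric vector of length `nrow(W)`.
#' @export
layerUpdate <- function(hSelf, hNbr, W, nonlinearity = "relu") {
  x <- c(hSelf, hNbr)
  if (ncol(W) != length(x))
    stop("weight matrix columns must match length(hSelf) + length(hNbr)")
  as.vector(.act(W %*% x, nonlinearity))
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y * log(yhat) + (1 - y) * log(1 - yhat))`, with predictions
#' clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param y 0/1 labels.
#' @param yhat predicted probabilities.
#' @return scalar loss.
#' @export
crossEntropy <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- parameters, forward, backward -----------------------------------------

.glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# Layer input dims: d0, hidden, hidden, ...; aggregator output dim equals the
# layer input dim, so W_k maps 2 * d_{k-1} -> d_k.
.sageInit <- function(cfg, inputDim) {
  dims <- c(inputDim, rep(cfg@hiddenDim, cfg@K))
  params <- list(W = vector("list", cfg@K), agg = vector("list", cfg@K))
  for (k in seq_len(cfg@K)) {
    params$W[[k]] <- .glorot(dims[k + 1], 2 * dims[k])
    if (cfg@aggregator == "pooling") {
      params$agg[[k]] <- list(W = .glorot(dims[k], dims[k]),
                              b = numeric(dims[k]))
    } else if (cfg@aggregator == "lstm") {
      d <- dims[k]
      b <- numeric(4 * d)
      b[d + seq_len(d)] <- 1       # forget-gate bias
      params$agg[[k]] <- list(W = .glorot(4 * d, 2 * d), b = b)
    } else {
      params$agg[[k]] <- list()
    }
  }
  params$headW <- .glorot(dims[cfg@K + 1], 1)
  params$headB <- 0
  params
}

# Batched forward over the layered node sets; uses the current RNG stream
# for neighbor sampling.  Returns scores, top-layer features and (optionally)
# the caches needed for backprop.  With the mean aggregator the bottom-layer
# neighbor means are computed as one sparse-matrix product over the unique
# sampled nodes instead of materializing every per-slot feature row.
.sageForward <- function(params, cfg, graph, featFn, ids, keepCache = FALSE) {
  K <- cfg@K
  meanBottom <- cfg@aggregator == "mean"
  nodes <- vector("list", K + 1)
  samp <- vector("list", K)
  nodes[[1]] <- ids
  for (d in seq_len(K)) {
    samp[[d]] <- .sampleNbrMat(graph, nodes[[d]], cfg@fanouts[d])
    nodes[[d + 1]] <- c(nodes[[d]], as.vector(t(samp[[d]])))
  }
  H <- if (!meanBottom) featFn(nodes[[K + 1]])
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    d <- K - k + 1
    m <- length(nodes[[d]])
    if (k == 1L && meanBottom) {
      S <- cfg@fanouts[d]
      Hself <- featFn(nodes[[d]])
      flat <- as.vector(t(samp[[d]]))
      u <- unique(flat)
      G <- Matrix::sparseMatrix(i = rep(seq_len(m), each = S),
                                j = match(flat, u), x = 1 / S,
                                dims = c(m, length(u)))
      agg <- list(out = as.matrix(G %*% featFn(u)),
                  cache = list(m = m, S = S))
    } else {
      Hself <- H[seq_len(m), , drop = FALSE]
      Hnbr <- H[(m + 1):nrow(H), , drop = FALSE]
      agg <- .aggForward(cfg@aggregator, Hnbr, m, cfg@fanouts[d],
                         params$agg[[k]])
    }
    dPrev <- ncol(Hself)
    W <- params$W[[k]]
    # Z = [Hself | agg] %*% t(W) without materializing the concatenation
    Z <- tcrossprod(Hself, W[, seq_len(dPrev), drop = FALSE]) +
      tcrossprod(agg$out, W[, dPrev + seq_len(dPrev), drop = FALSE])
    if (keepCache)
      caches[[k]] <- list(Hself = Hself, Hagg = agg$out, Z = Z,
                          agg = agg$cache, m = m, dimPrev = dPrev)
    H <- .act(Z, cfg@nonlinearity)
  }
  scores <- drop(H %*% params$headW) + params$headB
  list(scores = scores, h = H, caches = caches)
}

.sageBackward <- function(params, cfg, fwd, y) {
  n <- length(y)
  p <- stats::plogis(fwd$scores)
  ds <- (p - y) / n
  grads <- list(W = vector("list", cfg@K), agg = vector("list", cfg@K))
  grads$headW <- crossprod(fwd$h, ds)
  grads$headB <- sum(ds)
  dH <- matrix(ds, ncol = 1) %*% t(params$headW)
  for (k in rev(seq_len(cfg@K))) {
    cc <- fwd$caches[[k]]
    dZ <- dH * .actGrad(cc$Z, cfg@nonlinearity)
    grads$W[[k]] <- cbind(crossprod(dZ, cc$Hself), crossprod(dZ, cc$Hagg))
    W <- params$W[[k]]
    dAgg <- dZ %*% W[, cc$dimPrev + seq_len(cc$dimPrev), drop = FALSE]
    # at k = 1 the inputs are fixed initial features: only aggregator
    # parameter gradients are still needed, not input gradients
    needInput <- k > 1L
    ab <- .aggBackward(cfg@aggregator, dAgg, cc$agg, params$agg[[k]],
                       needInput = needInput ||
                         cfg@aggregator %in% c("pooling", "lstm"))
    grads$agg[k] <- list(ab$dPar)
    if (needInput) {
      dHself <- dZ %*% W[, seq_len(cc$dimPrev), drop = FALSE]
      dH <- rbind(dHself, ab$dF)
    }
  }
  grads
}

# Flatten nested parameter lists for the Adam update.
.flattenParams <- function(p) {
  out <- list(headW = p$headW, headB = p$headB)
  for (k in seq_along(p$W)) {
    out[[paste0("W", k)]] <- p$W[[k]]
    if (length(p$agg[[k]])) {
      out[[paste0("aggW", k)]] <- p$agg[[k]]$W
      out[[paste0("aggB", k)]] <- p$agg[[k]]$b
    }
  }
  out
}

.unflattenParams <- function(flat, template) {
  p <- template
  p$headW <- flat$headW
  p$headB <- flat$headB
  for (k in seq_along(p$W)) {
    p$W[[k]] <- flat[[paste0("W", k)]]
    if (length(p$agg[[k]])) {
      p$agg[[k]]$W <- flat[[paste0("aggW", k)]]
      p$agg[[k]]$b <- flat[[paste0("aggB", k)]]
    }
  }
  p
}

.adamStep <- function(flatP, flatG, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(flatG)) {
    g <- flatG[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    flatP[[nm]] <- flatP[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = flatP, state = state)
}

## ---- training and refinement -----------------------------------------------

# Closure computing initial pair features (drug || target embedding) for
# arbitrary pair ids, with id matching done once.
.makeFeatFn <- function(index, drugEmbeddings, targetEmbeddings) {
  dmat <- as.matrix(drugEmbeddings)
  tmat <- as.matrix(targetEmbeddings)
  di <- match(drugIds(index), rownames(dmat))
  tj <- match(targetIds(index), rownames(tmat))
  if (anyNA(di)) stop("missing drug embedding row(s)")
  if (anyNA(tj)) stop("missing target embedding row(s)")
  dmat <- dmat[di, , drop = FALSE]
  tmat <- tmat[tj, , drop = FALSE]
  nt <- nTargets(index)
  if (nPairs(index) <= 2e5) {
    # materialize all pair features once: one row gather per batch afterwards
    F0 <- cbind(dmat[rep(seq_len(nrow(dmat)), each = nt), , drop = FALSE],
                tmat[rep(seq_len(nt), nrow(dmat)), , drop = FALSE])
    function(ids) F0[ids + 1, , drop = FALSE]
  } else {
    function(ids) cbind(dmat[ids %/% nt + 1, , drop = FALSE],
                        tmat[ids %% nt + 1, , drop = FALSE])
  }
}

#' Train a supervised GraphSAGE on the implicit pair network
#'
#' Minibatch Adam training of the K-layer sample-and-aggregate architecture
#' with a sigmoid scoring head and binary cross-entropy loss.  Neighborhoods
#' are resampled every epoch.  Runs are reproducible for a fixed
#' configuration seed (single worker).  With `epochs = 0` the initialized
#' parameters are returned untrained.
#'
#' @param index a [DTPIndex-class].
#' @param drugEmbeddings,targetEmbeddings [EmbeddingMatrix-class] objects
#'   providing the initial pair features by concatenation.
#' @param trainIds 0-based pair ids of the labeled training nodes.
#' @param trainLabels 0/1 labels aligned with `trainIds`.
#' @param config a [SageConfig-class].
#' @param neighborUniverse optional pair-id vector; when
#'   `config@subgraphOnly` is TRUE, neighbor sampling is restricted to this
#'   set (defaults to `trainIds`).
#' @return a [SageModel-class].
#' @export
sageTrain <- function(index, drugEmbeddings, targetEmbeddings, trainIds,
                      trainLabels, config = sageConfig(),
                      neighborUniverse = NULL) {
  stopifnot(is(index, "DTPIndex"), is(config, "SageConfig"))
  if (length(trainIds) == 0L) stop("empty training sample")
  if (length(trainIds) != length(trainLabels))
    stop("trainIds and trainLabels must align")
  featFn <- .makeFeatFn(index, drugEmbeddings, targetEmbeddings)
  graph <- if (config@subgraphOnly) {
    uni <- if (is.null(neighborUniverse)) trainIds else neighborUniverse
    .sageGraphSubset(index, sort(unique(uni)))
  } else {
    .sageGraphFull(index)
  }
  inputDim <- ncol(as.matrix(drugEmbeddings)) + ncol(as.matrix(targetEmbeddings))
  withSeed(config@seed, {
    params <- .sageInit(config, inputDim)
    state <- list(m = list(), v = list())
    t <- 0L
    losses <- numeric(config@epochs)
    for (ep in seq_len(config@epochs)) {
      ord <- sample(length(trainIds))
      starts <- seq(1L, length(ord), by = config@batchSize)
      batchLoss <- numeric(length(starts))
      for (b in seq_along(starts)) {
        sel <- ord[starts[b]:min(starts[b] + config@batchSize - 1L,
                                 length(ord))]
        fwd <- .sageForward(params, config, graph, featFn, trainIds[sel],
                            keepCache = TRUE)
        p <- stats::plogis(fwd$scores)
        loss <- crossEntropy(trainLabels[sel], p)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep, ", batch ", b,
               " (learning rate too high or degenerate features?)")
        batchLoss[b] <- loss
        grads <- .sageBackward(params, config, fwd, trainLabels[sel])
        t <- t + 1L
        upd <- .adamStep(.flattenParams(params), .flattenParams(grads),
                         state, config@learningRate, t)
        params <- .unflattenParams(upd$p, params)
        state <- upd$state
      }
      losses[ep] <- mean(batchLoss)
    }
    new("SageModel", params = params, config = config,
        inputDim = as.integer(inputDim), losses = losses)
  })
}

#' Refined pair features and interaction scores from a trained GraphSAGE
#'
#' Computes the top-layer representation (the refined pair feature fed to the
#' downstream classifier) and the sigmoid head score for the requested pair
#' nodes, sampling fresh neighborhoods under `seed`.
#'
#' @param model a [SageModel-class].
#' @param index,drugEmbeddings,targetEmbeddings as in [sageTrain()].
#' @param ids 0-based pair ids to refine.
#' @param seed RNG seed for neighbor sampling.
#' @param neighborUniverse see [sageTrain()].
#' @param batchSize refinement batch size (default from the model config).
#' @return list with `features` (matrix, rownames = pair ids) and `scores`
#'   (head probabilities).
#' @export
sageRefine <- function(model, index, drugEmbeddings, targetEmbeddings, ids,
                       seed = 1, neighborUniverse = NULL, batchSize = NULL) {
  stopifnot(is(model, "SageModel"))
  cfg <- model@config
  featFn <- .makeFeatFn(index, drugEmbeddings, targetEmbeddings)
  graph <- if (cfg@subgraphOnly) {
    uni <- if (is.null(neighborUniverse)) ids else neighborUniverse
    .sageGraphSubset(index, sort(unique(uni)))
  } else {
    .sageGraphFull(index)
  }
  if (is.null(batchSize)) batchSize <- cfg@batchSize
  withSeed(seed, {
    starts <- seq(1L, length(ids), by = batchSize)
    feats <- NULL
    scores <- numeric(length(ids))
    for (b in seq_along(starts)) {
      sel <- starts[b]:min(starts[b] + batchSize - 1L, length(ids))
      fwd <- .sageForward(model@params, cfg, graph, featFn, ids[sel])
      if (is.null(feats))
        feats <- matrix(0, length(ids), ncol(fwd$h))
      feats[sel, ] <- fwd$h
      scores[sel] <- stats::plogis(fwd$scores)
    }
    rownames(feats) <- format(ids, scientific = FALSE, trim = TRUE)
    list(features = feats, scores = scores)
  })
}
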