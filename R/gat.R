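# Multi-head graph attention: vectorised forward and hand-derived backward
# passes over batches of joint graphs.
#
# A "graph batch" stacks several joint graphs block-diagonally: node features
# are concatenated, edges are stored as directed (src -> dst) index pairs
# covering both directions of every undirected edge plus one self-loop per
# node (so each node attends to itself), and a graphId column drives the
# per-graph pooling.  All per-edge operations are vectorised with rowsum()
# grouped by dst/src; because every node has a self-loop, the grouped results
# align row-for-row with node indices.

.graphPiece <- function(joint) {
  n <- nAtoms(joint)
  e <- edgeMatrix(joint)
  src <- c(e[, 1], e[, 2], seq_len(n))
  dst <- c(e[, 2], e[, 1], seq_len(n))
  list(X = nodeFeatures(joint), src = src, dst = dst, n = n)
}

.assembleGraphBatch <- function(pieces, which = seq_along(pieces)) {
  ns <- vapply(pieces[which], `[[`, 0L, "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(pieces[which], `[[`, "X"))
  src <- unlist(Map(function(p, o) p$src + o, pieces[which], off), use.names = FALSE)
  dst <- unlist(Map(function(p, o) p$dst + o, pieces[which], off), use.names = FALSE)
  N <- sum(ns)
  list(
    X = X, src = src, dst = dst, N = N, nGraphs = length(which),
    graphId = rep(seq_along(which), ns),
    dstSplit = split(seq_along(dst), dst),
    poolSplit = split(seq_len(N), rep(seq_along(which), ns)),
    sizes = as.numeric(ns)
  )
}

# One GAT layer: multi-head attention with LeakyReLU-scored, softmax-
# normalised coefficients over each node's in-neighbourhood (self included),
# heads concatenated, ReLU activation.
.gatLayer <- function(H, gb, W, aS, aD, keepAttention = FALSE) {
  heads <- ncol(aS)
  dh <- nrow(aS)
  P <- H %*% W
  pre <- matrix(0, gb$N, heads * dh)
  alpha <- matrix(0, length(gb$src), heads)
  raw <- matrix(0, length(gb$src), heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    Pk <- P[, cols, drop = FALSE]
    sS <- drop(Pk %*% aS[, k])
    sD <- drop(Pk %*% aD[, k])
    rawk <- sD[gb$dst] + sS[gb$src]
    ek <- .lrelu(rawk)
    mx <- vapply(gb$dstSplit, function(ix) max(ek[ix]), 0)
    ex <- exp(ek - mx[gb$dst])
    den <- drop(rowsum(ex, gb$dst))
    al <- ex / den[gb$dst]
    pre[, cols] <- rowsum(al * Pk[gb$src, , drop = FALSE], gb$dst)
    alpha[, k] <- al
    raw[, k] <- rawk
  }
  out <- .relu(pre)
  cache <- list(H = H, P = P, alpha = alpha, raw = raw, pre = pre)
  if (keepAttention) cache$attention <- alpha
  list(out = out, cache = cache)
}

.gatLayerBackward <- function(dAct, cache, gb, W, aS, aD) {
  heads <- ncol(aS)
  dh <- nrow(aS)
  dPre <- dAct * (cache$pre > 0)
  dP <- matrix(0, gb$N, heads * dh)
  daS <- matrix(0, dh, heads)
  daD <- matrix(0, dh, heads)
  for (k in seq_len(heads)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    Pk <- cache$P[, cols, drop = FALSE]
    al <- cache$alpha[, k]
    rawk <- cache$raw[, k]
    dOk <- dPre[, cols, drop = FALSE]
    dODst <- dOk[gb$dst, , drop = FALSE]
    PkSrc <- Pk[gb$src, , drop = FALSE]
    dal <- rowSums(dODst * PkSrc)
    dPagg <- rowsum(al * dODst, gb$src)
    gsum <- drop(rowsum(al * dal, gb$dst))
    de <- al * (dal - gsum[gb$dst])
    draw <- de * ifelse(rawk > 0, 1, 0.2)
    dsD <- drop(rowsum(draw, gb$dst))
    dsS <- drop(rowsum(draw, gb$src))
    dP[, cols] <- dPagg + outer(dsS, aS[, k]) + outer(dsD, aD[, k])
    daS[, k] <- drop(crossprod(Pk, dsS))
    daD[, k] <- drop(crossprod(Pk, dsD))
  }
  list(
    dH = dP %*% t(W),
    dW = crossprod(cache$H, dP),
    daS = daS, daD = daD
  )
}

# Graph-wise global pooling of node embeddings.
.poolForward <- function(H, gb, type) {
  D <- ncol(H)
  if (type == "mean") {
    Z <- rowsum(H, gb$graphId) / gb$sizes
    return(list(Z = Z, cache = NULL))
  }
  Z <- matrix(0, gb$nGraphs, D)
  argRow <- matrix(0L, gb$nGraphs, D)
  for (g in seq_len(gb$nGraphs)) {
    idx <- gb$poolSplit[[g]]
    sub <- H[idx, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    argRow[g, ] <- idx[w]
    Z[g, ] <- sub[cbind(w, seq_len(D))]
  }
  list(Z = Z, cache = argRow)
}

.poolBackward <- function(dZ, cache, gb, type, D) {
  dH <- matrix(0, gb$N, D)
  if (type == "mean") {
    dH <- (dZ / gb$sizes)[gb$graphId, , drop = FALSE]
    return(dH)
  }
  rows <- as.vector(t(cache))
  cols <- rep(seq_len(D), gb$nGraphs)
  dH[cbind(rows, cols)] <- as.vector(t(dZ))
  dH
}

# Full three-layer GAT + pooling over a graph batch.
.gatForward <- function(gatWeights, gb, pool, keepCache = FALSE, keepAttention = FALSE) {
  H <- gb$X
  caches <- vector("list", length(gatWeights))
  attn <- if (keepAttention) vector("list", length(gatWeights)) else NULL
  for (l in seq_along(gatWeights)) {
    wl <- gatWeights[[l]]
    r <- .gatLayer(H, gb, wl$W, wl$aS, wl$aD, keepAttention = keepAttention)
    H <- r$out
    caches[[l]] <- r$cache
    if (keepAttention) attn[[l]] <- r$cache$alpha
  }
  pooled <- .poolForward(H, gb, pool)
  list(
    Z = pooled$Z, caches = if (keepCache) caches else NULL,
    poolCache = pooled$cache, attention = attn, Hfinal = H
  )
}

.gatBackward <- function(dZ, fw, gatWeights, gb, pool) {
  D <- ncol(fw$Hfinal)
  dH <- .poolBackward(dZ, fw$poolCache, gb, pool, D)
  grads <- vector("list", length(gatWeights))
  for (l in rev(seq_along(gatWeights))) {
    wl <- gatWeights[[l]]
    bk <- .gatLayerBackward(dH, fw$caches[[l]], gb, wl$W, wl$aS, wl$aD)
    grads[[l]] <- list(W = bk$dW, aS = bk$daS, aD = bk$daD)
    dH <- bk$dH
  }
  grads
}

#' Graph-attention embedding of a joint graph
#'
#' Runs the model's three-layer multi-head graph attention network over one
#' joint graph and returns the pooled combination embedding, optionally with
#' the per-layer attention coefficients (one row per directed edge incl.
#' self-loops, one column per head; rows for a node's in-neighbourhood sum
#' to one).
#'
#' @param model a [SynergyModel-class].
#' @param joint a [JointGraph-class].
#' @param returnAttention if `TRUE`, also return attention coefficients and
#'   the directed edge list they refer to.
#' @return the embedding vector, or (with `returnAttention`) a list with
#'   `embedding`, `attention` (list per layer) and `edges` (data.frame with
#'   `src`, `dst`).
#' @export
gatEmbed <- function(model, joint, returnAttention = FALSE) {
  stopifnot(is(model, "SynergyModel"), is(joint, "JointGraph"))
  gb <- .assembleGraphBatch(list(.graphPiece(joint)))
  fw <- .gatForward(model@weights$gat, gb, model@config$pool,
    keepAttention = returnAttention
  )
  if (!returnAttention) {
    return(drop(fw$Z))
  }
  list(
    embedding = drop(fw$Z), attention = fw$attention,
    edges = data.frame(src = gb$src, dst = gb$dst)
  )
}
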