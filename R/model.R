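# The dual-view network: configuration, weight initialisation, full forward
# and hand-derived backward passes, and triplet prediction.

#' Model configuration
#'
#' Architecture settings of the dual-view network.  The depth of the three
#' sub-networks is fixed by the model definition (three GAT layers, a
#' two-layer cell MLP, three prediction-net ReLU layers before the output
#' layer); widths, head count, pooling, dropout and task are tunable.
#'
#' @param task `regression` (linear output head, squared-error loss) or
#'   `classification` (two-class softmax head, cross-entropy loss).
#' @param gatHeads number of attention heads per GAT layer.
#' @param gatHidden per-head hidden width; the combination embedding has
#'   dimension `gatHeads * gatHidden`.
#' @param pool global pooling over joint-graph nodes, `max` or `mean`.
#' @param cellMlpDims widths of the two cell-encoder layers.
#' @param dcDim width of the shared drug-on-cell encoder (view 2).
#' @param embedDim width of the two view embeddings `z_ec` and `z_ce`.
#' @param prednetDims widths of the three prediction-net ReLU layers.
#' @param dropout dropout probability on hidden MLP activations during
#'   training (0 disables).
#' @param seed seed for weight initialisation.
#' @return a validated configuration list of class `synergyConfig`.
#' @export
synergyConfig <- function(task = c("regression", "classification"),
                          gatHeads = 4L, gatHidden = 64L, pool = c("max", "mean"),
                          cellMlpDims = c(512L, 256L), dcDim = 256L,
                          embedDim = 256L, prednetDims = c(256L, 128L, 64L),
                          dropout = 0.2, seed = 1L) {
  task <- match.arg(task)
  pool <- match.arg(pool)
  stopifnot(
    .isCount(gatHeads) && gatHeads >= 1, .isCount(gatHidden) && gatHidden >= 1,
    length(cellMlpDims) == 2L, all(cellMlpDims >= 1),
    length(prednetDims) == 3L, all(prednetDims >= 1),
    .isCount(dcDim) && dcDim >= 1, .isCount(embedDim) && embedDim >= 1,
    dropout >= 0, dropout < 1
  )
  structure(
    list(
      task = task, gatLayers = 3L, gatHeads = as.integer(gatHeads),
      gatHidden = as.integer(gatHidden), pool = pool,
      cellMlpDims = as.integer(cellMlpDims), dcDim = as.integer(dcDim),
      embedDim = as.integer(embedDim), prednetDims = as.integer(prednetDims),
      dropout = dropout, seed = as.integer(seed)
    ),
    class = "synergyConfig"
  )
}

.glorot <- function(fanIn, fanOut) {
  l <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -l, l), fanIn, fanOut)
}

.initWeights <- function(config, nGenes, fpBits) {
  gatOut <- config$gatHeads * config$gatHidden
  gat <- vector("list", config$gatLayers)
  din <- 78L
  for (l in seq_len(config$gatLayers)) {
    gat[[l]] <- list(
      W = .glorot(din, gatOut),
      aS = .glorot(config$gatHidden, config$gatHeads),
      aD = .glorot(config$gatHidden, config$gatHeads)
    )
    din <- gatOut
  }
  cd <- config$cellMlpDims
  outDim <- if (config$task == "classification") 2L else 1L
  pd <- config$prednetDims
  list(
    gat = gat,
    cell = list(
      W1 = .glorot(nGenes, cd[1]), b1 = numeric(cd[1]),
      W2 = .glorot(cd[1], cd[2]), b2 = numeric(cd[2])
    ),
    ec = list(W = .glorot(gatOut + cd[2], config$embedDim), b = numeric(config$embedDim)),
    dc = list(W = .glorot(cd[2] + fpBits, config$dcDim), b = numeric(config$dcDim)),
    ce = list(W = .glorot(2L * config$dcDim, config$embedDim), b = numeric(config$embedDim)),
    pred = list(
      W1 = .glorot(2L * config$embedDim, pd[1]), b1 = numeric(pd[1]),
      W2 = .glorot(pd[1], pd[2]), b2 = numeric(pd[2]),
      W3 = .glorot(pd[2], pd[3]), b3 = numeric(pd[3]),
      Wout = .glorot(pd[3], outDim), bout = numeric(outDim)
    )
  )
}

#' Initialise an untrained dual-view model
#'
#' Draws Glorot-uniform weights with the configuration's seed.  The scaler
#' fixes the gene panel (and hence the cell-encoder input width); fingerprint
#' length and join method are frozen into the model so that prediction-time
#' features can be checked for compatibility.
#'
#' @param config a [synergyConfig()] list.
#' @param scaler an [ExpressionScaler-class] fitted on the training cells.
#' @param fpBits fingerprint length the model consumes.
#' @param joinMethod joint-graph construction method (see [joinGraphs()]).
#' @return an untrained [SynergyModel-class].
#' @export
initSynergyModel <- function(config, scaler, fpBits = 1024L,
                             joinMethod = c(
                               "super_edge", "all_nodes",
                               "one_super_node", "three_super_nodes"
                             )) {
  joinMethod <- match.arg(joinMethod)
  stopifnot(inherits(config, "synergyConfig"), is(scaler, "ExpressionScaler"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  w <- .initWeights(config, length(scaler@panel), as.integer(fpBits))
  new("SynergyModel",
    weights = w, config = unclass(config), scaler = scaler,
    fpBits = as.integer(fpBits), joinMethod = joinMethod,
    history = data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  )
}

.denseForward <- function(X, W, b, relu = TRUE) {
  pre <- X %*% W
  pre <- sweep(pre, 2L, b, "+")
  list(out = if (relu) .relu(pre) else pre, pre = pre, X = X)
}

# Backward through a dense layer; dPost is the gradient at the (post-ReLU)
# output when relu=TRUE, at the pre-activation otherwise.
.denseBackward <- function(dPost, cache, W, relu = TRUE) {
  dPre <- if (relu) dPost * (cache$pre > 0) else dPost
  list(
    dX = dPre %*% t(W),
    dW = crossprod(cache$X, dPre),
    db = colSums(dPre)
  )
}

.dropoutMask <- function(nr, nc, p) {
  if (p <= 0) {
    return(NULL)
  }
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

.applyMask <- function(x, mask) if (is.null(mask)) x else x * mask

# Forward pass over a prepared batch.  `gb` holds the joint graphs of the
# ordered pairs referenced by pairIdx; Xcell/FpA/FpB have one row per record.
.modelForward <- function(weights, config, gb, pairIdx, Xcell, FpA, FpB,
                          training = FALSE, keepCache = FALSE) {
  dropP <- if (training) config$dropout else 0
  gat <- .gatForward(weights$gat, gb, config$pool, keepCache = keepCache)
  Zab <- gat$Z[pairIdx, , drop = FALSE]
  B <- nrow(Xcell)

  c1 <- .denseForward(Xcell, weights$cell$W1, weights$cell$b1)
  m1 <- .dropoutMask(B, ncol(c1$out), dropP)
  h1 <- .applyMask(c1$out, m1)
  c2 <- .denseForward(h1, weights$cell$W2, weights$cell$b2)
  m2 <- .dropoutMask(B, ncol(c2$out), dropP)
  zcell <- .applyMask(c2$out, m2)

  ec <- .denseForward(cbind(Zab, zcell), weights$ec$W, weights$ec$b)
  dcA <- .denseForward(cbind(zcell, FpA), weights$dc$W, weights$dc$b)
  dcB <- .denseForward(cbind(zcell, FpB), weights$dc$W, weights$dc$b)
  ce <- .denseForward(cbind(dcA$out, dcB$out), weights$ce$W, weights$ce$b)

  p1 <- .denseForward(cbind(ec$out, ce$out), weights$pred$W1, weights$pred$b1)
  mp1 <- .dropoutMask(B, ncol(p1$out), dropP)
  h3 <- .applyMask(p1$out, mp1)
  p2 <- .denseForward(h3, weights$pred$W2, weights$pred$b2)
  mp2 <- .dropoutMask(B, ncol(p2$out), dropP)
  h4 <- .applyMask(p2$out, mp2)
  p3 <- .denseForward(h4, weights$pred$W3, weights$pred$b3)
  mp3 <- .dropoutMask(B, ncol(p3$out), dropP)
  h5 <- .applyMask(p3$out, mp3)
  outLayer <- .denseForward(h5, weights$pred$Wout, weights$pred$bout, relu = FALSE)
  out <- outLayer$pre

  probs <- NULL
  if (config$task == "classification") {
    mx <- apply(out, 1L, max)
    ex <- exp(out - mx)
    probs <- ex / rowSums(ex)
  }
  list(
    out = out, probs = probs, gat = gat, Zab = Zab,
    c1 = c1, c2 = c2, m1 = m1, m2 = m2, zcell = zcell,
    ec = ec, dcA = dcA, dcB = dcB, ce = ce,
    p1 = p1, p2 = p2, p3 = p3, mp1 = mp1, mp2 = mp2, mp3 = mp3,
    h3 = h3, h4 = h4, h5 = h5, outLayer = outLayer
  )
}

# Backward pass from the gradient at the output layer's pre-activation.
.modelBackward <- function(dOut, fw, weights, config, gb, pairIdx) {
  g <- list()
  bo <- .denseBackward(dOut, fw$outLayer, weights$pred$Wout, relu = FALSE)
  dH5 <- .applyMask(bo$dX, fw$mp3)
  b3 <- .denseBackward(dH5, fw$p3, weights$pred$W3)
  dH4 <- .applyMask(b3$dX, fw$mp2)
  b2 <- .denseBackward(dH4, fw$p2, weights$pred$W2)
  dH3 <- .applyMask(b2$dX, fw$mp1)
  b1 <- .denseBackward(dH3, fw$p1, weights$pred$W1)
  g$pred <- list(
    W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
    W3 = b3$dW, b3 = b3$db, Wout = bo$dW, bout = bo$db
  )

  embedDim <- config$embedDim
  dZec <- b1$dX[, seq_len(embedDim), drop = FALSE]
  dZce <- b1$dX[, embedDim + seq_len(embedDim), drop = FALSE]

  bce <- .denseBackward(dZce, fw$ce, weights$ce$W)
  g$ce <- list(W = bce$dW, b = bce$db)
  dcDim <- config$dcDim
  dDcA <- bce$dX[, seq_len(dcDim), drop = FALSE]
  dDcB <- bce$dX[, dcDim + seq_len(dcDim), drop = FALSE]
  bdcA <- .denseBackward(dDcA, fw$dcA, weights$dc$W)
  bdcB <- .denseBackward(dDcB, fw$dcB, weights$dc$W)
  g$dc <- list(W = bdcA$dW + bdcB$dW, b = bdcA$db + bdcB$db)

  bec <- .denseBackward(dZec, fw$ec, weights$ec$W)
  g$ec <- list(W = bec$dW, b = bec$db)
  gatOut <- ncol(fw$Zab)
  dZab <- bec$dX[, seq_len(gatOut), drop = FALSE]

  nCell <- ncol(fw$zcell)
  dZcell <- bec$dX[, gatOut + seq_len(nCell), drop = FALSE] +
    bdcA$dX[, seq_len(nCell), drop = FALSE] +
    bdcB$dX[, seq_len(nCell), drop = FALSE]
  dC2 <- .applyMask(dZcell, fw$m2)
  bc2 <- .denseBackward(dC2, fw$c2, weights$cell$W2)
  dC1 <- .applyMask(bc2$dX, fw$m1)
  bc1 <- .denseBackward(dC1, fw$c1, weights$cell$W1)
  g$cell <- list(W1 = bc1$dW, b1 = bc1$db, W2 = bc2$dW, b2 = bc2$db)

  # scatter record-level gradients back onto the unique pair embeddings
  dZ <- rowsum(dZab, pairIdx)
  dZfull <- matrix(0, gb$nGraphs, gatOut)
  dZfull[as.integer(rownames(dZ)), ] <- dZ
  g$gat <- .gatBackward(dZfull, fw$gat, weights$gat, gb, config$pool)
  g
}

# Loss and output-layer gradient for a batch.
.lossAndGrad <- function(fw, y, task) {
  B <- nrow(fw$out)
  if (task == "regression") {
    r <- drop(fw$out) - y
    list(loss = mean(r^2), dOut = matrix(2 * r / B, B, 1))
  } else {
    p <- fw$probs
    eps <- 1e-12
    loss <- -mean(log(p[cbind(seq_len(B), y)] + eps))
    dOut <- p
    dOut[cbind(seq_len(B), y)] <- dOut[cbind(seq_len(B), y)] - 1
    list(loss = loss, dOut = dOut / B)
  }
}
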