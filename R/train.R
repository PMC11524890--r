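# Optimiser loop, fine-tuning and prediction.

#' Training control settings
#'
#' Optimiser and schedule settings for [trainSynergyModel()] and
#' [fineTuneModel()].  The loss follows the model task: squared error for
#' regression, cross-entropy for classification.  Optimisation uses Adam.
#'
#' @param lr learning rate (default 1e-4; [fineTuneModel()] defaults to
#'   1e-5).
#' @param epochs maximum number of epochs.
#' @param batchSize minibatch size; `Inf` trains full-batch.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement) when a validation split exists; `Inf` disables.
#' @param valFraction fraction of training records held out for validation
#'   (0 disables early stopping and validation tracking).
#' @param stopLossFraction optional: stop once the training loss falls below
#'   this fraction of the first epoch's loss.
#' @param seed seed for shuffling, dropout and the validation split.
#' @param verbose print a progress line every `verboseEvery` epochs.
#' @param verboseEvery see `verbose`.
#' @return a control list of class `trainControl`.
#' @export
trainControl <- function(lr = 1e-4, epochs = 100L, batchSize = 128,
                         patience = 10L, valFraction = 0.1,
                         stopLossFraction = NULL, seed = 1L,
                         verbose = FALSE, verboseEvery = 10L) {
  stopifnot(lr > 0, epochs >= 1, batchSize >= 1, valFraction >= 0, valFraction < 1)
  structure(
    list(
      lr = lr, epochs = as.integer(epochs), batchSize = batchSize,
      patience = patience, valFraction = valFraction,
      stopLossFraction = stopLossFraction, seed = as.integer(seed),
      verbose = isTRUE(verbose), verboseEvery = as.integer(verboseEvery)
    ),
    class = "trainControl"
  )
}

# ---- Adam over nested weight lists ------------------------------------------

.zerosLike <- function(w) {
  if (is.list(w)) {
    return(lapply(w, .zerosLike))
  }
  w * 0
}

.adamUpdate <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(w)) {
    keys <- names(w) %||% seq_along(w)
    out <- lapply(keys, function(k) .adamUpdate(w[[k]], g[[k]], m[[k]], v[[k]], lr, t))
    names(out) <- names(w)
    return(list(
      w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
      v = lapply(out, `[[`, "v")
    ))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# ---- batch preparation ------------------------------------------------------

.checkFeatureCompat <- function(model, drugFeatures, profiles) {
  if (drugFeatures$fpBits != model@fpBits) {
    .dsStop(
      "fingerprint length mismatch: model %d, features %d",
      model@fpBits, drugFeatures$fpBits
    )
  }
  if (!identical(colnames(profiles), model@scaler@panel)) {
    .dsStop("profile gene panel does not match the model's frozen panel")
  }
}

# Symmetrise records (both drug orders), build ordered-pair graph pieces and
# per-record feature matrices.
.prepareBatchData <- function(records, drugFeatures, profiles, joinMethod,
                              symmetrize = TRUE) {
  need <- c(records$drug1, records$drug2)
  missD <- setdiff(unique(need), names(drugFeatures$graphs))
  if (length(missD)) .dsStop("no features for drugs: %s", paste(head(missD, 3), collapse = ", "))
  missC <- setdiff(unique(records$cell), rownames(profiles))
  if (length(missC)) .dsStop("no expression profile for cells: %s", paste(head(missC, 3), collapse = ", "))

  if (symmetrize) {
    rec2 <- records
    rec2$drug1 <- records$drug2
    rec2$drug2 <- records$drug1
    recAll <- rbind(records, rec2)
    srcRow <- rep(seq_len(nrow(records)), 2L)
  } else {
    recAll <- records
    srcRow <- seq_len(nrow(records))
  }
  pairId <- paste(recAll$drug1, recAll$drug2, sep = "\r")
  pairs <- unique(data.frame(
    drug1 = recAll$drug1, drug2 = recAll$drug2,
    id = pairId, stringsAsFactors = FALSE
  ))
  pieces <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pieces[[k]] <- .graphPiece(joinGraphs(
      drugFeatures$graphs[[pairs$drug1[k]]],
      drugFeatures$graphs[[pairs$drug2[k]]],
      method = joinMethod
    ))
  }
  list(
    records = recAll, srcRow = srcRow,
    pieces = pieces,
    pairIdx = match(pairId, pairs$id),
    Xcell = profiles[recAll$cell, , drop = FALSE],
    FpA = drugFeatures$fingerprints[recAll$drug1, , drop = FALSE],
    FpB = drugFeatures$fingerprints[recAll$drug2, , drop = FALSE]
  )
}

.targets <- function(records, task) {
  if (task == "regression") {
    if (any(!is.finite(records$score))) .dsStop("non-finite synergy scores")
    return(records$score)
  }
  if (is.null(records$label)) .dsStop("classification task needs a 'label' column")
  y <- match(records$label, c("antagonistic", "synergistic"))
  if (any(is.na(y))) .dsStop("classification records must be labelled synergistic/antagonistic")
  y
}

# Shared optimiser loop; returns weights + history.  `valBase` optionally
# fixes the validation records (base-record indices) instead of sampling
# them; with a validation set the initial weights compete as the epoch-0
# candidate, so a fit that never improves validation loss returns them.
.fitLoop <- function(weights, config, bd, y, control, valBase = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(control$seed)

  nBase <- max(bd$srcRow)
  nAll <- nrow(bd$records)
  if (is.null(valBase)) {
    valBase <- if (control$valFraction > 0 && nBase >= 10) {
      sort(.sampleVec(seq_len(nBase), max(1L, round(control$valFraction * nBase))))
    } else {
      integer(0)
    }
  }
  valRows <- which(bd$srcRow %in% valBase)
  trainRows <- setdiff(seq_len(nAll), valRows)

  valBatch <- NULL
  if (length(valRows)) valBatch <- .subsetBatch(bd, valRows)

  state <- list(m = .zerosLike(weights), v = .zerosLike(weights))
  t <- 0L
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  if (!is.null(valBatch)) {
    fw0 <- .modelForward(weights, config, valBatch$gb, valBatch$pairIdx,
      valBatch$Xcell, valBatch$FpA, valBatch$FpB,
      training = FALSE
    )
    best <- list(
      loss = .lossAndGrad(fw0, y[valRows], config$task)$loss,
      weights = weights, epoch = 0L
    )
  }
  sinceBest <- 0L
  firstLoss <- NA_real_

  for (epoch in seq_len(control$epochs)) {
    ord <- trainRows[sample.int(length(trainRows))]
    bs <- if (is.finite(control$batchSize)) control$batchSize else length(ord)
    starts <- seq(1L, length(ord), by = bs)
    epochLoss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + bs - 1L, length(ord))]
      sub <- .subsetBatch(bd, rows)
      fw <- .modelForward(weights, config, sub$gb, sub$pairIdx,
        sub$Xcell, sub$FpA, sub$FpB,
        training = TRUE, keepCache = TRUE
      )
      lg <- .lossAndGrad(fw, y[rows], config$task)
      if (!is.finite(lg$loss)) {
        .dsStop(
          "loss became non-finite at epoch %d (lr %.3g); lower the learning rate",
          epoch, control$lr
        )
      }
      grads <- .modelBackward(lg$dOut, fw, weights, config, sub$gb, sub$pairIdx)
      t <- t + 1L
      upd <- .adamUpdate(weights, grads, state$m, state$v, control$lr, t)
      weights <- upd$w
      state$m <- upd$m
      state$v <- upd$v
      epochLoss <- epochLoss + lg$loss * length(rows)
    }
    epochLoss <- epochLoss / length(ord)
    if (is.na(firstLoss)) firstLoss <- epochLoss

    valLoss <- NA_real_
    if (!is.null(valBatch)) {
      fwv <- .modelForward(weights, config, valBatch$gb, valBatch$pairIdx,
        valBatch$Xcell, valBatch$FpA, valBatch$FpB,
        training = FALSE
      )
      valLoss <- .lossAndGrad(fwv, y[valRows], config$task)$loss
      if (valLoss < best$loss - 1e-12) {
        best <- list(loss = valLoss, weights = weights, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train = epochLoss, val = valLoss))
    if (control$verbose && (epoch %% control$verboseEvery == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  train %.5g  val %.5g", epoch, epochLoss, valLoss))
    }
    if (!is.null(control$stopLossFraction) && epochLoss < control$stopLossFraction * firstLoss) break
    if (!is.null(valBatch) && is.finite(control$patience) && sinceBest >= control$patience) break
  }
  if (!is.null(valBatch)) weights <- best$weights
  list(weights = weights, history = hist)
}

# Subset a prepared batch to a set of record rows, rebuilding the graph batch
# over just the pairs those rows reference.
.subsetBatch <- function(bd, rows) {
  pairsUsed <- sort(unique(bd$pairIdx[rows]))
  gb <- .assembleGraphBatch(bd$pieces, pairsUsed)
  list(
    gb = gb,
    pairIdx = match(bd$pairIdx[rows], pairsUsed),
    Xcell = bd$Xcell[rows, , drop = FALSE],
    FpA = bd$FpA[rows, , drop = FALSE],
    FpB = bd$FpB[rows, , drop = FALSE]
  )
}

#' Train a dual-view synergy model
#'
#' Fits the network on a triplet table.  Every record is presented in both
#' drug orders (the joint graph and view 2 are order-sensitive; training on
#' both orders plus order-averaged prediction makes the model symmetric in
#' the pair).  A validation split carved from the training records drives
#' early stopping; the weights of the best validation epoch are kept.
#'
#' @param records triplet data.frame with `drug1`, `drug2`, `cell`, `score`
#'   (and `label` for classification).
#' @param drugFeatures output of [featurizeDrugs()] covering all drugs.
#' @param profiles cells-by-genes matrix from [applyExpressionScaler()].
#' @param scaler the [ExpressionScaler-class] that produced `profiles`.
#' @param config a [synergyConfig()]; defaults to `synergyConfig()`.
#' @param control a [trainControl()]; defaults to `trainControl()`.
#' @param joinMethod joint-graph construction method.
#' @param model optionally, a [SynergyModel-class] to continue training from
#'   (its config/scaler override the other arguments).
#' @return a trained [SynergyModel-class]; `trainHistory()` exposes the
#'   per-epoch losses.
#' @export
trainSynergyModel <- function(records, drugFeatures, profiles, scaler,
                              config = synergyConfig(), control = trainControl(),
                              joinMethod = c(
                                "super_edge", "all_nodes",
                                "one_super_node", "three_super_nodes"
                              ),
                              model = NULL) {
  if (is.null(model)) {
    joinMethod <- match.arg(joinMethod)
    model <- initSynergyModel(config, scaler,
      fpBits = drugFeatures$fpBits,
      joinMethod = joinMethod
    )
  }
  .checkFeatureCompat(model, drugFeatures, profiles)
  bd <- .prepareBatchData(records, drugFeatures, profiles, model@joinMethod)
  y <- .targets(bd$records, model@config$task)
  fit <- .fitLoop(model@weights, model@config, bd, y, control)
  model@weights <- fit$weights
  model@history <- fit$history
  model
}

#' Fine-tune a trained model on new measurements
#'
#' Continues optimisation of all layers at a reduced learning rate after new
#' measurements (the k shots of a held-out cell line or drug pair, or a slice
#' of an independent dataset) are added to the training records.  When
#' `valRecords` is supplied (typically a held-back subset of the shots),
#' fine-tuning early-stops on it and the initial weights compete as the
#' epoch-0 candidate, so fine-tuning that never helps returns the model
#' unchanged rather than degraded.  With zero records the model is returned
#' unchanged, weight-for-weight.
#'
#' @param model a trained [SynergyModel-class].
#' @inheritParams trainSynergyModel
#' @param control a [trainControl()]; the default uses lr 1e-5, 30 epochs,
#'   full batch and no sampled validation split (shot counts are small).
#' @param valRecords optional data.frame of records used only for
#'   early-stopping validation.
#' @return the fine-tuned [SynergyModel-class].
#' @export
fineTuneModel <- function(model, records, drugFeatures, profiles,
                          control = trainControl(
                            lr = 1e-5, epochs = 30L,
                            batchSize = Inf, valFraction = 0
                          ),
                          valRecords = NULL) {
  stopifnot(is(model, "SynergyModel"))
  if (nrow(records) == 0L) {
    return(model)
  }
  .checkFeatureCompat(model, drugFeatures, profiles)
  valBase <- NULL
  if (!is.null(valRecords) && nrow(valRecords)) {
    cols <- intersect(names(records), names(valRecords))
    records <- rbind(records[, cols, drop = FALSE], valRecords[, cols, drop = FALSE])
    valBase <- nrow(records) - nrow(valRecords) + seq_len(nrow(valRecords))
  }
  bd <- .prepareBatchData(records, drugFeatures, profiles, model@joinMethod)
  y <- .targets(bd$records, model@config$task)
  fit <- .fitLoop(model@weights, model@config, bd, y, control, valBase = valBase)
  model@weights <- fit$weights
  model@history <- fit$history
  model
}

#' Predict synergy for a table of triplets
#'
#' Runs the network on every record and averages the two drug orders, so the
#' returned prediction is exactly symmetric in the pair.
#'
#' @param model a trained [SynergyModel-class].
#' @param records data.frame with `drug1`, `drug2`, `cell`.
#' @inheritParams trainSynergyModel
#' @param chunkSize records per forward pass (bounds memory).
#' @return for regression, a numeric vector of predicted synergy scores; for
#'   classification, the probability of the synergistic class.
#' @export
predictTriplets <- function(model, records, drugFeatures, profiles,
                            chunkSize = 4096L) {
  stopifnot(is(model, "SynergyModel"))
  .checkFeatureCompat(model, drugFeatures, profiles)
  n <- nrow(records)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunkSize)) {
    rows <- s:min(s + chunkSize - 1L, n)
    bd <- .prepareBatchData(records[rows, , drop = FALSE], drugFeatures, profiles,
      model@joinMethod,
      symmetrize = TRUE
    )
    gb <- .assembleGraphBatch(bd$pieces)
    fw <- .modelForward(model@weights, model@config, gb, bd$pairIdx,
      bd$Xcell, bd$FpA, bd$FpB,
      training = FALSE
    )
    pred <- if (model@config$task == "regression") drop(fw$out) else fw$probs[, 2L]
    # rows 1..k are order (1,2), rows k+1..2k the swapped order
    k <- length(rows)
    out[rows] <- (pred[seq_len(k)] + pred[k + seq_len(k)]) / 2
  }
  out
}

#' Predict synergy for one triplet
#'
#' @param model a trained [SynergyModel-class].
#' @param drugA,drugB drug names present in `drugFeatures`.
#' @param cell cell-line identifier present in `profiles`.
#' @inheritParams predictTriplets
#' @return a single prediction (see [predictTriplets()]).
#' @export
predictTriplet <- function(model, drugA, drugB, cell, drugFeatures, profiles) {
  predictTriplets(
    model,
    data.frame(drug1 = drugA, drug2 = drugB, cell = cell, stringsAsFactors = FALSE),
    drugFeatures, profiles
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, configuration, the frozen expression
#' scaler (gene panel and order), fingerprint length and join method;
#' [predictTriplets()] refuses features that do not match.
#'
#' @param model a [SynergyModel-class].
#' @param path file path.
#' @return `saveSynergyModel` returns `path` invisibly; `loadSynergyModel`
#'   returns the model.
#' @export
saveSynergyModel <- function(model, path) {
  stopifnot(is(model, "SynergyModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSynergyModel
#' @export
loadSynergyModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "SynergyModel")) .dsStop("'%s' is not a SynergyModel checkpoint", path)
  model
}
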