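# Metric panel, repeated stratified cross-validation and all-pairs
# prediction matrices.

.pcc <- function(yTrue, yPred) {
  if (sd(yPred) == 0 || sd(yTrue) == 0) {
    .dsWarn("constant predictions or targets: PCC reported as 0")
    return(0)
  }
  cor(yTrue, yPred)
}

.prAuc <- function(yTrue, score) {
  # area under the precision-recall curve by step interpolation over
  # descending score thresholds (ties handled as one step)
  ord <- order(score, decreasing = TRUE)
  y <- yTrue[ord]
  s <- score[ord]
  keep <- which(!duplicated(rev(s))) # last index of each tie group, reversed
  last <- sort(length(s) + 1 - keep)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  pos <- sum(y)
  if (pos == 0 || pos == length(y)) {
    return(NA_real_)
  }
  rec <- tp / pos
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Regression and classification metric panel
#'
#' Computes the standard evaluation panel.  Regression: Pearson correlation
#' (PCC; 0 with a warning when predictions are constant), R2 computed as
#' `1 - SS_res / SS_tot`, MSE and RMSE.  Classification (true labels 0/1 or
#' `antagonistic`/`synergistic`, predictions = probability of the positive
#' synergistic class, decision threshold 0.5): Cohen's Kappa, F1, ROC AUC,
#' PR AUC, balanced accuracy, precision and recall.
#'
#' @param yTrue observed scores (regression) or labels (classification).
#' @param yPred predicted scores or positive-class probabilities.
#' @param task `regression` or `classification`.
#' @return a named list of metric values.
#' @examples
#' computeMetrics(c(1, 2, 3), c(1, 2, 3), task = "regression")
#' @export
computeMetrics <- function(yTrue, yPred, task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 2)
  if (task == "regression") {
    res <- yTrue - yPred
    mse <- mean(res^2)
    sstot <- sum((yTrue - mean(yTrue))^2)
    return(list(
      PCC = .pcc(yTrue, yPred), R2 = 1 - sum(res^2) / sstot,
      MSE = mse, RMSE = sqrt(mse)
    ))
  }
  if (is.character(yTrue) || is.factor(yTrue)) {
    yTrue <- as.integer(as.character(yTrue) == "synergistic")
  }
  stopifnot(all(yTrue %in% c(0, 1)), all(yPred >= 0 & yPred <= 1))
  yHat <- as.integer(yPred >= 0.5)
  tp <- sum(yHat == 1 & yTrue == 1)
  fp <- sum(yHat == 1 & yTrue == 0)
  fn <- sum(yHat == 0 & yTrue == 1)
  tn <- sum(yHat == 0 & yTrue == 0)
  n <- length(yTrue)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  rocAuc <- if (length(unique(yTrue)) == 2) {
    as.numeric(pROC::auc(pROC::roc(yTrue, yPred,
      levels = c(0, 1),
      direction = "<", quiet = TRUE
    )))
  } else {
    NA_real_
  }
  list(
    Kappa = kappa, F1 = f1, ROC_AUC = rocAuc,
    PR_AUC = .prAuc(yTrue, yPred), BACC = (rec + spec) / 2,
    precision = prec, recall = rec
  )
}

.assertDisjoint <- function(plan, fl) {
  rec <- plan@records
  tr <- rec[fl$train, , drop = FALSE]
  te <- rec[fl$test, , drop = FALSE]
  ok <- switch(plan@strategy,
    random = !length(intersect(fl$train, fl$test)),
    pair_out = !length(intersect(
      .pairKey(tr$drug1, tr$drug2),
      .pairKey(te$drug1, te$drug2)
    )),
    cell_out = !length(intersect(tr$cell, te$cell)),
    drug_out = {
      held <- names(plan@entityFold)[plan@entityFold == unique(plan@fold[fl$test])[1]]
      ok <- !any(c(tr$drug1, tr$drug2) %in% held)
      if (plan@drugOutMode == "both") {
        ok <- ok && !length(intersect(c(tr$drug1, tr$drug2), c(te$drug1, te$drug2)))
      }
      ok
    }
  )
  if (!ok) .dsStop("split leakage detected for strategy %s", plan@strategy)
}

#' Repeated stratified cross-validation
#'
#' Runs `repeats` rounds of `nFolds`-fold cross-validation under the chosen
#' split strategy, asserting the strategy's disjointness contract on every
#' fold, and reports each metric's per-fold values together with the mean
#' and a normal-approximation 95% confidence interval over all
#' `repeats * nFolds` fold values.
#'
#' @param records triplet data.frame (see [trainSynergyModel()]).
#' @param strategy split strategy (see [makeSplits()]).
#' @param nFolds,repeats folds per round and number of rounds.
#' @param seed base seed; round r uses `seed + r - 1`.
#' @param task `regression` or `classification`.
#' @param fitFun a function `(trainRecords) -> function(testRecords) ->
#'   predictions`.  The default trains a dual-view model with the remaining
#'   arguments.
#' @inheritParams trainSynergyModel
#' @return a list with `folds` (data.frame of per-fold metric values) and
#'   `summary` (mean, sd, lower/upper 95% CI per metric).
#' @export
crossValidate <- function(records, strategy = "random", nFolds = 5L, repeats = 10L,
                          seed = 1L, task = c("regression", "classification"),
                          fitFun = NULL,
                          drugFeatures = NULL, profiles = NULL, scaler = NULL,
                          config = synergyConfig(), control = trainControl(),
                          joinMethod = "super_edge") {
  task <- match.arg(task)
  if (is.null(fitFun)) {
    if (is.null(drugFeatures) || is.null(profiles) || is.null(scaler)) {
      .dsStop("either fitFun or drugFeatures+profiles+scaler must be given")
    }
    fitFun <- function(trainRec) {
      m <- trainSynergyModel(trainRec, drugFeatures, profiles, scaler,
        config = config, control = control, joinMethod = joinMethod
      )
      function(testRec) predictTriplets(m, testRec, drugFeatures, profiles)
    }
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    plan <- makeSplits(records, strategy, nFolds = nFolds, seed = seed + r - 1L)
    for (f in seq_len(nFolds)) {
      fl <- splitFold(plan, f)
      if (!length(fl$test) || !length(fl$train)) next
      .assertDisjoint(plan, fl)
      predict <- fitFun(records[fl$train, , drop = FALSE])
      pred <- predict(records[fl$test, , drop = FALSE])
      truth <- if (task == "regression") records$score[fl$test] else records$label[fl$test]
      met <- computeMetrics(truth, pred, task = task)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat. = r, fold = f, as.data.frame(met)
      )
    }
  }
  folds <- do.call(rbind, rows)
  metricCols <- setdiff(names(folds), c("repeat.", "fold"))
  summ <- do.call(rbind, lapply(metricCols, function(mc) {
    v <- folds[[mc]]
    v <- v[is.finite(v)]
    data.frame(
      metric = mc, mean = mean(v), sd = sd(v),
      lower = mean(v) - 1.96 * sd(v) / sqrt(length(v)),
      upper = mean(v) + 1.96 * sd(v) / sqrt(length(v))
    )
  }))
  list(folds = folds, summary = summ)
}

#' Dense pair-by-cell synergy prediction matrix
#'
#' Scores every drug pair on every cell line with [predictTriplets()],
#' streaming in chunks so memory stays bounded, and returns the dense
#' matrix.  The synergistic ratio of a pair (fraction of cell lines
#' predicted above a threshold) can be read off the rows.
#'
#' @param model a trained [SynergyModel-class].
#' @param pairs data.frame with `drug1`, `drug2`.
#' @param cells character vector of cell-line identifiers.
#' @inheritParams predictTriplets
#' @return a `nrow(pairs)` by `length(cells)` numeric matrix; rownames are
#'   `drug1|drug2`, colnames the cell ids.
#' @export
predictSynergyMatrix <- function(model, pairs, cells, drugFeatures, profiles,
                                 chunkSize = 4096L) {
  out <- matrix(NA_real_, nrow(pairs), length(cells),
    dimnames = list(paste(pairs$drug1, pairs$drug2, sep = "|"), cells)
  )
  grid <- data.frame(
    drug1 = rep(pairs$drug1, times = length(cells)),
    drug2 = rep(pairs$drug2, times = length(cells)),
    cell = rep(cells, each = nrow(pairs)),
    stringsAsFactors = FALSE
  )
  pred <- predictTriplets(model, grid, drugFeatures, profiles, chunkSize = chunkSize)
  out[] <- pred
  out
}

#' Synergistic ratio per pair
#'
#' Fraction of cell lines on which each pair's predicted synergy exceeds a
#' threshold.
#'
#' @param scoreMatrix output of [predictSynergyMatrix()].
#' @param posThr synergy threshold (default 10).
#' @return named numeric vector, one ratio per pair.
#' @export
synergisticRatio <- function(scoreMatrix, posThr = 10) {
  rowMeans(scoreMatrix > posThr)
}
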