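# Synergy screen data handling: replicate filtering, labels, triplet
# assembly, split plans and k-shot augmentation.

.pairKey <- function(d1, d2) paste(pmin(d1, d2), pmax(d1, d2), sep = "\r")

#' Filter replicate synergy measurements of one triplet
#'
#' A triplet is excluded when any two replicates have strictly opposite signs
#' (zero is compatible with either sign), or when the coefficient of
#' variation `sd / |mean|` (sample sd, computed only when there are at least
#' two replicates) exceeds `cvMax`.  A near-zero mean with unequal
#' replicates makes the CV undefined and the triplet is excluded; otherwise
#' the retained score is the median of the replicates.
#'
#' @param scores numeric vector of replicate synergy scores (length >= 1).
#' @param cvMax CV exclusion threshold (default 0.5).
#' @return the median score, or `NA_real_` if the triplet is excluded.
#' @examples
#' filterReplicates(c(10, -5)) # NA: sign conflict
#' filterReplicates(c(10, 30)) # NA: CV 0.707
#' filterReplicates(c(10, 12, 14)) # 12
#' @export
filterReplicates <- function(scores, cvMax = 0.5) {
  if (!length(scores)) .dsStop("empty replicate list")
  if (any(!is.finite(scores))) .dsStop("non-finite replicate score")
  if (any(scores > 0) && any(scores < 0)) return(NA_real_)
  if (length(scores) >= 2L) {
    m <- mean(scores)
    s <- sd(scores)
    if (abs(m) < 1e-8) {
      if (s > 0) return(NA_real_) # CV undefined at mean zero
    } else if (s / abs(m) > cvMax) {
      return(NA_real_)
    }
  }
  median(scores)
}

#' Classify a synergy score
#'
#' Scores above `posThr` are synergistic, below `negThr` antagonistic, and
#' anything in the additive dead band is unlabelled (`NA`), to be dropped
#' from the classification task.
#'
#' @param score numeric score vector.
#' @param posThr,negThr class thresholds (defaults +10 / -10 on the additive
#'   deviation scale).
#' @return character vector with values `"synergistic"`, `"antagonistic"` or
#'   `NA`.
#' @export
labelClasses <- function(score, posThr = 10, negThr = -10) {
  stopifnot(posThr >= negThr)
  ifelse(score > posThr, "synergistic",
    ifelse(score < negThr, "antagonistic", NA_character_)
  )
}

#' Read and assemble a triplet table
#'
#' Reads a CSV with columns `drug1,drug2,cell,score` and optionally
#' `replicate_id`.  Rows describing the same unordered (drug1, drug2, cell)
#' triplet are collapsed: replicates are passed through [filterReplicates()]
#' and unreliable triplets are dropped (reported via a message).  Triplets
#' pairing a drug with itself are rejected.
#'
#' @param path path to the CSV file.
#' @param cvMax CV threshold for [filterReplicates()].
#' @param posThr,negThr thresholds for [labelClasses()].
#' @return a data.frame with columns `drug1`, `drug2`, `cell`, `score`,
#'   `label` (one row per retained triplet; `drug1 < drug2`
#'   lexicographically).
#' @export
readTriplets <- function(path, cvMax = 0.5, posThr = 10, negThr = -10) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug1", "drug2", "cell", "score")
  if (!all(need %in% names(tab))) {
    .dsStop("triplet table '%s' must have columns drug1,drug2,cell,score", path)
  }
  aggregateReplicates(tab, cvMax = cvMax, posThr = posThr, negThr = negThr)
}

#' Collapse replicate rows into one record per triplet
#'
#' @param tab data.frame with columns `drug1,drug2,cell,score` (one row per
#'   replicate measurement).
#' @inheritParams readTriplets
#' @return see [readTriplets()].
#' @export
aggregateReplicates <- function(tab, cvMax = 0.5, posThr = 10, negThr = -10) {
  if (any(tab$drug1 == tab$drug2)) .dsStop("triplets must pair two distinct drugs")
  d1 <- pmin(tab$drug1, tab$drug2)
  d2 <- pmax(tab$drug1, tab$drug2)
  key <- paste(d1, d2, tab$cell, sep = "\r")
  grp <- split(seq_len(nrow(tab)), key)
  score <- vapply(grp, function(ix) filterReplicates(tab$score[ix], cvMax = cvMax), 0)
  first <- vapply(grp, `[`, 0L, 1L)
  out <- data.frame(
    drug1 = d1[first], drug2 = d2[first], cell = tab$cell[first],
    score = unname(score), stringsAsFactors = FALSE
  )
  nDrop <- sum(is.na(out$score))
  if (nDrop) {
    message(sprintf(
      "aggregateReplicates: excluded %d of %d triplets (sign conflict or CV > %.2g)",
      nDrop, nrow(out), cvMax
    ))
  }
  out <- out[!is.na(out$score), , drop = FALSE]
  out$label <- labelClasses(out$score, posThr = posThr, negThr = negThr)
  rownames(out) <- NULL
  out
}

#' Build a cross-validation split plan
#'
#' Partitions a triplet table into `nFolds` folds under one of four
#' strategies: `random` deals triplets, `pair_out` unordered drug pairs,
#' `cell_out` cell lines and `drug_out` drugs.  For entity-level strategies a
#' triplet's fold is the fold of its entity; for `drug_out` the recorded fold
#' is the smaller of the two drugs' folds, and fold membership at evaluation
#' time is resolved by [splitFold()].
#'
#' @param records triplet data.frame (`drug1`, `drug2`, `cell`, `score`).
#' @param strategy one of `random`, `pair_out`, `cell_out`, `drug_out`.
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed; the same seed always yields the same plan.
#' @param drugOutMode for `drug_out`: `both` (default; a test triplet must
#'   pair two held-out drugs, so every drug seen in a fold's test set is
#'   absent from its training set, and triplets mixing a held-out with a
#'   seen drug are dropped from that fold) or `any` (one held-out drug
#'   suffices for test membership).
#' @return a [SplitPlan-class].
#' @export
makeSplits <- function(records, strategy = c("random", "pair_out", "cell_out", "drug_out"),
                       nFolds = 5L, seed = 1L, drugOutMode = c("both", "any")) {
  strategy <- match.arg(strategy)
  drugOutMode <- match.arg(drugOutMode)
  if (!nrow(records)) .dsStop("no records to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  entity <- switch(strategy,
    random = as.character(seq_len(nrow(records))),
    pair_out = .pairKey(records$drug1, records$drug2),
    cell_out = as.character(records$cell),
    drug_out = NA_character_
  )
  if (strategy == "drug_out") {
    drugs <- sort(unique(c(records$drug1, records$drug2)))
    if (length(drugs) < nFolds) .dsStop("fewer drugs (%d) than folds (%d)", length(drugs), nFolds)
    ef <- setNames(.dealFolds(length(drugs), nFolds), drugs)
    fold <- pmin(ef[records$drug1], ef[records$drug2])
  } else {
    ents <- sort(unique(entity))
    if (length(ents) < nFolds) .dsStop("fewer entities (%d) than folds (%d)", length(ents), nFolds)
    ef <- setNames(.dealFolds(length(ents), nFolds), ents)
    fold <- ef[entity]
  }
  new("SplitPlan",
    records = records, strategy = strategy, fold = as.integer(unname(fold)),
    entityFold = ef, nFolds = as.integer(nFolds), seed = as.integer(seed),
    drugOutMode = drugOutMode
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Materialise the train/test indices of one fold
#'
#' For `random`, `pair_out` and `cell_out`, test = records assigned to the
#' fold and train = all others.  For `drug_out`, train = records containing
#' no held-out drug; in the default `both` mode test = records whose two
#' drugs are both held out (records mixing a held-out and a seen drug are
#' dropped, so no drug occurs on both sides), while `any` mode puts every
#' record with at least one held-out drug in the test set.
#'
#' @param plan a [SplitPlan-class].
#' @param fold fold id in `1..nFolds(plan)`.
#' @return a list with integer index vectors `train` and `test` (and
#'   `dropped`, non-empty only for `drug_out` mode `both`).
#' @export
splitFold <- function(plan, fold) {
  stopifnot(is(plan, "SplitPlan"), fold >= 1L, fold <= plan@nFolds)
  rec <- plan@records
  if (plan@strategy == "drug_out") {
    f1 <- plan@entityFold[rec$drug1]
    f2 <- plan@entityFold[rec$drug2]
    inTest <- if (plan@drugOutMode == "any") f1 == fold | f2 == fold else f1 == fold & f2 == fold
    inTrain <- f1 != fold & f2 != fold
    list(
      train = which(inTrain), test = which(inTest),
      dropped = which(!inTrain & !inTest)
    )
  } else {
    list(
      train = which(plan@fold != fold), test = which(plan@fold == fold),
      dropped = integer(0)
    )
  }
}

#' Move k shots of a held-out entity from test to train
#'
#' Implements the k-shot protocol for the two entity-holdout scenarios: for a
#' `cell_out` plan, `k` distinct drug combinations measured on the held-out
#' cell move from the fold's test set into its training set; for a
#' `pair_out` plan, `k` cell lines measured for the held-out pair move.
#' Sampling is without replacement and seeded; if fewer than `k` shots are
#' available, all of them move, with a warning.
#'
#' @param plan a [SplitPlan-class] with strategy `cell_out` or `pair_out`.
#' @param fold the fold whose test set holds the entity.
#' @param entity held-out cell identifier (`cell_out`), or character vector
#'   of the two drug names (`pair_out`).
#' @param k number of shots to move (k = 0 leaves the fold unchanged).
#' @param seed RNG seed for the sampling.
#' @return a list with `train`, `test` (index vectors after the move) and
#'   `moved` (the indices that changed side).
#' @export
kshotAugment <- function(plan, fold, entity, k, seed = 1L) {
  stopifnot(is(plan, "SplitPlan"))
  if (!plan@strategy %in% c("cell_out", "pair_out")) {
    .dsStop("k-shot augmentation applies to cell_out or pair_out plans")
  }
  if (!.isCount(k)) .dsStop("k must be a non-negative count")
  fl <- splitFold(plan, fold)
  rec <- plan@records
  if (plan@strategy == "cell_out") {
    cand <- fl$test[rec$cell[fl$test] == entity]
  } else {
    key <- .pairKey(entity[1], entity[2])
    cand <- fl$test[.pairKey(rec$drug1[fl$test], rec$drug2[fl$test]) == key]
  }
  if (!length(cand)) .dsStop("entity has no test records in this fold")
  if (k > length(cand)) {
    .dsWarn("only %d shots available, requested %d; moving all", length(cand), k)
    k <- length(cand)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  moved <- if (k > 0) sort(.sampleVec(cand, k)) else integer(0)
  list(
    train = sort(c(fl$train, moved)),
    test = setdiff(fl$test, moved),
    moved = moved
  )
}
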