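#' Molecular graph of a single drug
#'
#' Heavy-atom graph parsed from a SMILES string.  Nodes are heavy atoms, each
#' carrying a 78-dimensional feature row (atom-symbol one-hot over 44 symbols,
#' degree one-hot 0--10, total-hydrogen one-hot 0--10, implicit-valence one-hot
#' 0--10, aromatic flag); edges are chemical bonds stored once as unordered
#' index pairs with `i < j`.
#'
#' @slot nodeFeatures numeric matrix, one row per heavy atom, 78 columns.
#' @slot edges two-column integer matrix of 1-based atom index pairs, `i < j`.
#' @slot smiles the (canonicalised) SMILES the graph was parsed from.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(nodeFeatures = "matrix", edges = "matrix", smiles = "character"),
  prototype(
    nodeFeatures = matrix(numeric(0), 0, 78),
    edges = matrix(integer(0), 0, 2), smiles = NA_character_
  )
)

setValidity("MolecularGraph", function(object) {
  msg <- character()
  n <- nrow(object@nodeFeatures)
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge indices out of range")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1] > e[, 2])) msg <- c(msg, "edges must be stored with i < j")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Joint graph of a drug pair
#'
#' A single graph built from the molecular graphs of two drugs so that message
#' passing can cross the drug boundary.  Nodes of drug B are offset by the
#' number of atoms in drug A; both drugs' intra-molecular edge sets are
#' preserved verbatim.  Depending on the join method the graph additionally
#' contains one cross edge (`super_edge`), the full bipartite cross product
#' (`all_nodes`), one virtual super node (`one_super_node`) or three
#' (`three_super_nodes`).  Virtual nodes carry an all-zero feature row and are
#' labelled through `provenance`.
#'
#' @slot provenance per-node label in `A`, `B`, `SUP1`, `SUP2`, `SUP`.
#' @slot method the join method used.
#' @slot nA,nB atom counts of the two drugs.
#' @exportClass JointGraph
setClass("JointGraph",
  contains = "MolecularGraph",
  representation(
    provenance = "character", method = "character",
    nA = "integer", nB = "integer"
  )
)

setValidity("JointGraph", function(object) {
  msg <- character()
  n <- nrow(object@nodeFeatures)
  if (length(object@provenance) != n) msg <- c(msg, "provenance length != node count")
  if (!all(object@provenance %in% c("A", "B", "SUP1", "SUP2", "SUP"))) {
    msg <- c(msg, "invalid provenance label")
  }
  if (!object@method %in% names(.joinEdgeGain)) msg <- c(msg, "unknown join method")
  if (sum(object@provenance == "A") != object@nA) msg <- c(msg, "nA mismatch")
  if (sum(object@provenance == "B") != object@nB) msg <- c(msg, "nB mismatch")
  if (length(msg)) msg else TRUE
})

#' Frozen per-gene expression scaler
#'
#' Stores the gene panel (in fixed order) together with per-gene centre and
#' scale of `log2(TPM + 1)` computed on the training cell lines, so that
#' prediction-time profiles are transformed identically.
#'
#' @slot panel ordered gene symbols retained from the requested panel.
#' @slot center,scale per-gene mean and standard deviation on training cells.
#' @slot trainCells the cell-line identifiers the scaler was fitted on.
#' @exportClass ExpressionScaler
setClass("ExpressionScaler",
  representation(
    panel = "character", center = "numeric",
    scale = "numeric", trainCells = "character"
  )
)

setValidity("ExpressionScaler", function(object) {
  msg <- character()
  if (anyDuplicated(object@panel)) msg <- c(msg, "panel symbols must be unique")
  if (length(object@center) != length(object@panel)) msg <- c(msg, "center length != panel")
  if (length(object@scale) != length(object@panel)) msg <- c(msg, "scale length != panel")
  if (length(object@scale) && any(object@scale < 0)) msg <- c(msg, "negative scale")
  if (length(msg)) msg else TRUE
})

#' Cross-validation split plan
#'
#' Fold assignments for a triplet table under one of four strategies:
#' `random` (triplets dealt into folds), `pair_out` (unordered drug pairs
#' partitioned), `cell_out` (cell lines partitioned) and `drug_out` (drugs
#' partitioned).  Use [splitFold()] to materialise the train/test indices of a
#' fold; for `drug_out` a fold's test set contains every triplet with at least
#' one held-out drug (or both, in `both` mode) and its training set only
#' triplets with none.
#'
#' @slot records the triplet table the plan indexes into.
#' @slot strategy one of `random`, `pair_out`, `cell_out`, `drug_out`.
#' @slot fold integer fold id per record.
#' @slot entityFold named fold id per entity (pair key, cell or drug).
#' @slot nFolds,seed fold count and RNG seed used.
#' @slot drugOutMode `any` (default) or `both`; see [splitFold()].
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(
    records = "data.frame", strategy = "character", fold = "integer",
    entityFold = "integer", nFolds = "integer", seed = "integer",
    drugOutMode = "character"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (!object@strategy %in% c("random", "pair_out", "cell_out", "drug_out")) {
    msg <- c(msg, "unknown strategy")
  }
  if (length(object@fold) != nrow(object@records)) msg <- c(msg, "fold length != records")
  if (length(object@fold) && (any(object@fold < 1L) || any(object@fold > object@nFolds))) {
    msg <- c(msg, "fold ids out of range")
  }
  if (!object@drugOutMode %in% c("any", "both")) msg <- c(msg, "drugOutMode must be any/both")
  if (length(msg)) msg else TRUE
})

#' Trained dual-view synergy model
#'
#' Bundles everything needed to reproduce a prediction: the network weights,
#' the architecture configuration, the frozen expression scaler (which fixes
#' the gene panel and its order), the fingerprint length and the joint-graph
#' construction method.  [predictTriplets()] refuses to run if features
#' supplied at prediction time do not match these settings.
#'
#' @slot weights named list of weight matrices and bias vectors.
#' @slot config model configuration list, see [synergyConfig()].
#' @slot scaler the [ExpressionScaler-class] fitted on training cells.
#' @slot fpBits fingerprint length the model was trained with.
#' @slot joinMethod joint-graph construction method.
#' @slot history per-epoch training/validation loss of the last fit.
#' @exportClass SynergyModel
setClass("SynergyModel",
  representation(
    weights = "list", config = "list", scaler = "ExpressionScaler",
    fpBits = "integer", joinMethod = "character", history = "data.frame"
  )
)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf(
    "MolecularGraph: %d atoms, %d bonds [%s]\n",
    nrow(object@nodeFeatures), nrow(object@edges),
    ifelse(is.na(object@smiles), "?", object@smiles)
  ))
})

setMethod("show", "JointGraph", function(object) {
  cat(sprintf(
    "JointGraph (%s): %d + %d atoms, %d super nodes, %d edges\n",
    object@method, object@nA, object@nB,
    sum(!object@provenance %in% c("A", "B")), nrow(object@edges)
  ))
})

setMethod("show", "ExpressionScaler", function(object) {
  cat(sprintf(
    "ExpressionScaler: %d-gene panel, fitted on %d cells\n",
    length(object@panel), length(object@trainCells)
  ))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan: %s, %d folds, %d records (seed %d)\n",
    object@strategy, object@nFolds, nrow(object@records), object@seed
  ))
})

setMethod("show", "SynergyModel", function(object) {
  np <- sum(rapply(object@weights, length, how = "unlist"))
  cat(sprintf(
    "SynergyModel (%s task): %s parameters\n  join: %s | fingerprint: %d bits | panel: %d genes\n",
    object@config$task, format(np, big.mark = ","), object@joinMethod,
    object@fpBits, length(object@scaler@panel)
  ))
  if (nrow(object@history)) {
    cat(sprintf(
      "  trained %d epochs, final train loss %.4g\n",
      max(object@history$epoch), object@history$train[nrow(object@history)]
    ))
  }
})
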