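# Joint drug-pair graph construction.
#
# Four ways to join two molecular graphs into one graph whose message passing
# crosses the drug boundary: a single virtual edge between the two
# highest-betweenness atoms (super_edge, the default), the full bipartite
# cross product (all_nodes), one virtual super node connected to every atom
# (one_super_node), or per-drug super nodes aggregated by a third
# (three_super_nodes).  Super nodes carry an all-zero feature row; their role
# is encoded solely through connectivity and the provenance labels.

# extra edges added by each method given nA, nB
.joinEdgeGain <- list(
  super_edge = function(nA, nB) 1L,
  all_nodes = function(nA, nB) nA * nB,
  one_super_node = function(nA, nB) nA + nB,
  three_super_nodes = function(nA, nB) nA + nB + 2L
)

#' Betweenness centrality of a molecular graph
#'
#' For every node v, the sum over unordered node pairs \{s, t\} (s, t both
#' different from v) of the fraction of shortest s--t paths that pass through
#' v, with unit edge weights, endpoints excluded and no normalisation.
#' Unreachable pairs contribute zero, so disconnected molecules (salts,
#' mixtures) are handled per component.
#'
#' @param graph a [MolecularGraph-class].
#' @return a non-negative numeric vector, one score per atom.
#' @examples
#' g <- smilesToGraph("CCO")
#' betweennessCentrality(g) # middle atom scores 1
#' @export
betweennessCentrality <- function(graph) {
  n <- nAtoms(graph)
  if (n == 0L) .dsStop("empty graph")
  if (n == 1L) return(0)
  e <- edgeMatrix(graph)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e)) ig <- igraph::add_edges(ig, t(e))
  as.numeric(igraph::betweenness(ig, directed = FALSE, normalized = FALSE))
}

.jointBase <- function(gA, gB, nSuper, method) {
  nA <- nAtoms(gA); nB <- nAtoms(gB)
  if (nA == 0L || nB == 0L) .dsStop("both drugs must have at least one atom")
  feats <- rbind(
    nodeFeatures(gA), nodeFeatures(gB),
    matrix(0, nSuper, ncol(nodeFeatures(gA)))
  )
  eA <- edgeMatrix(gA)
  eB <- edgeMatrix(gB)
  if (nrow(eB)) eB <- eB + nA
  list(nA = nA, nB = nB, feats = feats, edges = rbind(eA, eB))
}

.finishJoint <- function(base, extraEdges, provExtra, method) {
  e <- rbind(base$edges, extraEdges)
  if (nrow(e)) e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  storage.mode(e) <- "integer"
  new("JointGraph",
    nodeFeatures = base$feats, edges = e,
    smiles = NA_character_,
    provenance = c(rep("A", base$nA), rep("B", base$nB), provExtra),
    method = method, nA = as.integer(base$nA), nB = as.integer(base$nB)
  )
}

#' Join two molecular graphs by a super edge
#'
#' Adds a single virtual edge between the highest-betweenness atom of drug A
#' and the highest-betweenness atom of drug B (ties broken by lowest atom
#' index).  The edge count is `|E_A| + |E_B| + 1`.
#'
#' @param gA,gB [MolecularGraph-class] objects for the two drugs.
#' @return a [JointGraph-class].
#' @export
joinSuperEdge <- function(gA, gB) {
  base <- .jointBase(gA, gB, 0L, "super_edge")
  v1 <- which.max(betweennessCentrality(gA)) # which.max takes lowest index on ties
  v2 <- which.max(betweennessCentrality(gB))
  .finishJoint(base, cbind(v1, v2 + base$nA), character(0), "super_edge")
}

#' Join two molecular graphs by the full bipartite product
#'
#' Every atom of drug A is connected to every atom of drug B; the edge count
#' is `|E_A| + |E_B| + nA * nB`.
#'
#' @inheritParams joinSuperEdge
#' @return a [JointGraph-class].
#' @export
joinAllNodes <- function(gA, gB) {
  base <- .jointBase(gA, gB, 0L, "all_nodes")
  cross <- as.matrix(expand.grid(seq_len(base$nA), seq_len(base$nB) + base$nA))
  dimnames(cross) <- NULL
  .finishJoint(base, cross, character(0), "all_nodes")
}

#' Join two molecular graphs through one super node
#'
#' A single virtual node is connected to every atom of both drugs; the node
#' count is `nA + nB + 1` and the edge count `|E_A| + |E_B| + nA + nB`.
#'
#' @inheritParams joinSuperEdge
#' @return a [JointGraph-class].
#' @export
joinOneSuperNode <- function(gA, gB) {
  base <- .jointBase(gA, gB, 1L, "one_super_node")
  sup <- base$nA + base$nB + 1L
  extra <- cbind(seq_len(base$nA + base$nB), sup)
  .finishJoint(base, extra, "SUP", "one_super_node")
}

#' Join two molecular graphs through three super nodes
#'
#' Super node 1 is connected to every atom of drug A, super node 2 to every
#' atom of drug B, and a third super node aggregates the two.  The node count
#' is `nA + nB + 3` and the edge count `|E_A| + |E_B| + nA + nB + 2`.
#'
#' @inheritParams joinSuperEdge
#' @return a [JointGraph-class].
#' @export
joinThreeSuperNodes <- function(gA, gB) {
  base <- .jointBase(gA, gB, 3L, "three_super_nodes")
  nAB <- base$nA + base$nB
  sup1 <- nAB + 1L; sup2 <- nAB + 2L; sup <- nAB + 3L
  extra <- rbind(
    cbind(seq_len(base$nA), sup1),
    cbind(seq_len(base$nB) + base$nA, sup2),
    c(sup1, sup), c(sup2, sup)
  )
  .finishJoint(base, extra, c("SUP1", "SUP2", "SUP"), "three_super_nodes")
}

#' Build the joint graph of a drug pair
#'
#' Dispatches to one of the four join constructions; `super_edge` is the
#' default method.
#'
#' @inheritParams joinSuperEdge
#' @param method one of `super_edge`, `all_nodes`, `one_super_node`,
#'   `three_super_nodes`.
#' @return a [JointGraph-class].
#' @examples
#' j <- joinGraphs(smilesToGraph("CCO"), smilesToGraph("CCO"))
#' joinMethod(j)
#' @export
joinGraphs <- function(gA, gB, method = c(
                         "super_edge", "all_nodes",
                         "one_super_node", "three_super_nodes"
                       )) {
  method <- match.arg(method)
  switch(method,
    super_edge = joinSuperEdge(gA, gB),
    all_nodes = joinAllNodes(gA, gB),
    one_super_node = joinOneSuperNode(gA, gB),
    three_super_nodes = joinThreeSuperNodes(gA, gB)
  )
}
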