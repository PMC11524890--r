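# Betweenness centrality and the four joint-graph constructions.

test_that("betweenness centrality matches hand-derived values on canonical graphs", {
  # path a-b-c: middle node lies on the single shortest path
  expect_equal(betweennessCentrality(bareGraph(3, c(1, 2, 2, 3))), c(0, 1, 0))
  # complete graph K4: no shortest path passes through a third node
  k4 <- bareGraph(4, t(combn(4, 2)))
  expect_equal(betweennessCentrality(k4), rep(0, 4))
  # star with 4 leaves: centre carries all C(4,2) pairs
  star <- bareGraph(5, c(1, 2, 1, 3, 1, 4, 1, 5))
  expect_equal(betweennessCentrality(star), c(6, 0, 0, 0, 0))
  # disconnected components contribute pairwise-reachable pairs only
  two <- bareGraph(5, c(1, 2, 2, 3, 4, 5))
  expect_equal(betweennessCentrality(two), c(0, 1, 0, 0, 0))
  expect_error(betweennessCentrality(bareGraph(0, integer(0))), "empty")
})

test_that("betweenness centrality equals the brute-force path-enumeration oracle", {
  graphs <- c(
    lapply(3:8, function(n) bareGraph(n, cbind(1:(n - 1), 2:n))), # paths
    lapply(4:8, function(n) bareGraph(n, cbind(1:n, c(2:n, 1)))), # cycles
    lapply(
      seq_len(20),
      function(k) randomConnectedGraph(sample(4:8, 1), extra = sample(0:3, 1), seed = 100 + k)
    )
  )
  for (g in graphs) {
    expect_equal(
      betweennessCentrality(g),
      bruteBetweenness(nAtoms(g), edgeMatrix(g)),
      tolerance = 1e-10
    )
  }
})

test_that("super-edge join links the most central atom of each drug", {
  eth <- smilesToGraph("CCO")
  j <- joinSuperEdge(eth, eth)
  expect_s4_class(j, "JointGraph")
  expect_identical(nrow(edgeMatrix(j)), 5L) # 2 + 2 + 1
  e <- edgeMatrix(j)
  intra <- (e[, 1] <= 3 & e[, 2] <= 3) | (e[, 1] > 3 & e[, 2] > 3)
  cross <- e[!intra, , drop = FALSE]
  expect_identical(nrow(cross), 1L)
  # both endpoints are each chain's middle atom (index 2, offset 3 for B)
  expect_equal(unname(cross[1, ]), c(2L, 5L))
  # degenerate argmax: single-atom drug
  j2 <- joinSuperEdge(smilesToGraph("C"), eth)
  e2 <- edgeMatrix(j2)
  expect_true(any(e2[, 1] == 1L & e2[, 2] > 1L))
})

test_that("all four joins obey their edge- and node-count identities", {
  lib <- makeDrugLibrary(10, seed = 17)
  feats <- featurizeDrugs(lib, fpBits = 64)
  pairs <- randomDrugPairs(lib, 12, seed = 5)
  gains <- list(
    super_edge = function(nA, nB) 1L,
    all_nodes = function(nA, nB) nA * nB,
    one_super_node = function(nA, nB) nA + nB,
    three_super_nodes = function(nA, nB) nA + nB + 2L
  )
  extraNodes <- c(super_edge = 0L, all_nodes = 0L, one_super_node = 1L, three_super_nodes = 3L)
  for (k in seq_len(nrow(pairs))) {
    gA <- feats$graphs[[pairs[k, 1]]]
    gB <- feats$graphs[[pairs[k, 2]]]
    for (m in names(gains)) {
      j <- joinGraphs(gA, gB, method = m)
      expect_true(validObject(j, test = TRUE) == TRUE, label = m)
      expect_identical(
        nrow(edgeMatrix(j)),
        as.integer(nrow(edgeMatrix(gA)) + nrow(edgeMatrix(gB)) +
          gains[[m]](nAtoms(gA), nAtoms(gB))),
        label = m
      )
      expect_identical(nAtoms(j), nAtoms(gA) + nAtoms(gB) + extraNodes[[m]], label = m)
      # intra-drug edges preserved verbatim (as sets)
      e <- edgeMatrix(j)
      nA <- nAtoms(gA)
      eA <- e[e[, 1] <= nA & e[, 2] <= nA, , drop = FALSE]
      origA <- edgeMatrix(gA)
      expect_setequal(paste(eA[, 1], eA[, 2]), paste(origA[, 1], origA[, 2]))
    }
  }
})

test_that("super-node joins wire the virtual nodes as specified", {
  gA <- smilesToGraph("CCO") # 3 atoms
  gB <- smilesToGraph("CC") # 2 atoms
  j1 <- joinOneSuperNode(gA, gB)
  expect_identical(sum(provenance(j1) == "SUP"), 1L)
  deg <- tabulate(edgeMatrix(j1), nAtoms(j1))
  expect_identical(deg[6], 5L) # super node connects all nA + nB atoms
  # removing the super node recovers the disjoint union
  e <- edgeMatrix(j1)
  expect_equal(
    e[e[, 1] != 6 & e[, 2] != 6, , drop = FALSE],
    rbind(edgeMatrix(gA), edgeMatrix(gB) + 3L)
  )

  j3 <- joinThreeSuperNodes(gA, gB)
  expect_identical(provenance(j3)[6:8], c("SUP1", "SUP2", "SUP"))
  deg3 <- tabulate(edgeMatrix(j3), nAtoms(j3))
  expect_identical(deg3[6:8], c(4L, 3L, 2L)) # Sup1 = nA + 1, Sup2 = nB + 1, Sup = 2
  # atoms of drug A never touch Sup2
  e3 <- edgeMatrix(j3)
  expect_false(any(e3[, 1] <= 3 & e3[, 2] == 7))
})

test_that("joint graphs are swap-invariant up to provenance-aware isomorphism", {
  gA <- smilesToGraph("CCO")
  gB <- smilesToGraph("c1ccccc1")
  colorOf <- function(j, swap = FALSE) {
    lv <- c("A", "B", "SUP1", "SUP2", "SUP")
    if (swap) lv <- c("B", "A", "SUP2", "SUP1", "SUP")
    match(provenance(j), lv)
  }
  for (m in c("super_edge", "all_nodes", "one_super_node", "three_super_nodes")) {
    jAB <- joinGraphs(gA, gB, method = m)
    jBA <- joinGraphs(gB, gA, method = m)
    igAB <- igraph::graph_from_edgelist(edgeMatrix(jAB), directed = FALSE)
    igBA <- igraph::graph_from_edgelist(edgeMatrix(jBA), directed = FALSE)
    expect_true(
      igraph::isomorphic(igAB, igBA,
        method = "vf2",
        vertex.color1 = colorOf(jAB), vertex.color2 = colorOf(jBA, swap = TRUE)
      ),
      label = m
    )
  }
})
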