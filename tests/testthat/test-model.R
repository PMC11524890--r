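# Dual-view network: attention normalisation, invariances, view contracts
# and the correctness of the hand-derived gradients.

tinyModel <- function(task = "regression", pool = "max", seed = 11L) {
  initSynergyModel(tinyConfig(task = task, pool = pool, seed = seed),
    tinyScaler,
    fpBits = 64L
  )
}

test_that("attention coefficients are softmax-normalised over every neighbourhood", {
  m <- tinyModel()
  for (k in 1:3) {
    j <- joinGraphs(
      tinyFeats$graphs[[k]], tinyFeats$graphs[[k %% 4 + 1]],
      method = "super_edge"
    )
    res <- gatEmbed(m, j, returnAttention = TRUE)
    for (l in seq_along(res$attention)) {
      al <- res$attention[[l]]
      for (h in seq_len(ncol(al))) {
        sums <- rowsum(al[, h], res$edges$dst)
        expect_true(all(abs(sums - 1) < 1e-5), label = sprintf("layer %d head %d", l, h))
      }
    }
  }
})

permuteJoint <- function(j, perm) {
  inv <- order(perm)
  e <- edgeMatrix(j)
  e <- cbind(inv[e[, 1]], inv[e[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  storage.mode(e) <- "integer"
  new("JointGraph",
    nodeFeatures = nodeFeatures(j)[perm, , drop = FALSE], edges = e,
    smiles = NA_character_, provenance = provenance(j)[perm],
    method = joinMethod(j), nA = j@nA, nB = j@nB
  )
}

test_that("the graph embedding is invariant to node permutations", {
  j <- joinGraphs(tinyFeats$graphs[[1]], tinyFeats$graphs[[2]], method = "super_edge")
  for (pool in c("max", "mean")) {
    m <- tinyModel(pool = pool)
    z <- gatEmbed(m, j)
    set.seed(5)
    for (r in 1:3) {
      perm <- sample(nAtoms(j))
      zp <- gatEmbed(m, permuteJoint(j, perm))
      expect_true(max(abs(z - zp)) < 1e-5, label = pool)
    }
  }
})

test_that("a single-node graph embeds as its own transformed features", {
  m <- tinyModel(pool = "max")
  j <- new("JointGraph",
    nodeFeatures = matrix(rnorm(78), 1, 78), edges = matrix(integer(0), 0, 2),
    smiles = NA_character_, provenance = "A", method = "super_edge",
    nA = 1L, nB = 0L
  )
  z <- gatEmbed(m, j)
  # with one node the attention is 1 and pooling is the identity
  w <- modelWeights(m)$gat
  h <- nodeFeatures(j)
  relu <- function(x) pmax(x, 0)
  for (l in 1:3) h <- relu(h %*% w[[l]]$W)
  expect_equal(unname(z), drop(h), tolerance = 1e-10)
})

test_that("view embeddings respect their structural contracts", {
  m <- tinyModel()
  bd <- dualsyn:::.prepareBatchData(tinyRecords, tinyFeats, tinyProf, "super_edge")
  gb <- dualsyn:::.assembleGraphBatch(bd$pieces)
  fw <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gb, bd$pairIdx,
    bd$Xcell, bd$FpA, bd$FpB
  )
  # ReLU outputs are non-negative
  expect_true(all(fw$ec$out >= 0))
  expect_true(all(fw$ce$out >= 0))
  # identical fingerprints through the shared encoder give identical embeddings
  recAA <- tinyRecords
  recAA$drug2 <- recAA$drug1
  bdA <- dualsyn:::.prepareBatchData(recAA[1, ], tinyFeats, tinyProf, "super_edge",
    symmetrize = FALSE
  )
  gbA <- dualsyn:::.assembleGraphBatch(bdA$pieces)
  fwA <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gbA, bdA$pairIdx,
    bdA$Xcell, bdA$FpA, bdA$FpB
  )
  expect_identical(fwA$dcA$out, fwA$dcB$out)
  # swapping drug order changes the view-2 embedding in general
  bdS <- dualsyn:::.prepareBatchData(tinyRecords[1, ], tinyFeats, tinyProf, "super_edge")
  gbS <- dualsyn:::.assembleGraphBatch(bdS$pieces)
  fwS <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gbS, bdS$pairIdx,
    bdS$Xcell, bdS$FpA, bdS$FpB
  )
  expect_gt(max(abs(fwS$ce$out[1, ] - fwS$ce$out[2, ])), 1e-8)
})

test_that("changing the cell profile changes the view-1 embedding", {
  m <- tinyModel()
  bd <- dualsyn:::.prepareBatchData(tinyRecords[1, ], tinyFeats, tinyProf, "super_edge",
    symmetrize = FALSE
  )
  gb <- dualsyn:::.assembleGraphBatch(bd$pieces)
  base <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gb, bd$pairIdx,
    bd$Xcell, bd$FpA, bd$FpB
  )
  bumped <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gb, bd$pairIdx,
    bd$Xcell + 0.1, bd$FpA, bd$FpB
  )
  expect_gt(max(abs(base$ec$out - bumped$ec$out)), 1e-8)
})

test_that("classification probabilities are a proper softmax", {
  m <- tinyModel(task = "classification")
  bd <- dualsyn:::.prepareBatchData(tinyRecords, tinyFeats, tinyProf, "super_edge")
  gb <- dualsyn:::.assembleGraphBatch(bd$pieces)
  fw <- dualsyn:::.modelForward(
    modelWeights(m), modelConfig(m), gb, bd$pairIdx,
    bd$Xcell, bd$FpA, bd$FpB
  )
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-6))
  expect_true(all(fw$probs >= 0))
})

test_that("zeroed prediction-net weights reduce the output to the head bias", {
  m <- tinyModel()
  w <- modelWeights(m)
  for (nm in c("W1", "W2", "W3", "Wout")) w$pred[[nm]][] <- 0
  w$pred$bout <- 0.7
  m@weights <- w
  p <- predictTriplets(m, tinyRecords, tinyFeats, tinyProf)
  expect_equal(p, rep(0.7, nrow(tinyRecords)))
})

test_that("triplet predictions are exactly symmetric and deterministic", {
  m <- tinyModel()
  p1 <- predictTriplet(
    m, tinyRecords$drug1[1], tinyRecords$drug2[1],
    tinyRecords$cell[1], tinyFeats, tinyProf
  )
  p2 <- predictTriplet(
    m, tinyRecords$drug2[1], tinyRecords$drug1[1],
    tinyRecords$cell[1], tinyFeats, tinyProf
  )
  expect_identical(p1, p2)
  expect_identical(
    p1,
    predictTriplet(
      m, tinyRecords$drug1[1], tinyRecords$drug2[1],
      tinyRecords$cell[1], tinyFeats, tinyProf
    )
  )
})

test_that("a forward pass runs on large joint graphs for all four join methods", {
  # two ~25-atom drugs give a ~50-node joint graph
  big <- data.frame(
    drug_name = c("x", "y"),
    smiles = c(
      "CC12CCC(O)CC1=CCC1C2CCC2(C)C(=CC12)c1cccnc1",
      "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(O)=O"
    )
  )
  feats <- featurizeDrugs(big, fpBits = 64)
  rec <- data.frame(drug1 = "x", drug2 = "y", cell = colnames(tinyExpr)[1], score = 0)
  for (m in c("super_edge", "all_nodes", "one_super_node", "three_super_nodes")) {
    mod <- initSynergyModel(tinyConfig(), tinyScaler, fpBits = 64L, joinMethod = m)
    expect_length(predictTriplets(mod, rec, feats, tinyProf), 1L)
  }
})

test_that("analytic gradients match finite differences", {
  for (task in c("regression", "classification")) {
    cfg <- tinyConfig(task = task)
    m <- initSynergyModel(cfg, tinyScaler, fpBits = 64L)
    bd <- dualsyn:::.prepareBatchData(tinyRecords, tinyFeats, tinyProf, "super_edge")
    y <- dualsyn:::.targets(bd$records, task)
    gb <- dualsyn:::.assembleGraphBatch(bd$pieces)
    w <- modelWeights(m)
    lossAt <- function(w) {
      fw <- dualsyn:::.modelForward(w, cfg, gb, bd$pairIdx, bd$Xcell, bd$FpA, bd$FpB)
      dualsyn:::.lossAndGrad(fw, y, task)$loss
    }
    fw <- dualsyn:::.modelForward(w, cfg, gb, bd$pairIdx, bd$Xcell, bd$FpA, bd$FpB,
      keepCache = TRUE
    )
    lg <- dualsyn:::.lossAndGrad(fw, y, task)
    gr <- dualsyn:::.modelBackward(lg$dOut, fw, w, cfg, gb, bd$pairIdx)
    probes <- list(
      list("gat", 1L, "W"), list("gat", 2L, "aS"), list("gat", 3L, "aD"),
      list("cell", "W1"), list("ec", "W"), list("dc", "W"), list("ce", "b"),
      list("pred", "W2"), list("pred", "bout")
    )
    setLeaf <- function(x, path, i, v) {
      if (!length(path)) {
        x[i] <- v
        return(x)
      }
      x[[path[[1]]]] <- setLeaf(x[[path[[1]]]], path[-1], i, v)
      x
    }
    set.seed(3)
    for (pth in probes) {
      wl <- w
      gl <- gr
      for (k in pth) {
        wl <- wl[[k]]
        gl <- gl[[k]]
      }
      i <- sample(length(wl), 1)
      eps <- 1e-5
      num <- (lossAt(setLeaf(w, pth, i, wl[i] + eps)) -
        lossAt(setLeaf(w, pth, i, wl[i] - eps))) / (2 * eps)
      expect_equal(gl[i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip and prediction refuses mismatched features", {
  m <- tinyModel()
  d <- withr::local_tempdir()
  f <- file.path(d, "model.rds")
  saveSynergyModel(m, f)
  m2 <- loadSynergyModel(f)
  expect_identical(modelWeights(m2), modelWeights(m))
  expect_identical(
    predictTriplets(m2, tinyRecords, tinyFeats, tinyProf),
    predictTriplets(m, tinyRecords, tinyFeats, tinyProf)
  )
  featsWrong <- featurizeDrugs(tinyDrugs, fpBits = 128)
  expect_error(predictTriplets(m, tinyRecords, featsWrong, tinyProf), "mismatch")
  profWrong <- tinyProf[, rev(seq_len(ncol(tinyProf)))]
  expect_error(predictTriplets(m, tinyRecords, tinyFeats, profWrong), "panel")
})
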