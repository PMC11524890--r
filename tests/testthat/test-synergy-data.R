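# Replicate filtering, class labels, triplet assembly, split plans and
# k-shot augmentation.

test_that("replicate filter reproduces the hand-computed truth table", {
  expect_true(is.na(filterReplicates(c(10, -5)))) # sign conflict
  expect_true(is.na(filterReplicates(c(10, 30)))) # CV = 14.14/20 = 0.707 > 0.5
  expect_identical(filterReplicates(c(10, 12, 14)), 12) # CV = 2/12 = 0.167, median 12
  expect_identical(filterReplicates(5), 5) # singleton never CV-excluded
  expect_identical(filterReplicates(-5), -5)
  expect_true(is.na(filterReplicates(c(0, 5, 6)))) # no sign conflict, but CV 0.88
  expect_identical(filterReplicates(c(0, 0, 0)), 0) # all-equal at mean zero kept
  expect_true(is.na(filterReplicates(c(-1, 1)))) # mean ~ 0: CV undefined
  expect_error(filterReplicates(numeric(0)), "empty")
})

test_that("class labels honour the additive dead band", {
  expect_identical(labelClasses(50), "synergistic")
  expect_identical(labelClasses(0), NA_character_)
  expect_identical(labelClasses(-20), "antagonistic")
  expect_identical(labelClasses(10), NA_character_) # boundary is additive
  expect_identical(labelClasses(c(15, -15, 3)), c("synergistic", "antagonistic", NA))
  expect_identical(labelClasses(4, posThr = 3, negThr = -3), "synergistic")
})

test_that("unordered pair identity collapses replicate rows", {
  tab <- data.frame(
    drug1 = c("A", "B", "A"), drug2 = c("B", "A", "B"),
    cell = "c1", score = c(10, 12, 14)
  )
  out <- aggregateReplicates(tab)
  expect_identical(nrow(out), 1L)
  expect_identical(out$drug1, "A")
  expect_identical(out$score, 12)
  expect_error(
    aggregateReplicates(data.frame(drug1 = "A", drug2 = "A", cell = "c", score = 1)),
    "distinct"
  )
})

test_that("split plans satisfy their disjointness contracts and determinism", {
  spec <- fixtureSpec(nDrugs = 8, nCells = 10, badFraction = 0, seed = 2)
  drugs <- makeDrugLibrary(spec$nDrugs, seed = spec$seed)
  expr <- makeExpression(spec$nCells, spec$nGenes, seed = spec$seed + 2L)
  rec <- suppressMessages(aggregateReplicates(makeSynergy(drugs, expr, spec)$replicates))

  for (strat in c("random", "pair_out", "cell_out", "drug_out")) {
    p1 <- makeSplits(rec, strat, seed = 7)
    p2 <- makeSplits(rec, strat, seed = 7)
    expect_identical(foldAssignments(p1), foldAssignments(p2)) # same seed, same plan
    for (f in seq_len(nFolds(p1))) {
      fl <- splitFold(p1, f)
      expect_length(intersect(fl$train, fl$test), 0)
      expect_setequal(c(fl$train, fl$test, fl$dropped), seq_len(nrow(rec)))
      tr <- rec[fl$train, ]
      te <- rec[fl$test, ]
      if (strat == "pair_out") {
        expect_length(intersect(
          paste(tr$drug1, tr$drug2),
          paste(te$drug1, te$drug2)
        ), 0)
      }
      if (strat == "cell_out") expect_length(intersect(tr$cell, te$cell), 0)
      if (strat == "drug_out") {
        expect_length(intersect(c(tr$drug1, tr$drug2), c(te$drug1, te$drug2)), 0)
      }
    }
  }
  expect_error(makeSplits(rec[1:3, ], "cell_out", nFolds = 5), "fewer")
})

test_that("strict both-drugs-out mode drops singly contaminated triplets", {
  spec <- fixtureSpec(nDrugs = 8, nCells = 6, badFraction = 0, seed = 3)
  drugs <- makeDrugLibrary(spec$nDrugs, seed = spec$seed)
  expr <- makeExpression(spec$nCells, spec$nGenes, seed = spec$seed + 2L)
  rec <- suppressMessages(aggregateReplicates(makeSynergy(drugs, expr, spec)$replicates))
  p <- makeSplits(rec, "drug_out", seed = 5, drugOutMode = "both")
  fl <- splitFold(p, 1)
  te <- rec[fl$test, ]
  held <- names(p@entityFold)[p@entityFold == 1]
  expect_true(all(te$drug1 %in% held & te$drug2 %in% held))
  expect_gt(length(fl$dropped), 0)
})

test_that("k-shot augmentation moves records without loss or duplication", {
  spec <- fixtureSpec(nDrugs = 8, nCells = 10, badFraction = 0, seed = 4)
  drugs <- makeDrugLibrary(spec$nDrugs, seed = spec$seed)
  expr <- makeExpression(spec$nCells, spec$nGenes, seed = spec$seed + 2L)
  rec <- suppressMessages(aggregateReplicates(makeSynergy(drugs, expr, spec)$replicates))

  plan <- makeSplits(rec, "cell_out", seed = 9)
  cell <- rec$cell[splitFold(plan, 2)$test][1]
  fold <- unname(plan@entityFold[cell])
  base <- splitFold(plan, fold)

  k0 <- kshotAugment(plan, fold, cell, k = 0)
  expect_identical(k0$train, sort(base$train)) # k = 0 leaves the plan unchanged
  expect_identical(sort(k0$test), sort(base$test))

  k3 <- kshotAugment(plan, fold, cell, k = 3, seed = 2)
  expect_length(k3$moved, 3)
  expect_true(all(k3$moved %in% k3$train))
  expect_length(intersect(k3$train, k3$test), 0)
  expect_setequal(c(k3$train, k3$test), setdiff(seq_len(nrow(rec)), splitFold(plan, fold)$dropped))
  expect_identical(kshotAugment(plan, fold, cell, k = 3, seed = 2)$moved, k3$moved)

  avail <- sum(rec$cell[base$test] == cell)
  kAll <- expect_warning(
    kshotAugment(plan, fold, cell, k = avail + 100, seed = 2),
    "available"
  )
  expect_length(kAll$test[rec$cell[kAll$test] == cell], 0) # test emptied

  # pair_out: k cells of a held-out pair move
  pp <- makeSplits(rec, "pair_out", seed = 9)
  fl1 <- splitFold(pp, 1)
  pair <- unlist(rec[fl1$test[1], c("drug1", "drug2")], use.names = FALSE)
  kp <- kshotAugment(pp, 1, pair, k = 2, seed = 3)
  expect_length(kp$moved, 2)
  moved <- rec[kp$moved, ]
  expect_true(all(moved$drug1 == pair[1] & moved$drug2 == pair[2]))
})

test_that("triplet tables round-trip through CSV with filtering applied", {
  d <- withr::local_tempdir()
  tab <- data.frame(
    drug1 = c("A", "A", "A", "B", "B"),
    drug2 = c("B", "B", "B", "C", "C"),
    cell = "c1",
    score = c(10, 12, 14, 10, -5),
    replicate_id = c(1, 2, 3, 1, 2)
  )
  f <- file.path(d, "trip.csv")
  write.csv(tab, f, row.names = FALSE)
  out <- suppressMessages(readTriplets(f, posThr = 5))
  expect_identical(nrow(out), 1L) # B-C excluded by sign conflict
  expect_identical(out$score, 12)
  expect_identical(out$label, "synergistic")
})
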