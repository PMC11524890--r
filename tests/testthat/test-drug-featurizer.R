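# SMILES parsing, the 78-dim atom feature layout and circular fingerprints.

# Reference atom/bond counts computed with an independent cheminformatics
# toolkit (RDKit) and frozen here.
refMolecules <- list(
  list(name = "abiraterone", smiles = "CC12CCC(O)CC1=CCC1C2CCC2(C)C(=CC12)c1cccnc1", atoms = 25L, bonds = 29L),
  list(name = "atorvastatin", smiles = "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(O)=O", atoms = 41L, bonds = 44L),
  list(name = "bortezomib_frag", smiles = "CC(C)CC(NC(=O)C(Cc1ccccc1)NC(=O)c1cnccn1)B(O)O", atoms = 28L, bonds = 29L),
  list(name = "busulfan", smiles = "CS(=O)(=O)OCCCCOS(C)(=O)=O", atoms = 14L, bonds = 13L),
  list(name = "caffeine", smiles = "Cn1cnc2c1c(=O)n(C)c(=O)n2C", atoms = 14L, bonds = 15L),
  list(name = "carboplatin", smiles = "O=C1OC(=O)C2(CCC2)C(=O)O1", atoms = 12L, bonds = 13L),
  list(name = "cocaine", smiles = "COC(=O)C1C(OC(=O)c2ccccc2)CC2CCC1N2C", atoms = 22L, bonds = 24L),
  list(name = "dacarbazine", smiles = "CN(C)/N=N/c1[nH]cnc1C(N)=O", atoms = 13L, bonds = 13L),
  list(name = "dexamethasone", smiles = "CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO", atoms = 28L, bonds = 31L),
  list(name = "erlotinib", smiles = "COCCOc1cc2ncnc(Nc3cccc(c3)C#C)c2cc1OCCOC", atoms = 29L, bonds = 31L),
  list(name = "fluoxetine", smiles = "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1", atoms = 22L, bonds = 23L),
  list(name = "hydrochlorothiazide", smiles = "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O", atoms = 17L, bonds = 18L),
  list(name = "lomustine", smiles = "O=C(NC1CCCCC1)N(CCCl)N=O", atoms = 15L, bonds = 15L),
  list(name = "morphine", smiles = "CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5", atoms = 21L, bonds = 25L),
  list(name = "nifedipine", smiles = "COC(=O)C1=C(C)NC(C)=C(C1c1ccccc1[N+]([O-])=O)C(=O)OC", atoms = 25L, bonds = 26L),
  list(name = "phenytoin", smiles = "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1", atoms = 19L, bonds = 21L),
  list(name = "piroxicam", smiles = "CN1c2ccccc2S(=O)(=O)C=C1C(=O)Nc1ccccn1", atoms = 22L, bonds = 24L),
  list(name = "procaine", smiles = "CCN(CC)CCOC(=O)c1ccc(N)cc1", atoms = 17L, bonds = 17L),
  list(name = "sertraline", smiles = "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12", atoms = 20L, bonds = 22L),
  list(name = "vorinostat", smiles = "ONC(=O)CCCCCCC(=O)Nc1ccccc1", atoms = 19L, bonds = 19L)
)

test_that("atom and bond counts agree with the reference toolkit on 20 molecules", {
  for (m in refMolecules) {
    g <- smilesToGraph(m$smiles)
    expect_identical(nAtoms(g), m$atoms, label = m$name)
    expect_identical(nrow(edgeMatrix(g)), m$bonds, label = m$name)
  }
})

test_that("small-molecule graphs have the expected topology and layout", {
  g1 <- smilesToGraph("C") # methane: one heavy atom
  expect_identical(nAtoms(g1), 1L)
  expect_identical(nrow(edgeMatrix(g1)), 0L)
  expect_identical(ncol(nodeFeatures(g1)), 78L)

  g2 <- smilesToGraph("CCO") # ethanol chain
  expect_identical(nAtoms(g2), 3L)
  expect_equal(unname(edgeMatrix(g2)), matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE))

  g3 <- smilesToGraph("c1ccccc1") # benzene
  expect_identical(nAtoms(g3), 6L)
  expect_identical(nrow(edgeMatrix(g3)), 6L)
  # aromatic flag is the final feature column
  expect_true(all(nodeFeatures(g3)[, 78] == 1))
  expect_true(all(nodeFeatures(smilesToGraph("CCO"))[, 78] == 0))
})

test_that("every node row activates exactly one bit per one-hot block", {
  for (m in refMolecules[1:8]) {
    f <- nodeFeatures(smilesToGraph(m$smiles))
    expect_true(all(rowSums(f[, 1:44, drop = FALSE]) == 1), label = m$name)
    expect_true(all(rowSums(f[, 45:55, drop = FALSE]) == 1), label = m$name)
    expect_true(all(rowSums(f[, 56:66, drop = FALSE]) == 1), label = m$name)
    expect_true(all(rowSums(f[, 67:77, drop = FALSE]) == 1), label = m$name)
    expect_true(all(f[, 78] %in% c(0, 1)), label = m$name)
  }
})

test_that("hydrogen counts match the reference toolkit per atom", {
  # total hydrogens per heavy atom, frozen from an RDKit parse
  refH <- list(
    "CC(=O)Oc1ccccc1C(=O)O" = c(3, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 1),
    "CN1CCCC1c1cccnc1" = c(3, 0, 2, 2, 2, 1, 0, 1, 1, 1, 0, 1)
  )
  for (smi in names(refH)) {
    f <- nodeFeatures(smilesToGraph(smi))
    hBlock <- f[, 56:66, drop = FALSE]
    expect_equal(unname(apply(hBlock, 1, which.max) - 1), refH[[smi]], label = smi)
  }
})

test_that("features are invariant to how the same molecule is written", {
  feats <- function(s) {
    g <- smilesToGraph(s)
    f <- nodeFeatures(g)
    f[do.call(order, as.data.frame(f)), ] # sort rows: order-free comparison
  }
  expect_equal(feats("c1ccccc1"), feats("C1=CC=CC=C1"))
  expect_equal(feats("CC(N)=O"), feats("O=C(C)N"))
})

test_that("unparseable and degenerate SMILES raise informative errors", {
  expect_error(smilesToGraph("not a smiles"), "not a smiles")
  expect_error(smilesToGraph(""), "invalid SMILES")
  expect_error(smilesToFingerprint("xx(("), "cannot parse")
  expect_error(smilesToFingerprint("C", nBits = 32), "nBits")
})

test_that("fingerprints are deterministic and order-invariant", {
  bits <- function(s, n = 1024L) as.integer(smilesToFingerprint(s, nBits = n))
  expect_identical(bits("CCO"), bits("CCO"))
  expect_identical(bits("CCO"), bits("OCC"))
  expect_identical(bits("c1ccccc1"), bits("C1=CC=CC=C1"))
  expect_identical(
    bits("CC(=O)Oc1ccccc1C(=O)O"),
    bits("OC(=O)c1ccccc1OC(C)=O")
  )
  # single-environment molecule: exactly one bit at any length
  expect_identical(sum(bits("C")), 1L)
  expect_identical(sum(bits("C", 4096L)), 1L)
  fp <- smilesToFingerprint("CCO", nBits = 256L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_length(fp, 256L)
})

test_that("canonicalisation maps atom orderings to one representation", {
  expect_identical(canonicalSmiles("CCO"), canonicalSmiles("OCC"))
  expect_error(canonicalSmiles("(((("), "cannot parse")
})

test_that("featurizeDrugs caches by canonical SMILES and round-trips a drug table", {
  tab <- data.frame(
    drug_name = c("a", "b"), smiles = c("CCO", "OCC"),
    stringsAsFactors = FALSE
  )
  res <- featurizeDrugs(tab, fpBits = 64)
  expect_named(res$graphs, c("a", "b"))
  expect_identical(res$fingerprints["a", ], res$fingerprints["b", ])
  # cache primed: same environment is reused and already holds the key
  expect_gt(length(ls(res$cache)), 0)
  res2 <- featurizeDrugs(tab, fpBits = 64, cache = res$cache)
  expect_identical(res$fingerprints, res2$fingerprints)

  d <- withr::local_tempdir()
  f <- file.path(d, "drugs.csv")
  write.csv(tab, f, row.names = FALSE)
  expect_identical(readDrugTable(f)$smiles, tab$smiles)
  expect_error(readDrugTable({
    f2 <- file.path(d, "bad.csv")
    write.csv(data.frame(x = 1), f2, row.names = FALSE)
    f2
  }), "drug_name")

  # on-disk store
  cd <- file.path(d, "fpcache")
  featurizeDrugs(tab, fpBits = 64, cacheDir = cd)
  expect_gt(length(list.files(cd)), 0)
})
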