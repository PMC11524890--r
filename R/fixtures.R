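# Self-contained synthetic fixtures: a drug library of real small-molecule
# SMILES (plus generated alkanes/alcohols), an expression matrix with
# correlated gene blocks, and synergy scores generated by a planted function
# of drug substructure and expression features.
#
# The planted score of triplet (A, B, c) is
#   score = sdDrug * z1(<AND(fpA, fpB), beta>) + sdCell * z2(<blockMeans_c,
#           gamma_AB>) + eps,  eps ~ N(0, noiseSd),
# where z1/z2 standardise each component to unit variance so that sdDrug and
# sdCell are the component standard deviations on the score scale.  The two
# components mirror the two information sources the dual-view model consumes
# (shared fingerprint substructure and expression state); the AND of the two
# fingerprints makes the score symmetric in the pair by construction.

.curatedSmiles <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  gefitinib = "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1",
  erlotinib = "COCCOc1cc2ncnc(Nc3cccc(c3)C#C)c2cc1OCCOC",
  imatinib = "Cc1ccc(cc1Nc1nccc(n1)-c1cccnc1)NC(=O)c1ccc(cc1)CN1CCN(C)CC1",
  sorafenib = "CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(c3)C(F)(F)F)cc2)ccn1",
  sunitinib = "CCN(CC)CCNC(=O)c1c(C)[nH]c(c1C)/C=C1\\C(=O)Nc2ccc(F)cc12",
  lapatinib = "CS(=O)(=O)CCNCc1ccc(o1)-c1ccc2ncnc(Nc3ccc(OCc4cccc(F)c4)c(Cl)c3)c2c1",
  dasatinib = "Cc1nc(Nc2ncc(s2)C(=O)Nc2c(C)cccc2Cl)cc(n1)N1CCN(CCO)CC1",
  `5FU` = "O=c1[nH]cc(F)c(=O)[nH]1",
  gemcitabine = "NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1(F)F",
  methotrexate = "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(O)=O)C(O)=O",
  doxorubicin = "COc1cccc2C(=O)c3c(O)c4CC(O)(CC(OC5CC(N)C(O)C(C)O5)c4c(O)c3C(=O)c12)C(=O)CO",
  paclitaxel = "CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(c1ccccc1)NC(=O)c1ccccc1)O)O)OC(=O)c1ccccc1)(CO4)OC(C)=O)O)C)OC(C)=O",
  etoposide = "COc1cc(cc(OC)c1O)C1c2cc3OCOc3cc2C(OC2OC3COC(C)OC3C(O)C2O)C2COC(=O)C12",
  topotecan = "CCC1(O)C(=O)OCc2c1cc1n(c2=O)Cc2cc3c(CN(C)C)c(O)ccc3nc21",
  carboplatin = "O=C1OC(=O)C2(CCC2)C(=O)O1",
  temozolomide = "Cn1nnc2c(ncn2c1=O)C(N)=O",
  vorinostat = "ONC(=O)CCCCCCC(=O)Nc1ccccc1",
  dexamethasone = "CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO",
  celecoxib = "Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F",
  metformin = "CN(C)C(=N)N=C(N)N",
  warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  quercetin = "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O",
  resveratrol = "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",
  atorvastatin = "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(O)=O",
  simvastatin = "CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12",
  penicillinG = "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(O)=O",
  ciprofloxacin = "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",
  sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
  trimethoprim = "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",
  fluconazole = "OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F",
  omeprazole = "COc1ccc2[nH]c(nc2c1)S(=O)Cc1ncc(C)c(OC)c1C",
  loratadine = "CCOC(=O)N1CCC(CC1)=C1c2ccc(Cl)cc2CCc2cccnc12",
  diazepam = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
  fluoxetine = "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",
  sertraline = "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12",
  morphine = "CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5",
  nicotine = "CN1CCCC1c1cccnc1",
  cocaine = "COC(=O)C1C(OC(=O)c2ccccc2)CC2CCC1N2C",
  atropine = "CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",
  lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
  procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
  ketamine = "CNC1(CCCCC1=O)c1ccccc1Cl",
  propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
  metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
  verapamil = "COc1ccc(CCN(C)CCCC(C#N)(C(C)C)c2ccc(OC)c(OC)c2)cc1OC",
  nifedipine = "COC(=O)C1=C(C)NC(C)=C(C1c1ccccc1[N+]([O-])=O)C(=O)OC",
  losartan = "CCCCc1nc(Cl)c(CO)n1Cc1ccc(cc1)-c1ccccc1-c1nnn[nH]1",
  hydrochlorothiazide = "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",
  furosemide = "NS(=O)(=O)c1cc(C(O)=O)c(NCc2ccco2)cc1Cl",
  allopurinol = "O=c1[nH]cnc2[nH]ncc12",
  theophylline = "Cn1c2[nH]cnc2c(=O)n(C)c1=O",
  chloroquine = "CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12",
  primaquine = "COc1cc(NC(C)CCCN)c2ncccc2c1",
  isoniazid = "NNC(=O)c1ccncc1",
  rifampicin_frag = "Cc1ccc(cc1)N1CCN(C)CC1",
  abiraterone = "CC12CCC(O)CC1=CCC1C2CCC2(C)C(=CC12)c1cccnc1",
  tamoxifen = "CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1",
  raloxifene = "Oc1ccc2c(c1)sc(-c1ccc(O)cc1)c2C(=O)c1ccc(OCCN2CCCCC2)cc1",
  bicalutamide = "CC(O)(CS(=O)(=O)c1ccc(F)cc1)C(=O)Nc1ccc(C#N)c(c1)C(F)(F)F",
  olaparib = "O=C(c1cc(Cc2n[nH]c(=O)c3ccccc23)ccc1F)N1CCN(CC1)C(=O)C1CC1",
  vemurafenib = "CCCS(=O)(=O)Nc1ccc(F)c(c1F)C(=O)c1c[nH]c2ncc(cc12)-c1ccc(Cl)cc1",
  dabrafenib = "CC(C)(C)c1nc(-c2cccc(NS(=O)(=O)c3c(F)cccc3F)c2F)c(s1)-c1ccnc(N)n1",
  trametinib_frag = "CC(=O)Nc1ccc2c(c1)ncn2C1CC1",
  palbociclib = "CC(=O)c1c(C)c2cnc(Nc3ccc(cn3)N3CCNCC3)nc2n(C1=O)C1CCCC1",
  crizotinib = "CC(Oc1cc(ccc1Cl)-c1cnn(c1)C1CCNCC1)c1cc(F)ccc1N",
  axitinib = "CNC(=O)c1ccccc1Sc1ccc2c(c1)cnn2/C=C/c1ccccn1",
  bortezomib_frag = "CC(C)CC(NC(=O)C(Cc1ccccc1)NC(=O)c1cnccn1)B(O)O",
  lenalidomide = "NC1=CC=CC2=C1CN(C1CCC(=O)NC1=O)C2=O",
  azathioprine = "Cn1cnc(c1Sc1ncnc2[nH]cnc12)[N+]([O-])=O",
  mercaptopurine = "Sc1ncnc2[nH]cnc12",
  cytarabine = "NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1O",
  decitabine = "NC1=NC(=O)N(C=N1)C1CC(O)C(CO)O1",
  cladribine = "Nc1nc(Cl)nc2n(cnc12)C1CC(O)C(CO)O1",
  melphalan = "NC(Cc1ccc(cc1)N(CCCl)CCCl)C(O)=O",
  chlorambucil = "OC(=O)CCCc1ccc(cc1)N(CCCl)CCCl",
  busulfan = "CS(=O)(=O)OCCCCOS(C)(=O)=O",
  lomustine = "O=C(NC1CCCCC1)N(CCCl)N=O",
  dacarbazine = "CN(C)/N=N/c1[nH]cnc1C(N)=O",
  procarbazine = "CNNCc1ccc(cc1)C(=O)NC(C)C",
  hydroxyurea = "NC(=O)NO",
  thalidomide = "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",
  menadione = "CC1=CC(=O)c2ccccc2C1=O",
  folicacid = "Nc1nc2ncc(CNc3ccc(cc3)C(=O)NC(CCC(O)=O)C(O)=O)nc2c(=O)[nH]1",
  biotin = "OC(=O)CCCCC1SCC2NC(=O)NC12",
  ascorbate = "OCC(O)C1OC(=O)C(O)=C1O",
  salicylate = "OC(=O)c1ccccc1O",
  benzocaine = "CCOC(=O)c1ccc(N)cc1",
  coumarin = "O=c1ccc2ccccc2o1",
  indomethacin = "COc1ccc2c(c1)c(CC(O)=O)c(C)n2C(=O)c1ccc(Cl)cc1",
  piroxicam = "CN1c2ccccc2S(=O)(=O)C=C1C(=O)Nc1ccccn1",
  phenytoin = "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1",
  carbamazepine = "NC(=O)N1c2ccccc2C=Cc2ccccc12",
  valproate = "CCCC(CCC)C(O)=O",
  gabapentin = "NCC1(CC(O)=O)CCCCC1"
)

#' Synthetic fixture specification
#'
#' Study conditions of the synthetic benchmark: counts, planted effect sizes
#' (component standard deviations on the synergy-score scale), replicate
#' noise, the fraction of triplets given deliberately unreliable replicates,
#' and the strength of the planted domain shift used by the fine-tuning
#' scenario.
#'
#' @param nDrugs,nCells,nGenes library sizes.
#' @param nBlocks,rho correlated gene blocks and their within-block
#'   correlation.
#' @param nTriplets optional cap on the number of triplets (sampled from the
#'   full pair-by-cell grid).
#' @param replicates measurements per triplet.
#' @param sdDrug,sdCell standard deviations of the fingerprint and
#'   expression-interaction components of the planted score.
#' @param noiseSd triplet-level noise sd.
#' @param repNoiseSd replicate-level noise sd.
#' @param badFraction fraction of triplets given sign-conflicting or
#'   high-variance replicates (to exercise the replicate filter).
#' @param domainShift sd of the additional score shift applied to the last
#'   20% of cell lines (0 = no shift).
#' @param fpBits fingerprint length used by the generator.
#' @param seed master seed; everything the generator draws derives from it.
#' @return a specification list of class `fixtureSpec`.
#' @export
fixtureSpec <- function(nDrugs = 12L, nCells = 30L, nGenes = 64L, nBlocks = 4L,
                        rho = 0.7, nTriplets = NULL, replicates = 3L,
                        sdDrug = 8.5, sdCell = 5.3, noiseSd = 3,
                        repNoiseSd = 1, badFraction = 0.05, domainShift = 0,
                        fpBits = 256L, seed = 1L) {
  stopifnot(
    nDrugs >= 2, nCells >= 1, nGenes >= nBlocks, nBlocks >= 1,
    rho >= 0, rho < 1, replicates >= 1, badFraction >= 0, badFraction <= 1
  )
  structure(
    list(
      nDrugs = as.integer(nDrugs), nCells = as.integer(nCells),
      nGenes = as.integer(nGenes), nBlocks = as.integer(nBlocks), rho = rho,
      nTriplets = nTriplets, replicates = as.integer(replicates),
      sdDrug = sdDrug, sdCell = sdCell, noiseSd = noiseSd,
      repNoiseSd = repNoiseSd, badFraction = badFraction,
      domainShift = domainShift, fpBits = as.integer(fpBits),
      seed = as.integer(seed)
    ),
    class = "fixtureSpec"
  )
}

.randomAlkanol <- function() {
  n <- sample(2:8, 1)
  atoms <- rep("C", n)
  if (n >= 4 && runif(1) < 0.5) {
    pos <- sample(2:(n - 1), 1)
    atoms[pos] <- "C(C)"
  }
  smi <- paste(atoms, collapse = "")
  if (runif(1) < 0.5) smi <- paste0(smi, "O")
  smi
}

#' Generate a drug library
#'
#' Draws unique, parseable SMILES: first from a curated in-package list of
#' real small molecules, then (if more are requested) generated linear or
#' branched alkanes/alcohols.  Every entry is validated through the
#' featurizer.
#'
#' @param nDrugs number of drugs.
#' @param seed RNG seed.
#' @param validate parse every SMILES through [smilesToGraph()] (default
#'   TRUE).
#' @return data.frame with columns `drug_name`, `smiles`.
#' @export
makeDrugLibrary <- function(nDrugs, seed = 1L, validate = TRUE) {
  stopifnot(.isCount(nDrugs), nDrugs >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- min(nDrugs, length(.curatedSmiles))
  pick <- .sampleVec(seq_along(.curatedSmiles), take)
  smiles <- unname(.curatedSmiles[pick])
  names <- names(.curatedSmiles)[pick]
  while (length(smiles) < nDrugs) {
    cand <- .randomAlkanol()
    if (!cand %in% smiles) {
      smiles <- c(smiles, cand)
      names <- c(names, sprintf("alkanol_%03d", length(smiles) - take))
    }
  }
  if (validate) {
    for (s in smiles) smilesToGraph(s) # errors on any invalid entry
  }
  data.frame(drug_name = names, smiles = smiles, stringsAsFactors = FALSE)
}

#' Generate a block-correlated expression matrix
#'
#' Log-normal TPM with `nBlocks` correlated gene blocks: gene g in block b
#' has `log2(TPM) = mu_g + sd_g * (sqrt(rho) f_b + sqrt(1 - rho) eps)`, so
#' genes within a block share the latent factor `f_b` with correlation `rho`
#' while genes of different blocks are independent.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param nBlocks,rho block count and within-block correlation.
#' @param seed RNG seed.
#' @return genes-by-cells TPM matrix (all entries > 0), with gene symbols
#'   `G001..` and cell ids `CELL01..`; the block of each gene is attached as
#'   attribute `block`.
#' @export
makeExpression <- function(nCells, nGenes = 64L, nBlocks = 4L, rho = 0.7, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  block <- rep_len(seq_len(nBlocks), nGenes)
  mu <- rnorm(nGenes, mean = 5, sd = 2)
  sdg <- runif(nGenes, 0.5, 1.5)
  f <- matrix(rnorm(nBlocks * nCells), nBlocks, nCells)
  eps <- matrix(rnorm(nGenes * nCells), nGenes, nCells)
  x <- mu + sdg * (sqrt(rho) * f[block, , drop = FALSE] + sqrt(1 - rho) * eps)
  tpm <- 2^x
  dimnames(tpm) <- list(
    sprintf("G%03d", seq_len(nGenes)),
    sprintf("CELL%02d", seq_len(nCells))
  )
  attr(tpm, "block") <- block
  tpm
}

#' Generate planted-signal synergy measurements
#'
#' Builds the full (or subsampled) pair-by-cell triplet grid and draws
#' replicate synergy scores from the planted model described in
#' [fixtureSpec()].  A `badFraction` of triplets receives deliberately
#' unreliable replicates (half with a sign conflict, half with a coefficient
#' of variation of 0.75) so that the replicate filter has something to
#' remove.  With `domainShift > 0` the last 20% of cell lines get an extra
#' score shift composed of a per-cell offset and a fingerprint-linked pair
#' term, emulating a systematic domain difference that k-shot fine-tuning
#' can adapt to.
#'
#' @param drugLib output of [makeDrugLibrary()].
#' @param expression output of [makeExpression()].
#' @param spec a [fixtureSpec()].
#' @return a list with `replicates` (data.frame `drug1,drug2,cell,score,
#'   replicate_id`, one row per measurement), `truth` (per-triplet
#'   data.frame with the noise-free planted `signal`, the realised `score`
#'   and the `unreliable` flag) and `shiftedCells`.
#' @export
makeSynergy <- function(drugLib, expression, spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)

  fps <- t(vapply(
    drugLib$smiles,
    function(s) smilesToFingerprint(s, nBits = spec$fpBits),
    integer(spec$fpBits)
  ))
  rownames(fps) <- drugLib$drug_name
  pairs <- t(combn(drugLib$drug_name, 2L))
  nPairs <- nrow(pairs)
  andMat <- fps[pairs[, 1], , drop = FALSE] * fps[pairs[, 2], , drop = FALSE]

  nBeta <- max(4L, round(0.15 * spec$fpBits))
  beta <- numeric(spec$fpBits)
  beta[.sampleVec(seq_len(spec$fpBits), nBeta)] <- rnorm(nBeta)
  drugComp <- drop(andMat %*% beta)
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  drugComp <- zs(drugComp)

  cells <- colnames(expression)
  block <- attr(expression, "block")
  lg <- log2(expression + 1)
  blockMeans <- apply(
    lg, 2L,
    function(col) tapply(col, block, mean)
  ) # nBlocks x nCells
  blockMeans <- t(scale(t(blockMeans))) # z-score each block across cells
  gamma <- matrix(rnorm(nPairs * spec$nBlocks), nPairs, spec$nBlocks)

  grid <- expand.grid(pair = seq_len(nPairs), cell = seq_along(cells))
  if (!is.null(spec$nTriplets) && spec$nTriplets < nrow(grid)) {
    grid <- grid[.sampleVec(seq_len(nrow(grid)), spec$nTriplets), , drop = FALSE]
  }
  inter <- rowSums(gamma[grid$pair, , drop = FALSE] *
    t(blockMeans)[grid$cell, , drop = FALSE])
  inter <- zs(inter)
  signal <- spec$sdDrug * drugComp[grid$pair] + spec$sdCell * inter

  nShift <- ceiling(0.2 * length(cells))
  shifted <- cells[(length(cells) - nShift + 1L):length(cells)]
  if (spec$domainShift > 0) {
    # pair-specific offset, active only in the shifted cell domain; linked to
    # fingerprint substructure so that adaptation can generalise across pairs
    beta2 <- numeric(spec$fpBits)
    beta2[.sampleVec(seq_len(spec$fpBits), nBeta)] <- rnorm(nBeta)
    pairShift <- zs(drop(andMat %*% beta2))
    isShift <- cells[grid$cell] %in% shifted
    signal <- signal + spec$domainShift * ifelse(isShift, pairShift[grid$pair], 0)
  }

  score <- signal + rnorm(nrow(grid), sd = spec$noiseSd)
  nTrip <- nrow(grid)
  unreliable <- rep(FALSE, nTrip)
  nBad <- floor(spec$badFraction * nTrip)
  badIdx <- if (nBad > 0) .sampleVec(seq_len(nTrip), nBad) else integer(0)

  repList <- vector("list", nTrip)
  for (i in seq_len(nTrip)) {
    s <- score[i]
    if (i %in% badIdx) {
      unreliable[i] <- TRUE
      a <- max(abs(s), 5)
      if (i %% 2L == 0L) {
        reps <- c(a, -a, a / 2) # sign conflict
      } else {
        m <- ifelse(s >= 0, 1, -1) * a
        reps <- m * c(0.25, 1, 1.75) # CV = 0.75 > 0.5, consistent signs
      }
      reps <- reps[seq_len(min(length(reps), max(2L, spec$replicates)))]
    } else {
      reps <- s + rnorm(spec$replicates, sd = spec$repNoiseSd)
    }
    repList[[i]] <- reps
  }
  nReps <- lengths(repList)
  replicates <- data.frame(
    drug1 = rep(pairs[grid$pair, 1], nReps),
    drug2 = rep(pairs[grid$pair, 2], nReps),
    cell = rep(cells[grid$cell], nReps),
    score = unlist(repList),
    replicate_id = unlist(lapply(nReps, seq_len)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    drug1 = pairs[grid$pair, 1], drug2 = pairs[grid$pair, 2],
    cell = cells[grid$cell], signal = signal, score = score,
    unreliable = unreliable, stringsAsFactors = FALSE
  )
  list(replicates = replicates, truth = truth, shiftedCells = shifted)
}

#' Write a complete fixture set to disk
#'
#' Generates the drug library, expression matrix and replicate table of a
#' [fixtureSpec()] and writes them in the formats the pipeline reads:
#' `drugs.csv` (`drug_name,smiles`), `expression.csv` (gene symbol +
#' one column per cell), `triplets.csv`
#' (`drug1,drug2,cell,score,replicate_id`) and `panel.txt` (one gene per
#' line).  Regeneration with the same spec is byte-identical.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the in-memory
#'   `drugs`, `expression` and `synergy` objects.
#' @export
makeFixtureSet <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- makeDrugLibrary(spec$nDrugs, seed = spec$seed)
  expression <- makeExpression(spec$nCells, spec$nGenes,
    nBlocks = spec$nBlocks,
    rho = spec$rho, seed = spec$seed + 2L
  )
  synergy <- makeSynergy(drugs, expression, spec)
  paths <- list(
    drugs = file.path(dir, "drugs.csv"),
    expression = file.path(dir, "expression.csv"),
    triplets = file.path(dir, "triplets.csv"),
    panel = file.path(dir, "panel.txt")
  )
  write.csv(drugs, paths$drugs, row.names = FALSE, quote = FALSE)
  write.csv(
    data.frame(gene = rownames(expression), expression, check.names = FALSE),
    paths$expression,
    row.names = FALSE, quote = FALSE
  )
  write.csv(synergy$replicates, paths$triplets, row.names = FALSE, quote = FALSE)
  writeLines(rownames(expression), paths$panel)
  invisible(list(
    paths = paths, drugs = drugs, expression = expression,
    synergy = synergy
  ))
}
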