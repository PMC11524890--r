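# SMILES -> molecular graph (78-dim atom features) and circular fingerprints.
#
# Parsing goes through OpenBabel (ChemmineR/ChemmineOB).  The 78-dimensional
# atom feature layout follows the convention widely used by graph models of
# small molecules:
#   [ 1..44] atom symbol one-hot (44-symbol vocabulary, last slot = unknown)
#   [45..55] heavy-atom degree one-hot (0..10)
#   [56..66] total hydrogen count one-hot (0..10)
#   [67..77] implicit valence (implicit hydrogen count) one-hot (0..10)
#   [    78] aromatic flag
# Hydrogens are implicit: the graph contains heavy atoms only.

.atomSymbols <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "Unknown"
)

.defaultValence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4
)

# Parse one SMILES into symbols, bonds (with kekulised orders), formal
# charges and aromatic perception.  Explicit hydrogens written in the SMILES
# are folded into their neighbour's hydrogen count.
.parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
    !nzchar(trimws(smiles))) {
    .dsStop("invalid SMILES input (empty or not a single string)")
  }
  raw <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) ""
  )
  txt <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  if (length(txt) < 4L) .dsStop("cannot parse SMILES '%s'", smiles)
  # V2000 counts line: atom and bond counts in fixed 3-character fields
  nAtomsAll <- suppressWarnings(as.integer(substr(txt[4], 1, 3)))
  nBondsAll <- suppressWarnings(as.integer(substr(txt[4], 4, 6)))
  if (is.na(nAtomsAll) || nAtomsAll < 1L) .dsStop("SMILES '%s' has no atoms", smiles)

  atomLines <- txt[5:(4 + nAtomsAll)]
  atomFields <- lapply(atomLines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  syms <- vapply(atomFields, `[`, "", 4L)
  codeToCharge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  charge <- vapply(atomFields, function(f) codeToCharge[[f[6]]] %||% 0, 0)
  chgLines <- grep("^M  CHG", txt, value = TRUE)
  if (length(chgLines)) { # "M  CHG" property lines override the atom codes
    charge[] <- 0
    for (l in chgLines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      for (k in seq_len(f[1])) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }

  bonds <- matrix(integer(0), 0, 3)
  if (!is.na(nBondsAll) && nBondsAll > 0L) {
    bondLines <- txt[(5 + nAtomsAll):(4 + nAtomsAll + nBondsAll)]
    bonds <- cbind(
      as.integer(substr(bondLines, 1, 3)),
      as.integer(substr(bondLines, 4, 6)),
      as.integer(substr(bondLines, 7, 9))
    )
  }

  # Aromatic perception: atoms and bonds that lie on an aromatic ring
  # (ChemmineR's ring perception over the same molecule).
  aromAtom <- rep(FALSE, nAtomsAll)
  aromBondKey <- character(0)
  if (nrow(bonds) > 2L) {
    rng <- tryCatch(
      {
        sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(txt)))[[1]]
        suppressMessages(ChemmineR::rings(sdf, type = "all", arom = TRUE))
      },
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    aromRings <- rng$RINGS[which(vapply(rng$AROMATIC, isTRUE, TRUE))]
    for (r in aromRings) {
      idx <- as.integer(gsub("^.*_", "", r))
      aromAtom[idx] <- TRUE
      nxt <- c(idx[-1], idx[1])
      aromBondKey <- c(aromBondKey, paste(pmin(idx, nxt), pmax(idx, nxt)))
    }
  }

  # Fold explicit hydrogens into neighbour H counts, then drop them.
  explicitH <- rep(0L, nAtomsAll)
  isH <- syms == "H"
  keepBond <- rep(TRUE, nrow(bonds))
  if (any(isH) && nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      if (isH[i] || isH[j]) {
        keepBond[r] <- FALSE
        if (isH[j] && !isH[i]) explicitH[i] <- explicitH[i] + 1L
        if (isH[i] && !isH[j]) explicitH[j] <- explicitH[j] + 1L
      }
    }
  }
  heavy <- which(!isH)
  if (!length(heavy)) .dsStop("SMILES '%s' has no heavy atoms", smiles)
  remap <- integer(nAtomsAll); remap[heavy] <- seq_along(heavy)
  bonds <- bonds[keepBond, , drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]

  bondArom <- if (nrow(bonds)) {
    paste(pmin(heavy[bonds[, 1]], heavy[bonds[, 2]]),
      pmax(heavy[bonds[, 1]], heavy[bonds[, 2]])) %in% aromBondKey
  } else {
    logical(0)
  }

  list(
    symbols = syms[heavy], bonds = bonds, bondAromatic = bondArom,
    charge = charge[heavy], explicitH = explicitH[heavy],
    aromatic = aromAtom[heavy]
  )
}

# Degree, hydrogen counts and implicit valence from the heavy-atom bond table.
.atomBookkeeping <- function(p) {
  n <- length(p$symbols)
  degree <- rep(0L, n)
  bsum <- rep(0, n)
  if (nrow(p$bonds)) {
    for (r in seq_len(nrow(p$bonds))) {
      i <- p$bonds[r, 1]; j <- p$bonds[r, 2]; o <- p$bonds[r, 3]
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
    }
  }
  base <- .defaultValence[p$symbols]
  base[is.na(base)] <- 0
  adj <- ifelse(p$symbols %in% c("N", "P", "O", "S"), p$charge,
    ifelse(p$symbols == "C", -abs(p$charge), 0)
  )
  implicitH <- pmax(0, base + adj - bsum - p$explicitH)
  list(
    degree = degree, implicitH = implicitH,
    totalH = implicitH + p$explicitH
  )
}

.oneHot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(value, levels)
  if (is.na(k)) k <- length(levels) # clamp to final slot
  v[k] <- 1
  v
}

.atomFeatureRow <- function(symbol, degree, totalH, implicitH, aromatic) {
  c(
    .oneHot(if (symbol %in% .atomSymbols) symbol else "Unknown", .atomSymbols),
    .oneHot(min(degree, 10L), 0:10),
    .oneHot(min(totalH, 10L), 0:10),
    .oneHot(min(implicitH, 10L), 0:10),
    as.numeric(aromatic)
  )
}

#' Convert a SMILES string into a molecular graph
#'
#' Parses the SMILES with OpenBabel and returns a [MolecularGraph-class]:
#' one node per heavy atom carrying the 78-dimensional feature vector
#' (symbol/degree/hydrogen/valence one-hots plus aromatic flag, see the class
#' documentation for the exact layout), one undirected edge per bond.
#'
#' @param smiles a single SMILES string.
#' @return a [MolecularGraph-class] object.
#' @examples
#' g <- smilesToGraph("CCO")
#' nAtoms(g) # 3
#' edgeMatrix(g) # bonds 1-2 and 2-3
#' @export
smilesToGraph <- function(smiles) {
  p <- .parseSmiles(smiles)
  bk <- .atomBookkeeping(p)
  n <- length(p$symbols)
  feats <- matrix(0, n, 78)
  for (i in seq_len(n)) {
    feats[i, ] <- .atomFeatureRow(
      p$symbols[i], bk$degree[i], bk$totalH[i], bk$implicitH[i], p$aromatic[i]
    )
  }
  e <- p$bonds[, 1:2, drop = FALSE]
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
  }
  storage.mode(e) <- "integer"
  new("MolecularGraph", nodeFeatures = feats, edges = e, smiles = smiles)
}

#' Canonicalise a SMILES string
#'
#' Round-trips the SMILES through OpenBabel's canonical writer, so that
#' different atom orderings of the same molecule map to one cache key.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES.
#' @export
canonicalSmiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out)) .dsStop("cannot parse SMILES '%s'", smiles)
  out
}

#' Circular (Morgan-type) fingerprint of a molecule
#'
#' Hashes atom-centred substructure environments of increasing radius
#' (default 6) into a fixed-length bit vector.  Atom environments are built
#' iteratively from an initial atom invariant (symbol, degree, hydrogen
#' count, charge, ring membership); at each radius the environment of every
#' atom is re-hashed from its own identifier and the sorted (bond order,
#' neighbour identifier) pairs, aromatic bonds carrying their own order code
#' so that the result does not depend on the kekulisation.  Environments that
#' cover an identical bond set are collapsed to a single bit (the smallest
#' identifier), which makes the fingerprint invariant to atom reordering of
#' the input SMILES.
#'
#' @param smiles a single SMILES string.
#' @param nBits fingerprint length, at least 64 (default 1024).
#' @param radius maximum environment radius (default 6).
#' @return an integer vector of 0/1 of length `nBits`, with attributes
#'   `radius` and `smiles`.
#' @examples
#' fp <- smilesToFingerprint("C", nBits = 1024)
#' sum(fp) # single-environment molecule: exactly one bit
#' @export
smilesToFingerprint <- function(smiles, nBits = 1024L, radius = 6L) {
  if (!.isCount(nBits) || nBits < 64) .dsStop("nBits must be a count >= 64")
  if (!.isCount(radius) || radius < 1) .dsStop("radius must be a positive count")
  p <- .parseSmiles(smiles)
  bk <- .atomBookkeeping(p)
  n <- length(p$symbols)
  nb <- nrow(p$bonds)
  bondCode <- if (nb) ifelse(p$bondAromatic, 4L, p$bonds[, 3]) else integer(0)

  # adjacency: neighbour atom and incident bond index per atom
  nbr <- vector("list", n); nbrBond <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); nbrBond[[i]] <- integer(0) }
  if (nb) {
    for (r in seq_len(nb)) {
      i <- p$bonds[r, 1]; j <- p$bonds[r, 2]
      nbr[[i]] <- c(nbr[[i]], j); nbrBond[[i]] <- c(nbrBond[[i]], r)
      nbr[[j]] <- c(nbr[[j]], i); nbrBond[[j]] <- c(nbrBond[[j]], r)
    }
  }

  symCode <- match(p$symbols, .atomSymbols)
  symCode[is.na(symCode)] <- length(.atomSymbols)
  inRing <- rep(FALSE, n)
  if (nb) {
    # ring bonds = non-bridge edges
    g <- igraph::graph_from_edgelist(p$bonds[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- as.integer(igraph::bridges(g))
    for (r in setdiff(seq_len(nb), br)) inRing[p$bonds[r, 1:2]] <- TRUE
  }

  ids <- vapply(seq_len(n), function(i) {
    .dsHash(c(symCode[i], bk$degree[i], bk$totalH[i], p$charge[i] + 10, as.integer(inRing[i])))
  }, 0)

  bits <- integer(nBits)
  bits[ids %% nBits + 1] <- 1L

  # BFS distances once per atom (small molecules: plain loops are fine)
  if (nb) {
    dist <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
      d <- rep(Inf, n); d[s] <- 0; frontier <- s
      while (length(frontier)) {
        nxt <- integer(0)
        for (u in frontier) {
          for (v in nbr[[u]]) {
            if (d[v] > d[u] + 1) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
          }
        }
        frontier <- nxt
      }
      dist[s, ] <- d
    }
    bondMaxDist <- function(s) pmax(dist[s, p$bonds[, 1]], dist[s, p$bonds[, 2]])

    envTable <- new.env(parent = emptyenv()) # bond-set key -> min env id
    cur <- ids
    for (r in seq_len(radius)) {
      nxtIds <- cur
      for (i in seq_len(n)) {
        js <- nbr[[i]]
        if (!length(js)) next
        codes <- bondCode[nbrBond[[i]]]
        ord <- order(codes, cur[js])
        nxtIds[i] <- .dsHash(c(r, cur[i], rbind(codes[ord], cur[js][ord])))
      }
      for (i in seq_len(n)) {
        if (!length(nbr[[i]])) next
        env <- which(bondMaxDist(i) <= r)
        if (!length(env)) next
        key <- paste(env, collapse = ",")
        old <- envTable[[key]]
        if (is.null(old) || nxtIds[i] < old) envTable[[key]] <- nxtIds[i]
      }
      cur <- nxtIds
    }
    envIds <- unlist(as.list(envTable), use.names = FALSE)
    if (length(envIds)) bits[envIds %% nBits + 1] <- 1L
  }

  structure(bits, radius = as.integer(radius), smiles = smiles)
}

#' Read a drug table
#'
#' Reads a CSV with header columns `drug_name,smiles` (UTF-8).
#'
#' @param path path to the CSV file.
#' @return a data.frame with columns `drug_name` and `smiles`.
#' @export
readDrugTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("drug_name", "smiles") %in% names(tab))) {
    .dsStop("drug table '%s' must have columns drug_name,smiles", path)
  }
  if (anyDuplicated(tab$drug_name)) .dsStop("duplicate drug names in '%s'", path)
  tab[, c("drug_name", "smiles")]
}

#' Featurise a set of drugs
#'
#' Computes the molecular graph and circular fingerprint of every drug in a
#' drug table, with optional in-memory and on-disk caching keyed by canonical
#' SMILES.
#'
#' @param drugTable data.frame with columns `drug_name` and `smiles`.
#' @param fpBits fingerprint length (default 1024).
#' @param radius fingerprint radius (default 6).
#' @param cache an environment created by a previous call (reused across
#'   calls), or `NULL`.
#' @param cacheDir optional directory for an on-disk feature store.
#' @return a list with elements `graphs` (named list of
#'   [MolecularGraph-class]), `fingerprints` (drugs-by-bits 0/1 matrix),
#'   `fpBits`, `radius` and `cache`.
#' @export
featurizeDrugs <- function(drugTable, fpBits = 1024L, radius = 6L,
                           cache = NULL, cacheDir = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  graphs <- vector("list", nrow(drugTable))
  fps <- matrix(0L, nrow(drugTable), fpBits,
    dimnames = list(drugTable$drug_name, NULL)
  )
  for (k in seq_len(nrow(drugTable))) {
    smi <- drugTable$smiles[k]
    key <- paste0(canonicalSmiles(smi), "|", fpBits, "|", radius)
    hit <- cache[[key]]
    if (is.null(hit) && !is.null(cacheDir)) {
      f <- file.path(cacheDir, paste0(.dsHash(utf8ToInt(key)), ".rds"))
      if (file.exists(f)) hit <- readRDS(f)
    }
    if (is.null(hit)) {
      hit <- list(
        graph = smilesToGraph(smi),
        fp = smilesToFingerprint(smi, nBits = fpBits, radius = radius)
      )
      cache[[key]] <- hit
      if (!is.null(cacheDir)) {
        dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(hit, file.path(cacheDir, paste0(.dsHash(utf8ToInt(key)), ".rds")))
      }
    }
    graphs[[k]] <- hit$graph
    fps[k, ] <- hit$fp
  }
  names(graphs) <- drugTable$drug_name
  list(
    graphs = graphs, fingerprints = fps, fpBits = as.integer(fpBits),
    radius = as.integer(radius), cache = cache
  )
}
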