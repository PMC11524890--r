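# Shared small fixtures and oracles, built once per test run.

tinyDrugs <- makeDrugLibrary(4, seed = 3)
tinyExpr <- makeExpression(6, 16, seed = 4)
tinyFeats <- featurizeDrugs(tinyDrugs, fpBits = 64)
tinyScaler <- fitExpressionScaler(tinyExpr)
tinyProf <- applyExpressionScaler(tinyScaler, tinyExpr)

tinyConfig <- function(task = "regression", pool = "max", seed = 11L, dropout = 0) {
  synergyConfig(
    task = task, pool = pool, gatHeads = 2L, gatHidden = 4L,
    cellMlpDims = c(7L, 6L), dcDim = 5L, embedDim = 6L,
    prednetDims = c(8L, 5L, 4L), dropout = dropout, seed = seed
  )
}

tinyRecords <- data.frame(
  drug1 = tinyDrugs$drug_name[c(1, 2, 3)],
  drug2 = tinyDrugs$drug_name[c(2, 3, 4)],
  cell = colnames(tinyExpr)[c(1, 2, 3)],
  score = c(5, -3, 10),
  label = c("synergistic", "antagonistic", "synergistic"),
  stringsAsFactors = FALSE
)

# a molecular graph with given node count and edge list (feature content
# irrelevant for topology-only tests)
bareGraph <- function(n, edges) {
  e <- if (is.matrix(edges)) {
    matrix(as.integer(edges), ncol = 2)
  } else if (length(edges)) {
    matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  } else {
    matrix(integer(0), 0, 2)
  }
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  storage.mode(e) <- "integer"
  new("MolecularGraph", nodeFeatures = matrix(0, n, 78), edges = e)
}

# Brute-force betweenness oracle: enumerate every simple path between every
# unordered pair, keep the shortest ones, and count pass-throughs.
bruteBetweenness <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]
      j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  cb <- numeric(n)
  if (n < 3) {
    return(cb)
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      walk <- function(path) {
        u <- path[length(path)]
        if (u == t) {
          paths[[length(paths) + 1]] <<- path
          return()
        }
        for (v in adj[[u]]) if (!v %in% path) walk(c(path, v))
      }
      walk(s)
      if (!length(paths)) next
      lens <- lengths(paths)
      sp <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        cb[v] <- cb[v] + sum(vapply(sp, function(p) v %in% p, TRUE)) / length(sp)
      }
    }
  }
  cb
}

# seeded random connected graph on n nodes (spanning tree + extra edges)
randomConnectedGraph <- function(n, extra = 2L, seed = 1L) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  all <- t(combn(n, 2))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  avail <- all[!paste(all[, 1], all[, 2]) %in% key, , drop = FALSE]
  if (extra > 0 && nrow(avail)) {
    pick <- sample.int(nrow(avail), min(extra, nrow(avail)))
    edges <- rbind(edges, avail[pick, , drop = FALSE])
  }
  bareGraph(n, edges)
}

# random drug pairs from a library, as a two-column name matrix
randomDrugPairs <- function(drugTable, nPairs, seed = 1L) {
  set.seed(seed)
  t(replicate(nPairs, sample(drugTable$drug_name, 2L)))
}
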