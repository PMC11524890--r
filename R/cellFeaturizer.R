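# Cell-line expression features: load, log-transform, panel-subset, z-score.
#
# "Normalisation" is per-gene z-scoring of log2(TPM + 1), with centre and
# scale computed on the training cell lines only and frozen in an
# ExpressionScaler so that prediction-time profiles are transformed
# identically.  Zero-variance genes are mapped to 0 rather than NaN.

#' Read a gene-by-cell expression matrix
#'
#' Reads a CSV/TSV whose first column holds gene symbols and whose remaining
#' columns are cell-line identifiers, as exported from TPM-level expression
#' resources.  The separator is inferred from the file extension (`.tsv`/
#' `.txt` = tab, otherwise comma).
#'
#' @param path path to the matrix file.
#' @return a numeric matrix, genes in rows (rownames = symbols), cells in
#'   columns.
#' @export
readExpressionMatrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) .dsStop("expression matrix '%s' needs gene + >=1 cell column", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) .dsStop("TPM values must be finite and >= 0")
  m
}

#' Read a gene panel
#'
#' One gene symbol per line; blank lines are dropped.
#'
#' @param path path to the panel file.
#' @return a character vector of unique symbols, in file order.
#' @export
readGenePanel <- function(path) {
  panel <- trimws(readLines(path, warn = FALSE))
  panel <- panel[nzchar(panel)]
  unique(panel)
}

#' Fit the expression scaler on training cells
#'
#' Subsets the matrix to the gene panel, applies `log2(TPM + 1)` and computes
#' the per-gene mean and (population) standard deviation over the training
#' cells.  Panel genes absent from the matrix are dropped with a warning;
#' an empty intersection is an error.
#'
#' @param tpm genes-by-cells TPM matrix (rownames = gene symbols).
#' @param panel character vector of gene symbols; `NULL` uses all rows.
#' @param cells cell-line identifiers to fit on; `NULL` uses all columns.
#' @return an [ExpressionScaler-class].
#' @export
fitExpressionScaler <- function(tpm, panel = NULL, cells = NULL) {
  if (is.null(panel)) panel <- rownames(tpm)
  missing <- setdiff(panel, rownames(tpm))
  if (length(missing)) {
    .dsWarn(
      "%d of %d panel genes missing from the expression matrix (e.g. %s); dropped",
      length(missing), length(panel), paste(head(missing, 3), collapse = ", ")
    )
  }
  panel <- panel[panel %in% rownames(tpm)]
  if (!length(panel)) .dsStop("no panel gene is present in the expression matrix")
  if (is.null(cells)) cells <- colnames(tpm)
  if (!all(cells %in% colnames(tpm))) .dsStop("unknown training cell identifiers")
  x <- log2(tpm[panel, cells, drop = FALSE] + 1)
  ctr <- rowMeans(x)
  scl <- sqrt(rowMeans((x - ctr)^2)) # population sd
  new("ExpressionScaler",
    panel = panel, center = unname(ctr), scale = unname(scl),
    trainCells = as.character(cells)
  )
}

#' Apply a frozen expression scaler
#'
#' Transforms TPM profiles with the panel, centre and scale stored in the
#' scaler: `(log2(TPM + 1) - center) / scale`, with zero-variance genes
#' mapped to 0.
#'
#' @param scaler an [ExpressionScaler-class].
#' @param tpm genes-by-cells TPM matrix containing at least the panel genes.
#' @return a cells-by-genes matrix of normalised values (rows = cells, in
#'   column order of `tpm`), ready to feed the cell encoder.
#' @export
applyExpressionScaler <- function(scaler, tpm) {
  stopifnot(is(scaler, "ExpressionScaler"))
  miss <- setdiff(scaler@panel, rownames(tpm))
  if (length(miss)) .dsStop("expression matrix lacks %d scaler panel genes", length(miss))
  x <- log2(tpm[scaler@panel, , drop = FALSE] + 1)
  x <- x - scaler@center
  ok <- scaler@scale > 0
  x[ok, ] <- x[ok, , drop = FALSE] / scaler@scale[ok]
  x[!ok, ] <- 0
  t(x)
}
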