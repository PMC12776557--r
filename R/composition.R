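#' Per-sample cell-type composition
#'
#' The fraction of each sample's cells carrying each cell-type label.
#'
#' @param x a SingleCellExperiment or per-cell data.frame with sample and
#'   cell-type columns.
#' @param sampleCol,cellTypeCol column names (defaults \code{"sample_id"},
#'   \code{"cell_type"}).
#' @return A sample x cell-type matrix of proportions; every row sums
#'   to 1.
#' @export
compositionFractions <- function(x, sampleCol = "sample_id",
                                 cellTypeCol = "cell_type") {
  cells <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x))
           else as.data.frame(x)
  if (!all(c(sampleCol, cellTypeCol) %in% names(cells)))
    stop("cell table needs columns '", sampleCol, "' and '",
         cellTypeCol, "'")
  tab <- table(cells[[sampleCol]], cells[[cellTypeCol]])
  if (any(rowSums(tab) == 0)) stop("empty sample in composition table")
  frac <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  frac
}

#' Genotype composition log2 fold changes
#'
#' For each cell type, the mean over test-genotype samples of
#' \code{log2((f_sample + delta) / (f_refmean + delta))}, where
#' \code{f_refmean} is the reference fraction averaged across reference
#' samples first (the stable choice with unequal replicate counts) and
#' \code{delta} guards empty cell types. Cell types whose absolute mean
#' log2 fold change exceeds \code{flagThreshold} (strictly) are flagged —
#' the reporting rule for composition-shift panels.
#'
#' @param fractions sample x cell-type proportion matrix from
#'   [compositionFractions()].
#' @param genotypeOf named vector (or factor) mapping each sample (row
#'   name) to its genotype.
#' @param reference reference genotype label.
#' @param flagThreshold absolute log2 fold-change reporting cut
#'   (default 0.5).
#' @param delta pseudo-fraction for empty types (default 1e-6).
#' @param perPair when TRUE each test sample is compared to the
#'   positionally paired reference sample instead of the reference mean.
#' @return A [S4Vectors::DataFrame] with columns \code{cell_type},
#'   \code{genotype}, \code{mean_log2fc}, \code{flagged}.
#' @export
compositionLog2FC <- function(fractions, genotypeOf, reference = "WT",
                              flagThreshold = 0.5, delta = 1e-6,
                              perPair = FALSE) {
  genotypeOf <- setNames(as.character(genotypeOf), names(genotypeOf))
  if (is.null(names(genotypeOf)))
    names(genotypeOf) <- rownames(fractions)
  gts <- genotypeOf[rownames(fractions)]
  if (!reference %in% gts)
    stop("reference genotype '", reference, "' has no samples")
  refRows <- fractions[gts == reference, , drop = FALSE]
  refMean <- colMeans(refRows)
  tests <- setdiff(unique(gts), reference)
  out <- lapply(tests, function(g) {
    testRows <- fractions[gts == g, , drop = FALSE]
    if (perPair) {
      nPair <- min(nrow(testRows), nrow(refRows))
      lfc <- log2((testRows[seq_len(nPair), , drop = FALSE] + delta) /
                    (refRows[seq_len(nPair), , drop = FALSE] + delta))
    } else {
      lfc <- log2(sweep(testRows + delta, 2L, refMean + delta, "/"))
    }
    m <- colMeans(lfc)
    DataFrame(cell_type = colnames(fractions), genotype = g,
              mean_log2fc = unname(m),
              flagged = unname(abs(m) > flagThreshold))
  })
  do.call(rbind, out)
}

#' Genes expressed per cell
#'
#' Number of genes with linear normalised expression strictly above the
#' threshold, per cell — the transcriptomic-diversity metric.
#'
#' @param x a SingleCellExperiment with \code{normcounts}, or a genes x
#'   cells matrix of linear normalised expression.
#' @param exprThreshold expression cut (default 0.1, strict).
#' @param assayName assay holding linear normalised expression.
#' @return Named integer vector, one entry per cell.
#' @export
genesPerCell <- function(x, exprThreshold = 0.1,
                         assayName = "normcounts") {
  norm <- .normOf(x, assayName)
  n <- Matrix::colSums(norm > exprThreshold)
  setNames(as.integer(n), colnames(norm))
}

#' Fraction of expressed genes that are TRAs, per cell
#'
#' Among each cell's expressed genes (normalised expression strictly above
#' the threshold), the fraction classified as tissue-restricted antigens.
#' Cells expressing no gene get 0 with an attribute flag.
#'
#' @param x as in [genesPerCell()].
#' @param traCalls a [classifyTRA()] table, or a character vector of TRA
#'   gene ids, or a named logical vector. Genes of \code{x} not covered
#'   are treated as non-TRA with a warning.
#' @param exprThreshold expression cut (default 0.1, strict).
#' @param assayName assay holding linear normalised expression.
#' @return Numeric vector per cell; attribute \code{"no_expressed"} marks
#'   cells with no expressed gene.
#' @export
traFractionPerCell <- function(x, traCalls, exprThreshold = 0.1,
                               assayName = "normcounts") {
  norm <- .normOf(x, assayName)
  genes <- rownames(norm)
  if (is.character(traCalls)) {
    isTra <- setNames(genes %in% traCalls, genes)
  } else if (is.logical(traCalls)) {
    isTra <- traCalls
  } else {
    isTra <- setNames(as.logical(traCalls$is_tra), traCalls$gene)
  }
  uncovered <- setdiff(genes, names(isTra)[!is.na(isTra)])
  if (length(uncovered) && !is.null(names(isTra)))
    warning(length(uncovered),
            " gene(s) not covered by TRA calls; treated as non-TRA")
  traMask <- rep(FALSE, length(genes))
  hit <- match(genes, names(isTra))
  traMask[!is.na(hit)] <- isTra[hit[!is.na(hit)]] %in% TRUE
  expressed <- norm > exprThreshold
  nExpr <- Matrix::colSums(expressed)
  nTra <- Matrix::colSums(expressed[traMask, , drop = FALSE])
  frac <- ifelse(nExpr > 0, nTra / pmax(nExpr, 1), 0)
  frac <- setNames(as.numeric(frac), colnames(norm))
  attr(frac, "no_expressed") <- setNames(nExpr == 0, colnames(norm))
  frac
}

#' Mean log-transformed expression per gene and genotype
#'
#' For a chosen cell subset, the per-gene mean of \code{ln(1 + x)} of
#' linear normalised expression within each genotype — the table behind
#' WT-vs-KO mean-expression scatters, where the diagonal marks equivalent
#' expression.
#'
#' @param x a SingleCellExperiment with \code{normcounts} and a genotype
#'   colData column, or a genes x cells matrix.
#' @param genotype per-cell genotype labels (taken from colData for a
#'   SingleCellExperiment).
#' @param subset optional logical/index vector restricting the cells
#'   (e.g. one cell type).
#' @param genotypeCol colData column name (default \code{"genotype"}).
#' @param assayName assay holding linear normalised expression.
#' @return A [S4Vectors::DataFrame] with a \code{gene} column and one
#'   mean-log-expression column per genotype.
#' @export
meanLogExpression <- function(x, genotype = NULL, subset = NULL,
                              genotypeCol = "genotype",
                              assayName = "normcounts") {
  norm <- .normOf(x, assayName)
  if (is(x, "SummarizedExperiment") && is.null(genotype))
    genotype <- colData(x)[[genotypeCol]]
  stopifnot(length(genotype) == ncol(norm))
  if (!is.null(subset)) {
    norm <- norm[, subset, drop = FALSE]
    genotype <- genotype[subset]
  }
  if (ncol(norm) == 0L) stop("empty cell subset")
  out <- DataFrame(gene = if (!is.null(rownames(norm))) rownames(norm)
                          else seq_len(nrow(norm)))
  for (g in unique(genotype)) {
    cols <- genotype == g
    if (!any(cols)) stop("empty cell subset for genotype '", g, "'")
    out[[g]] <- rowMeans(log1p(as.matrix(norm[, cols, drop = FALSE])))
  }
  out
}
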