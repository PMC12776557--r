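#' @importFrom utils read.delim write.table
NULL

#' Write a count experiment as Matrix Market + TSV triplet
#'
#' Standard on-disk exchange layout: \code{matrix.mtx} (genes x cells,
#' Matrix Market), \code{genes.tsv} (gene_id, biotype and any further
#' rowData columns), \code{barcodes.tsv}, and \code{cells.tsv} with the
#' full per-cell metadata. Ground-truth tables attached by the simulators
#' are written alongside as \code{ground_truth_*.tsv}.
#'
#' @param x a SingleCellExperiment with assay \code{counts}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeCountsDir <- function(x, dir) {
  stopifnot(is(x, "SummarizedExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- .countsOf(x)
  Matrix::writeMM(as(as(counts, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(as.data.frame(rowData(x)), file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  write.table(as.data.frame(colData(x)), file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- S4Vectors::metadata(x)$groundTruth
  if (!is.null(gt)) {
    if (!is.null(gt$tra_labels))
      write.table(data.frame(gene_id = names(gt$tra_labels),
                             is_tra = gt$tra_labels,
                             breadth = gt$breadth),
                  file.path(dir, "ground_truth_tra.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gt$regulated) && nrow(gt$regulated)) {
      reg <- gt$regulated
      reg$cell_types <- vapply(reg$cell_types, function(v)
        paste(v, collapse = ","), character(1L))
      write.table(reg, file.path(dir, "ground_truth_regulated.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(gt$compositionLog2FC))
      write.table(data.frame(genotype = rownames(gt$compositionLog2FC),
                             gt$compositionLog2FC, check.names = FALSE),
                  file.path(dir, "ground_truth_composition.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a Matrix Market + TSV count directory
#'
#' Counterpart of [writeCountsDir()]; also accepts minimal external
#' triplets (\code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv})
#' without a cell-metadata table.
#'
#' @param dir directory holding the triplet.
#' @return A SingleCellExperiment with assay \code{counts} (sparse), the
#'   gene table as rowData, any \code{cells.tsv} as colData and, when
#'   umap1/umap2 columns are present, a \code{"UMAP"} reducedDim.
#' @export
readCountsDir <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")),
               "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"),
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes$gene_id, barcodes)
  cellsFile <- file.path(dir, "cells.tsv")
  colDf <- if (file.exists(cellsFile)) {
    cells <- read.delim(cellsFile, stringsAsFactors = FALSE)
    S4Vectors::DataFrame(cells, row.names = barcodes)
  } else S4Vectors::DataFrame(cell_id = barcodes, row.names = barcodes)
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = colDf)
  if (all(c("umap1", "umap2") %in% colnames(colDf)))
    reducedDim(sce, "UMAP") <- cbind(umap1 = colDf$umap1,
                                     umap2 = colDf$umap2)
  sce
}
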