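# matrix extraction helpers: most user-facing functions accept either a
# SingleCellExperiment or a bare genes x cells matrix

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
}

.normOf <- function(x, assayName = "normcounts") {
  if (is(x, "SummarizedExperiment")) {
    if (!assayName %in% SummarizedExperiment::assayNames(x))
      stop("assay '", assayName, "' not found; run normalizeCells() first")
    assay(x, assayName)
  } else x
}

#' Keep protein-coding genes
#'
#' Subsets a count matrix to genes whose biotype annotation equals
#' \code{keep}. The cell set is unchanged.
#'
#' @param x a SingleCellExperiment whose rowData has a biotype column.
#' @param biotypeCol name of the rowData column (default "biotype").
#' @param keep biotype to retain (default "protein_coding").
#' @param ignoreCase compare biotypes case-insensitively (default FALSE:
#'   exact match).
#' @return The subsetted object. Retaining zero genes is allowed and
#'   produces a warning.
#' @export
filterProteinCoding <- function(x, biotypeCol = "biotype",
                                keep = "protein_coding",
                                ignoreCase = FALSE) {
  stopifnot(is(x, "SummarizedExperiment"))
  bt <- rowData(x)[[biotypeCol]]
  if (is.null(bt))
    stop("rowData column '", biotypeCol, "' not found")
  keepRows <- if (ignoreCase) tolower(bt) %in% tolower(keep) else bt %in% keep
  if (!any(keepRows))
    warning("no genes with biotype '", paste(keep, collapse = ","),
            "' retained")
  x[keepRows, ]
}

#' Quality-control filter cascade
#'
#' Applies the cell/gene filter cascade in its stated order: (1) a
#' preliminary filter removing cells with fewer than
#' \code{prelimGenesMin} detected genes, then genes detected in fewer than
#' \code{geneMinCells} cells; (2) doublet exclusion (score strictly over
#' \code{doubletScoreMax}); (3) removal of damaged or low-quality cells by
#' mitochondrial percentage (strictly over \code{mitoPctMax}), UMI total
#' (strictly over \code{umiMax} or strictly under \code{umiMin}) and
#' detected genes (strictly over \code{genesMax} or strictly under
#' \code{genesMin}). Stage-3 metrics are computed on the matrix left by the
#' preliminary gene filter, and each cell is attributed to the first rule
#' that removes it.
#'
#' @param x a SingleCellExperiment with assay \code{counts} and a doublet
#'   score column in \code{colData}.
#' @param thresholds a [QCThresholds-class] (default [qcThresholds()]).
#' @param mitoGenes explicit character vector of mitochondrial gene ids;
#'   if \code{NULL}, genes whose name starts with \code{mitoPrefix} are
#'   used. An empty set gives 0% mitochondrial reads everywhere.
#' @param mitoPrefix gene-name prefix defining the mitochondrial set
#'   (default \code{"mt-"}).
#' @param doubletCol colData column holding doublet scores. Missing column
#'   is an error: supply scores or zero-fill the column.
#' @return A list with elements \code{sce} (the filtered object) and
#'   \code{report} (a [QCReport-class]).
#' @examples
#' sce <- simulateTECExperiment(experimentDesign(cellsPerSample = 150,
#'                                               nGenes = 300, seed = 2))
#' res <- qcFilter(sce, qcThresholds(umiMin = 10, genesMin = 10))
#' res$report
#' @export
qcFilter <- function(x, thresholds = qcThresholds(), mitoGenes = NULL,
                     mitoPrefix = "mt-", doubletCol = "doublet_score") {
  stopifnot(is(x, "SummarizedExperiment"), is(thresholds, "QCThresholds"))
  validObject(thresholds)
  if (!doubletCol %in% colnames(colData(x)))
    stop("colData column '", doubletCol, "' is missing: supply doublet ",
         "scores or zero-fill the column before filtering")
  t <- thresholds
  counts <- .countsOf(x)
  cellsIn <- ncol(counts); genesIn <- nrow(counts)
  stages <- data.frame(stage = character(), what = character(),
                       removed = integer())
  addStage <- function(stage, what, removed)
    rbind(stages, data.frame(stage = stage, what = what,
                             removed = as.integer(removed)))

  # stage 1: preliminary cell filter, then gene filter
  genesDetected <- Matrix::colSums(counts > 0)
  keepCell <- genesDetected >= t@prelimGenesMin
  stages <- addStage("preliminary_min_genes", "cells", sum(!keepCell))
  x <- x[, keepCell]; counts <- counts[, keepCell, drop = FALSE]

  cellsDetected <- Matrix::rowSums(counts > 0)
  keepGene <- cellsDetected >= t@geneMinCells
  stages <- addStage("gene_min_cells", "genes", sum(!keepGene))
  x <- x[keepGene, ]; counts <- counts[keepGene, , drop = FALSE]

  # stage 2: doublets
  score <- colData(x)[[doubletCol]]
  isDoublet <- score > t@doubletScoreMax
  stages <- addStage("doublet_score", "cells", sum(isDoublet))
  x <- x[, !isDoublet]; counts <- counts[, !isDoublet, drop = FALSE]

  # stage 3: QC metrics on the post-gene-filter matrix
  if (is.null(mitoGenes))
    mitoGenes <- rownames(counts)[startsWith(rownames(counts), mitoPrefix)]
  mitoGenes <- intersect(mitoGenes, rownames(counts))
  umi <- Matrix::colSums(counts)
  mitoPct <- if (length(mitoGenes))
    100 * Matrix::colSums(counts[mitoGenes, , drop = FALSE]) /
      pmax(umi, 1) else rep(0, ncol(counts))
  nGenes <- Matrix::colSums(counts > 0)

  failMito <- mitoPct > t@mitoPctMax
  failUMI <- !failMito & (umi > t@umiMax | umi < t@umiMin)
  failGenes <- !failMito & !failUMI &
    (nGenes > t@genesMax | nGenes < t@genesMin)
  stages <- addStage("mito_pct", "cells", sum(failMito))
  stages <- addStage("umi_window", "cells", sum(failUMI))
  stages <- addStage("genes_window", "cells", sum(failGenes))
  keep <- !(failMito | failUMI | failGenes)
  x <- x[, keep]

  report <- new("QCReport", stages = stages,
                cellsIn = as.integer(cellsIn), cellsOut = ncol(x),
                genesIn = as.integer(genesIn), genesOut = nrow(x))
  validObject(report)
  list(sce = x, report = report)
}

#' Library-size normalisation
#'
#' Scales every cell to \code{targetSum} total counts (linear scale), the
#' normalisation contract used by every downstream statistic, optionally
#' followed by a natural-log(1 + x) transform. All-zero cells are left as
#' zeros with a warning.
#'
#' @param x a SingleCellExperiment with assay \code{counts}, or a bare
#'   genes x cells matrix.
#' @param targetSum per-cell total after scaling (default 10000).
#' @param log1p also store/return the log-transformed values.
#' @return For a SingleCellExperiment: the object with an added
#'   \code{normcounts} assay (and \code{logcounts} when \code{log1p};
#'   the \code{normcounts} assay always stays linear). For a
#'   matrix: the normalised (and possibly log-transformed) matrix.
#' @examples
#' m <- matrix(c(1, 1, 2), nrow = 3)
#' normalizeCells(m)           # 2500, 2500, 5000
#' @export
normalizeCells <- function(x, targetSum = 10000, log1p = FALSE) {
  counts <- .countsOf(x)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    warning(sum(totals == 0), " all-zero cell(s) left unnormalised")
  sf <- ifelse(totals > 0, targetSum / totals, 0)
  norm <- if (is(counts, "Matrix"))
    counts %*% Matrix::Diagonal(x = sf)
  else sweep(counts, 2L, sf, "*")
  dimnames(norm) <- dimnames(counts)
  if (is(x, "SummarizedExperiment")) {
    assay(x, "normcounts") <- norm
    if (log1p) assay(x, "logcounts") <- log1p(norm)
    x
  } else {
    if (log1p) log1p(norm) else norm
  }
}

#' Detection filter for atlas-scale TRA scoring
#'
#' Removes cells with fewer than \code{minGenesPerCell} detected genes,
#' then genes not reaching \code{minCount} raw counts in at least
#' \code{minCells} cells (both boundaries inclusive).
#'
#' @param x a SingleCellExperiment or genes x cells count matrix.
#' @param minGenesPerCell minimum detected genes per retained cell
#'   (default 500).
#' @param minCount,minCells a retained gene needs \code{>= minCount} raw
#'   counts in \code{>= minCells} cells (defaults 2 and 100).
#' @return The filtered object/matrix.
#' @export
atlasDetectionFilter <- function(x, minGenesPerCell = 500,
                                 minCount = 2, minCells = 100) {
  counts <- .countsOf(x)
  keepCell <- Matrix::colSums(counts > 0) >= minGenesPerCell
  x <- if (is(x, "SummarizedExperiment")) x[, keepCell]
       else x[, keepCell, drop = FALSE]
  counts <- counts[, keepCell, drop = FALSE]
  keepGene <- Matrix::rowSums(counts >= minCount) >= minCells
  if (is(x, "SummarizedExperiment")) x[keepGene, ]
  else x[keepGene, , drop = FALSE]
}

#' Winsorise values to the 1st/99th percentile for display
#'
#' Clips a vector of per-cell expression values to its lower/upper
#' percentiles so colour scales on feature plots are not dominated by
#' outliers. Percentiles use linear interpolation (\code{quantile}
#' type 7).
#'
#' @param v numeric vector (nonempty).
#' @param probs lower/upper percentile pair (default \code{c(0.01, 0.99)}).
#' @return The clipped vector.
#' @examples
#' clipForDisplay(0:100)   # clipped to [1, 99]
#' @export
clipForDisplay <- function(v, probs = c(0.01, 0.99)) {
  stopifnot(length(v) >= 1L, length(probs) == 2L, probs[1L] <= probs[2L])
  q <- quantile(v, probs = probs, names = FALSE, type = 7)
  pmin(pmax(v, q[1L]), q[2L])
}
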