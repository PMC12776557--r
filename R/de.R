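#' Cell types eligible for a differential-expression contrast
#'
#' A cell type participates in DE only when every sample of the contrast
#' contributes at least \code{minCells} of its cells (inclusive boundary).
#'
#' @param x a SingleCellExperiment or a per-cell data.frame.
#' @param minCells minimum cells per sample (default 30).
#' @param samples samples that must each reach the minimum; default all
#'   samples present.
#' @param cellTypeCol,sampleCol column names in colData / the data.frame.
#' @return Character vector of eligible cell types.
#' @export
eligibleCellTypes <- function(x, minCells = 30L, samples = NULL,
                              cellTypeCol = "cell_type",
                              sampleCol = "sample_id") {
  cells <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x))
           else as.data.frame(x)
  if (!all(c(cellTypeCol, sampleCol) %in% names(cells)))
    stop("cell table needs columns '", cellTypeCol, "' and '",
         sampleCol, "'")
  if (is.null(samples)) samples <- unique(cells[[sampleCol]])
  cells <- cells[cells[[sampleCol]] %in% samples, ]
  tab <- table(cells[[cellTypeCol]], cells[[sampleCol]])
  tab <- tab[, as.character(samples), drop = FALSE]
  rownames(tab)[apply(tab >= minCells, 1L, all)]
}

# bootstrap resampling weight matrix: each row one bootstrap's cell weights
.bootWeights <- function(n, nBoot) {
  w <- matrix(0, nrow = nBoot, ncol = n)
  for (b in seq_len(nBoot))
    w[b, ] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
  w
}

#' Per-gene statistics for a two-group contrast
#'
#' Computes, for every gene, the mean log2 fold change of linear
#' normalised expression between two cell groups, a bootstrap Bayes factor
#' quantifying the evidence that the fold change's sign is real, the
#' fraction of cells with nonzero expression in each group, and the peak
#' (99th percentile) normalised expression over the pooled cells of the
#' contrast.
#'
#' The Bayes factor is \code{ln(q / (1 - q))} where \code{q} is the
#' bootstrap probability (resampling cells with replacement within each
#' group) that the resampled log fold change has the same sign as the
#' point estimate, clipped to \code{[1/(nBoot+1), nBoot/(nBoot+1)]} so the
#' log odds stay finite. Externally computed statistics tables with the
#' same columns are accepted everywhere downstream as drop-in
#' replacements.
#'
#' @param x a SingleCellExperiment with a \code{normcounts} assay, or a
#'   genes x cells matrix of linear normalised expression.
#' @param cellsA,cellsB column indices, logical masks or cell ids of the
#'   two groups; group A is the group of interest (fold changes are A over
#'   B).
#' @param nBoot bootstrap replicates (default 500).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param epsilon pseudo-expression guarding the fold-change ratio
#'   (default 1e-4).
#' @param assayName assay holding linear normalised expression.
#' @return A [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{bayes_factor}, \code{lfc_mean}, \code{frac_nonzero_A},
#'   \code{frac_nonzero_B}, \code{peak_expr}.
#' @export
estimateGeneStats <- function(x, cellsA, cellsB, nBoot = 500L, seed = 1L,
                              epsilon = 1e-4, assayName = "normcounts") {
  norm <- .normOf(x, assayName)
  A <- as.matrix(norm[, cellsA, drop = FALSE])
  B <- as.matrix(norm[, cellsB, drop = FALSE])
  if (ncol(A) == 0L || ncol(B) == 0L)
    stop("both contrast groups must be nonempty")
  meanA <- rowMeans(A); meanB <- rowMeans(B)
  lfc <- log2((meanA + epsilon) / (meanB + epsilon))

  set.seed(seed)
  wA <- .bootWeights(ncol(A), nBoot)
  wB <- .bootWeights(ncol(B), nBoot)
  bootA <- A %*% t(wA)   # genes x nBoot resampled means
  bootB <- B %*% t(wB)
  bootLfc <- log2((bootA + epsilon) / (bootB + epsilon))
  match_ <- sweep(sign(bootLfc), 1L, sign(lfc), "==")
  q <- rowMeans(match_)
  q <- pmin(pmax(q, 1 / (nBoot + 1)), nBoot / (nBoot + 1))
  bf <- log(q / (1 - q))

  pooled <- cbind(A, B)
  peak <- apply(pooled, 1L, quantile, probs = 0.99, names = FALSE, type = 7)

  DataFrame(
    gene = if (!is.null(rownames(norm))) rownames(norm)
           else seq_len(nrow(norm)),
    bayes_factor = unname(bf), lfc_mean = unname(lfc),
    frac_nonzero_A = unname(rowMeans(A > 0)),
    frac_nonzero_B = unname(rowMeans(B > 0)),
    peak_expr = unname(peak))
}

#' Gene statistics per eligible cell type for a sample contrast
#'
#' Runs [estimateGeneStats()] within each cell type for a pair of samples
#' (group A cells of \code{contrast[1]}, group B cells of
#' \code{contrast[2]}), restricted to cell types eligible under the
#' \code{minCells} rule in both samples.
#'
#' @param x a SingleCellExperiment with \code{normcounts}, and
#'   \code{sample_id} / \code{cell_type} colData columns.
#' @param contrast length-2 character: samples A and B (fold changes A
#'   over B; for a KO-vs-WT contrast put the KO first).
#' @param cellTypes restrict to these cell types; default all eligible.
#' @param minCells eligibility threshold per sample (default 30).
#' @inheritParams estimateGeneStats
#' @return A [S4Vectors::DataFrame] of per-gene statistics with added
#'   \code{cell_type} and \code{contrast} columns.
#' @export
geneStatsByCellType <- function(x, contrast, cellTypes = NULL,
                                minCells = 30L, nBoot = 500L, seed = 1L,
                                epsilon = 1e-4,
                                assayName = "normcounts") {
  stopifnot(is(x, "SummarizedExperiment"), length(contrast) == 2L)
  cells <- colData(x)
  eligible <- eligibleCellTypes(x, minCells = minCells, samples = contrast)
  if (is.null(cellTypes)) cellTypes <- eligible
  else cellTypes <- intersect(cellTypes, eligible)
  out <- vector("list", length(cellTypes))
  for (k in seq_along(cellTypes)) {
    ct <- cellTypes[k]
    inType <- cells$cell_type == ct
    st <- estimateGeneStats(
      x,
      cellsA = which(inType & cells$sample_id == contrast[1L]),
      cellsB = which(inType & cells$sample_id == contrast[2L]),
      nBoot = nBoot, seed = seed + k, epsilon = epsilon,
      assayName = assayName)
    st$cell_type <- ct
    st$contrast <- paste(contrast, collapse = "_vs_")
    out[[k]] <- st
  }
  do.call(rbind, out)
}

#' Filter gene statistics into differential-expression calls
#'
#' Applies a [DEThresholds-class] to a statistics table: Bayes factor
#' strictly over \code{bfMin}, absolute log2 fold change strictly over
#' \code{lfcAbsMin}, nonzero-expression fraction at least \code{fracMin}
#' (per the threshold set's \code{fracRule}: the larger of the two groups'
#' fractions, or group A alone), and — when the threshold set defines it —
#' peak normalised expression strictly over \code{peakMin}.
#'
#' @param stats per-gene statistics ([estimateGeneStats()] output or an
#'   externally computed table with the same columns).
#' @param thresholds a [DEThresholds-class].
#' @return The passing rows with an added \code{direction} column
#'   ("up"/"down", the sign of \code{lfc_mean}).
#' @export
applyDEFilter <- function(stats, thresholds = deThresholds("genotype")) {
  stopifnot(is(thresholds, "DEThresholds"))
  validObject(thresholds)
  need <- c("gene", "bayes_factor", "lfc_mean", "frac_nonzero_A")
  if (!is.na(thresholds@peakMin)) need <- c(need, "peak_expr")
  if (thresholds@fracRule == "max") need <- c(need, "frac_nonzero_B")
  missing_ <- setdiff(need, colnames(stats))
  if (length(missing_))
    stop("statistics table lacks required column(s): ",
         paste(missing_, collapse = ", "))
  frac <- if (thresholds@fracRule == "max")
    pmax(stats$frac_nonzero_A, stats$frac_nonzero_B)
  else stats$frac_nonzero_A
  pass <- stats$bayes_factor > thresholds@bfMin &
    abs(stats$lfc_mean) > thresholds@lfcAbsMin &
    frac >= thresholds@fracMin
  if (!is.na(thresholds@peakMin))
    pass <- pass & stats$peak_expr > thresholds@peakMin
  out <- stats[pass, , drop = FALSE]
  out$direction <- ifelse(out$lfc_mean > 0, "up", "down")
  out
}

.callKey <- function(calls) {
  ct <- if ("cell_type" %in% colnames(calls)) calls$cell_type else ""
  paste(calls$gene, ct, sep = "\r")
}

#' Consensus differential expression across replicate contrasts
#'
#' Retains a (gene, cell type) call only when it is made in every
#' replicate KO-vs-WT contrast, with the same direction in all of them
#' (opposite effects across samples are removed), and is absent from every
#' batch-control contrast (WT-vs-WT and KO-vs-KO). Fold changes and Bayes
#' factors of retained calls are averaged over the replicate contrasts.
#'
#' @param replicateCalls list of two or more [applyDEFilter()] outputs,
#'   one per replicate contrast.
#' @param batchCalls list (possibly empty) of [applyDEFilter()] outputs
#'   for the batch-control contrasts.
#' @param koVsWT when TRUE (default) the contrasts are oriented KO over
#'   WT and a \code{regulation} column is added mapping direction to the
#'   transcription factor's action: lower in KO ("down") means
#'   TF-induced, higher in KO ("up") means TF-repressed.
#' @return A [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{cell_type}, \code{direction}, \code{lfc_mean},
#'   \code{bayes_factor} (and \code{regulation}).
#' @export
consensusAcrossReplicates <- function(replicateCalls, batchCalls = list(),
                                      koVsWT = TRUE) {
  if (length(replicateCalls) < 1L)
    stop("at least one replicate contrast is required")
  keys <- lapply(replicateCalls, .callKey)
  common <- Reduce(intersect, keys)
  batchKeys <- unique(unlist(lapply(batchCalls, .callKey)))
  common <- setdiff(common, batchKeys)
  if (!length(common)) {
    out <- DataFrame(gene = character(), cell_type = character(),
                     direction = character(), lfc_mean = numeric(),
                     bayes_factor = numeric())
    if (koVsWT) out$regulation <- character()
    return(out)
  }
  rows <- lapply(seq_along(replicateCalls), function(i) {
    calls <- replicateCalls[[i]]
    calls[match(common, keys[[i]]), , drop = FALSE]
  })
  dirs <- do.call(cbind, lapply(rows, function(r) r$direction))
  consistent <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  rows <- lapply(rows, function(r) r[consistent, , drop = FALSE])
  first <- rows[[1L]]
  lfc <- rowMeans(do.call(cbind, lapply(rows, function(r) r$lfc_mean)))
  bf <- rowMeans(do.call(cbind, lapply(rows,
                                       function(r) r$bayes_factor)))
  out <- DataFrame(
    gene = first$gene,
    cell_type = if ("cell_type" %in% colnames(first)) first$cell_type
                else rep("", nrow(first)),
    direction = first$direction, lfc_mean = lfc, bayes_factor = bf)
  if (koVsWT)
    out$regulation <- ifelse(out$direction == "down", "induced",
                             "repressed")
  out
}

#' Collapse multi-subset calls to one record per gene
#'
#' For volcano plotting: when a gene is differentially expressed in more
#' than one cell subset, the record with the highest absolute log2 fold
#' change is kept together with its own Bayes factor. Exact ties go to the
#' higher Bayes factor, then to the lexicographically first cell type.
#'
#' @param calls calls with \code{gene}, \code{lfc_mean},
#'   \code{bayes_factor} and optionally \code{cell_type} columns.
#' @return One row per gene.
#' @export
collapseForVolcano <- function(calls) {
  if (!nrow(calls)) return(calls)
  df <- as.data.frame(calls)
  if (!"cell_type" %in% names(df)) df$cell_type <- ""
  ord <- order(df$gene, -abs(df$lfc_mean), -df$bayes_factor, df$cell_type)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  DataFrame(df, row.names = NULL)
}

#' Tally call directions
#'
#' @param calls a call table with a \code{direction} column.
#' @param by optionally a column to tally within (e.g.
#'   \code{"regulation"}).
#' @return Named integer vector \code{c(up = , down = )}, or a table when
#'   \code{by} is given.
#' @export
countDirections <- function(calls, by = NULL) {
  if (!is.null(by)) return(table(calls[[by]]))
  c(up = sum(calls$direction == "up"),
    down = sum(calls$direction == "down"))
}
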