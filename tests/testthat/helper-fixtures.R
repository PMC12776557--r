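suppressMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

# minimal SingleCellExperiment from a genes x cells count matrix
makeSCE <- function(counts, biotype = "protein_coding",
                    cellMeta = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  cd <- S4Vectors::DataFrame(cell_id = colnames(counts),
                             row.names = colnames(counts))
  if (!is.null(cellMeta))
    for (nm in names(cellMeta)) cd[[nm]] <- cellMeta[[nm]]
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      gene_id = rownames(counts),
      biotype = rep_len(biotype, nrow(counts)),
      row.names = rownames(counts)),
    colData = cd)
}

randomCounts <- function(nGenes, nCells, lambda = 2, seed = 1) {
  set.seed(seed)
  matrix(rpois(nGenes * nCells, lambda), nrow = nGenes,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("c%03d", seq_len(nCells))))
}

# independent brute-force QC cascade: per-rule loops, sequential stages
bruteQC <- function(counts, score, t, mitoGenes = character()) {
  keptCells <- colnames(counts)
  # stage 1
  keptCells <- keptCells[vapply(keptCells, function(cl)
    sum(counts[, cl] > 0) >= t@prelimGenesMin, logical(1))]
  m <- counts[, keptCells, drop = FALSE]
  keptGenes <- rownames(m)[vapply(rownames(m), function(g)
    sum(m[g, ] > 0) >= t@geneMinCells, logical(1))]
  m <- m[keptGenes, , drop = FALSE]
  # stage 2
  keptCells <- keptCells[score[keptCells] <= t@doubletScoreMax]
  m <- m[, keptCells, drop = FALSE]
  # stage 3
  ok <- vapply(keptCells, function(cl) {
    v <- m[, cl]
    umi <- sum(v)
    mito <- if (length(mitoGenes))
      100 * sum(v[intersect(mitoGenes, keptGenes)]) / max(umi, 1) else 0
    ng <- sum(v > 0)
    !(mito > t@mitoPctMax || umi > t@umiMax || umi < t@umiMin ||
        ng > t@genesMax || ng < t@genesMin)
  }, logical(1))
  list(cells = keptCells[ok], genes = keptGenes)
}

# brute-force atlas detection filter
bruteAtlasDetection <- function(counts, minGenesPerCell, minCount,
                                minCells) {
  keepC <- vapply(seq_len(ncol(counts)), function(j)
    sum(counts[, j] > 0) >= minGenesPerCell, logical(1))
  m <- counts[, keepC, drop = FALSE]
  keepG <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] >= minCount) >= minCells, logical(1))
  list(cells = colnames(counts)[keepC], genes = rownames(m)[keepG])
}

# brute-force DE threshold pass (genotype variant semantics)
bruteDEPass <- function(df, bfMin, lfcMin, fracMin, peakMin,
                        fracRule = "max") {
  vapply(seq_len(nrow(df)), function(i) {
    frac <- if (fracRule == "max")
      max(df$frac_nonzero_A[i], df$frac_nonzero_B[i])
    else df$frac_nonzero_A[i]
    pass <- df$bayes_factor[i] > bfMin &&
      abs(df$lfc_mean[i]) > lfcMin && frac >= fracMin
    if (!is.na(peakMin)) pass <- pass && df$peak_expr[i] > peakMin
    pass
  }, logical(1))
}
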