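#' @importFrom stats rnbinom rpois rlnorm rnorm runif quantile sd lm coef setNames
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim<- reducedDim
#' @importFrom SummarizedExperiment assay assay<- rowData colData rowData<- colData<-
NULL

# NB draw with Poisson limit at size = Inf
.rcounts <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, lambda = mu) else rnbinom(n, mu = mu, size = size)
}

#' Simulate a multi-cell-type expression atlas with planted TRAs
#'
#' Draws negative-binomial counts for an atlas in which each gene is "on"
#' (mean \code{onMean}) in a planted subset of cell types of known size
#' (its breadth) and "off" (mean \code{offMean}) elsewhere. Genes with
#' breadth at most \code{traBreadthMax} are labelled tissue-restricted
#' antigens (TRAs) in the ground truth, giving specificity scoring a known
#' answer key.
#'
#' @param design an [AtlasDesign-class].
#' @param traBreadthMax maximal breadth still counted as restricted
#'   (default 2).
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   \code{counts} (genes x cells), per-gene \code{rowData} columns
#'   \code{gene_id}, \code{biotype}, \code{breadth}, \code{is_tra},
#'   \code{detectable}, per-cell \code{colData} columns \code{cell_id} and
#'   \code{cell_type}, and the design plus ground truth in
#'   \code{metadata()}.
#' @examples
#' sce <- simulateAtlas(atlasDesign(nCellTypes = 4, nCellsPerType = 10,
#'                                  nGenes = 50, seed = 1))
#' table(SummarizedExperiment::rowData(sce)$is_tra)
#' @export
simulateAtlas <- function(design, traBreadthMax = 2L) {
  stopifnot(is(design, "AtlasDesign"))
  validObject(design)
  nT <- design@nCellTypes
  nG <- design@nGenes
  nC <- design@nCellsPerType
  set.seed(design@seed)

  # planted on-groups per gene
  onGroups <- lapply(design@breadth, function(b) sort(sample.int(nT, b)))
  meanMat <- matrix(design@offMean, nrow = nG, ncol = nT)
  for (g in seq_len(nG)) meanMat[g, onGroups[[g]]] <- design@onMean

  counts <- matrix(0L, nrow = nG, ncol = nT * nC)
  for (t in seq_len(nT)) {
    mu <- rep(meanMat[, t], times = nC)
    block <- .rcounts(nG * nC, mu = mu, size = design@dispersion)
    counts[, (t - 1L) * nC + seq_len(nC)] <- block
  }

  geneIds <- sprintf("gene%05d", seq_len(nG))
  types <- paste0("celltype", seq_len(nT))
  cellType <- rep(types, each = nC)
  cellIds <- sprintf("%s_cell%04d", cellType, unlist(lapply(seq_len(nT),
                     function(t) seq_len(nC))))
  dimnames(counts) <- list(geneIds, cellIds)

  isTRA <- design@breadth <= traBreadthMax
  detectable <- rowSums(counts) > 0

  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      gene_id = geneIds, biotype = "protein_coding",
      breadth = design@breadth, is_tra = isTRA, detectable = detectable,
      row.names = geneIds),
    colData = S4Vectors::DataFrame(
      cell_id = cellIds, cell_type = cellType, row.names = cellIds))
  S4Vectors::metadata(sce) <- list(
    design = design,
    groundTruth = list(
      tra_labels = setNames(isTRA, geneIds),
      breadth = setNames(design@breadth, geneIds),
      on_groups = setNames(lapply(onGroups, function(i) types[i]), geneIds),
      detectable = setNames(detectable, geneIds)))
  sce
}

#' Simulate a replicated WT/KO single-cell experiment
#'
#' Generates a multi-sample experiment with the statistical structure the
#' downstream analyses assume: per-sample cell-type draws from
#' genotype-specific composition vectors (so composition shifts are planted
#' exactly), multiplicative regulated-gene effects applied only in
#' non-reference genotypes and only in affected cell types, batch genes
#' with replicate-specific offsets shared across genotypes, per-cell-type
#' Gaussian embedding clusters, lognormal cell size factors, and planted
#' doublets (inflated totals, high doublet score) and damaged cells
#' (elevated mitochondrial share) for the QC cascade to remove.
#'
#' Each sample is drawn from its own RNG stream derived from the master
#' seed and the sample index, so adding a sample never perturbs earlier
#' ones.
#'
#' @param design an [ExperimentDesign-class].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   \code{counts}, colData columns \code{cell_id}, \code{sample_id},
#'   \code{genotype}, \code{replicate}, \code{cell_type}, \code{umap1},
#'   \code{umap2}, \code{doublet_score}, \code{planted_doublet},
#'   \code{planted_low_quality}, a \code{"UMAP"} entry in
#'   \code{reducedDims}, and ground truth (regulated calls, batch offsets,
#'   per-genotype planted composition log2 fold changes) in
#'   \code{metadata()}.
#' @examples
#' sce <- simulateTECExperiment(experimentDesign(cellsPerSample = 100,
#'                                               nGenes = 40, seed = 3))
#' table(sce$sample_id)
#' @export
simulateTECExperiment <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  if (!design@reference %in% design@genotypes)
    stop("reference genotype '", design@reference,
         "' absent from design genotypes")
  nG <- design@nGenes
  nT <- length(design@cellTypes)
  nR <- design@replicates
  genotypes <- design@genotypes

  ## ---- master stream: gene-level structure shared across samples ----
  set.seed(design@seed)
  geneMean <- rlnorm(nG, meanlog = log(design@baseMean) - 0.5, sdlog = 1)
  typeEffect <- matrix(rlnorm(nG * nT, meanlog = -0.045, sdlog = 0.3),
                       nrow = nG, ncol = nT)

  geneIds <- sprintf("gene%05d", seq_len(nG))
  mitoIdx <- seq_len(min(design@nMitoGenes, nG))
  if (length(mitoIdx)) {
    geneIds[mitoIdx] <- paste0("mt-", seq_along(mitoIdx))
    # pin baseline mitochondrial share near 2% of counts, well under the
    # 5% exclusion cut, so only planted damaged cells cross it
    nonMito <- sum(geneMean[-mitoIdx])
    geneMean[mitoIdx] <- nonMito * 0.02 / 0.98 / length(mitoIdx)
    typeEffect[mitoIdx, ] <- 1
  }

  ## regulated-gene multipliers per (gene, type), non-reference genotypes only
  regMult <- matrix(1, nrow = nG, ncol = nT)
  reg <- design@regulated
  if (nrow(reg)) {
    for (k in seq_len(nrow(reg))) {
      tys <- reg$cell_types[[k]]
      cols <- if (is.null(tys) || all(is.na(tys))) seq_len(nT)
              else match(tys, design@cellTypes)
      shift <- if (reg$direction[k] == "induced") -reg$effect[k] else reg$effect[k]
      regMult[reg$gene[k], cols] <- 2^shift
    }
  }

  ## replicate-specific batch offsets (log2), shared across genotypes
  batchOff <- matrix(0, nrow = nG, ncol = nR)
  if (length(design@batchGenes)) {
    for (g in design@batchGenes) {
      s <- sample(c(-1, 0, 1), nR, replace = TRUE)
      while (length(unique(s)) == 1L) s <- sample(c(-1, 0, 1), nR, replace = TRUE)
      batchOff[g, ] <- design@batchEffect * s
    }
  }

  ## ---- per-sample streams ----
  samples <- expand.grid(replicate = seq_len(nR), genotype = genotypes,
                         stringsAsFactors = FALSE)[, 2:1]
  pieces <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    gt <- samples$genotype[i]; rep_ <- samples$replicate[i]
    set.seed(design@seed + 1009L * i)
    n <- design@cellsPerSample
    type <- sample(design@cellTypes, n, replace = TRUE,
                   prob = design@composition[gt, ])
    sizeFactor <- rlnorm(n, meanlog = -0.045, sdlog = 0.3)
    u <- runif(n)
    doublet <- u < design@doubletFraction
    lowq <- !doublet & u < design@doubletFraction + design@lowQualityFraction
    sizeFactor[doublet] <- sizeFactor[doublet] * 2

    tIdx <- match(type, design@cellTypes)
    mu <- geneMean * typeEffect[, tIdx, drop = FALSE]
    if (gt != design@reference) mu <- mu * regMult[, tIdx, drop = FALSE]
    mu <- mu * 2^batchOff[, rep_]
    mu <- sweep(mu, 2L, sizeFactor, "*")
    if (any(lowq) && length(mitoIdx)) {
      boost <- runif(sum(lowq), 3, 10)
      mu[mitoIdx, lowq] <- sweep(mu[mitoIdx, lowq, drop = FALSE], 2L, boost, "*")
    }
    counts <- matrix(.rcounts(length(mu), mu = as.vector(mu),
                              size = design@dispersion),
                     nrow = nG, ncol = n)

    coords <- design@embeddingCenters[tIdx, , drop = FALSE] +
      matrix(rnorm(2L * n, sd = design@embeddingSD), ncol = 2L)
    score <- runif(n, 0, 0.15)
    score[doublet] <- runif(sum(doublet), 0.25, 0.9)

    sid <- paste0(gt, "_r", rep_)
    pieces[[i]] <- list(
      counts = counts,
      cells = data.frame(
        cell_id = sprintf("%s_c%04d", sid, seq_len(n)),
        sample_id = sid, genotype = gt, replicate = rep_,
        cell_type = type, umap1 = coords[, 1L], umap2 = coords[, 2L],
        doublet_score = score, planted_doublet = doublet,
        planted_low_quality = lowq, stringsAsFactors = FALSE))
  }

  counts <- do.call(cbind, lapply(pieces, `[[`, "counts"))
  cells <- do.call(rbind, lapply(pieces, `[[`, "cells"))
  dimnames(counts) <- list(geneIds, cells$cell_id)

  rowDf <- S4Vectors::DataFrame(
    gene_id = geneIds, biotype = "protein_coding",
    is_mito = seq_len(nG) %in% mitoIdx,
    base_mean = geneMean,
    is_regulated = seq_len(nG) %in% reg$gene,
    is_batch = seq_len(nG) %in% design@batchGenes,
    row.names = geneIds)

  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = rowDf,
    colData = S4Vectors::DataFrame(cells, row.names = cells$cell_id))
  reducedDim(sce, "UMAP") <- as.matrix(cells[, c("umap1", "umap2")])

  ## ---- ground truth ----
  ref <- design@composition[design@reference, ]
  nonRef <- setdiff(genotypes, design@reference)
  compFC <- NULL
  if (length(nonRef)) {
    compFC <- t(vapply(nonRef, function(g) {
      fc <- log2(design@composition[g, ] / ref)
      fc[design@composition[g, ] == 0 & ref == 0] <- 0
      fc
    }, numeric(nT)))
    dimnames(compFC) <- list(nonRef, design@cellTypes)
  }
  regTruth <- if (nrow(reg)) data.frame(
    gene_id = geneIds[reg$gene], direction = reg$direction,
    effect = reg$effect,
    ko_log2fc = ifelse(reg$direction == "induced", -reg$effect, reg$effect),
    cell_types = I(reg$cell_types), stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), direction = character(),
                  effect = numeric(), ko_log2fc = numeric(),
                  cell_types = I(list()))

  S4Vectors::metadata(sce) <- list(
    design = design,
    groundTruth = list(
      regulated = regTruth,
      batch = list(gene_id = geneIds[design@batchGenes],
                   log2_offsets = batchOff[design@batchGenes, , drop = FALSE]),
      compositionLog2FC = compFC,
      qc = cells[, c("cell_id", "planted_doublet", "planted_low_quality")]))
  sce
}
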