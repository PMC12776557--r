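#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# Simulation designs
# ---------------------------------------------------------------------------

#' Design of a synthetic multi-tissue atlas
#'
#' Describes a cross-cell-type expression atlas used to exercise
#' tissue-restricted antigen (TRA) scoring: a set of cell types, a set of
#' genes each "on" in a controlled number of cell types (its restriction
#' breadth), and a negative-binomial count model.
#'
#' @slot nCellTypes number of cell types (groups) in the atlas.
#' @slot nCellsPerType cells simulated per cell type.
#' @slot nGenes number of genes.
#' @slot breadth integer vector, one entry per gene, giving the number of
#'   cell types (1..nCellTypes) in which the gene is expressed at
#'   \code{onMean}; elsewhere it is expressed at \code{offMean}.
#' @slot onMean,offMean expected raw counts in on/off cell types;
#'   \code{onMean > offMean >= 0}.
#' @slot dispersion negative-binomial size (inverse-dispersion) parameter;
#'   \code{Inf} selects the Poisson limit.
#' @slot seed integer master seed.
#'
#' @seealso [atlasDesign()], [simulateAtlas()]
#' @export
setClass("AtlasDesign",
  slots = c(
    nCellTypes = "integer",
    nCellsPerType = "integer",
    nGenes = "integer",
    breadth = "integer",
    onMean = "numeric",
    offMean = "numeric",
    dispersion = "numeric",
    seed = "integer"
  )
)

setValidity("AtlasDesign", function(object) {
  msg <- character()
  if (length(object@nCellTypes) != 1L || object@nCellTypes < 1L)
    msg <- c(msg, "nCellTypes: must be a single positive integer")
  if (length(object@nCellsPerType) != 1L || object@nCellsPerType < 1L)
    msg <- c(msg, "nCellsPerType: must be a single positive integer")
  if (length(object@nGenes) != 1L || object@nGenes < 1L)
    msg <- c(msg, "nGenes: must be a single positive integer")
  if (length(object@breadth) != object@nGenes)
    msg <- c(msg, "breadth: must have one entry per gene")
  else if (any(object@breadth < 1L) ||
           any(object@breadth > object@nCellTypes))
    msg <- c(msg, "breadth: every gene's breadth must lie in 1..nCellTypes")
  if (length(object@offMean) != 1L || object@offMean < 0)
    msg <- c(msg, "offMean: must be a single value >= 0")
  if (length(object@onMean) != 1L ||
      (length(object@offMean) == 1L && object@onMean < object@offMean))
    msg <- c(msg, "onMean: must satisfy onMean > offMean >= 0 (equality only when both are 0)")
  if (length(object@onMean) == 1L && length(object@offMean) == 1L &&
      object@onMean == object@offMean && object@onMean > 0)
    msg <- c(msg, "onMean: must be strictly greater than offMean unless both are 0")
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msg <- c(msg, "dispersion: must be a single value > 0 (Inf for Poisson)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an atlas simulation design
#'
#' @param nCellTypes,nCellsPerType,nGenes atlas dimensions.
#' @param breadth per-gene restriction breadth. The default assigns 10% of
#'   genes breadth 1, 10% breadth 2, and the remainder the full breadth
#'   \code{nCellTypes}, mimicking an atlas dominated by broadly expressed
#'   genes with a restricted minority.
#' @param onMean,offMean expected counts in on/off cell types.
#' @param dispersion negative-binomial size parameter (\code{Inf} = Poisson).
#' @param seed integer master seed.
#' @return An [AtlasDesign-class] object.
#' @examples
#' atlasDesign(nCellTypes = 5, nCellsPerType = 20, nGenes = 100, seed = 1)
#' @export
atlasDesign <- function(nCellTypes = 20L, nCellsPerType = 200L,
                        nGenes = 2000L, breadth = NULL,
                        onMean = 5, offMean = 0.1,
                        dispersion = 2, seed = 1L) {
  nCellTypes <- as.integer(nCellTypes)
  nGenes <- as.integer(nGenes)
  if (is.null(breadth)) {
    n1 <- max(1L, round(0.1 * nGenes))
    n2 <- max(1L, round(0.1 * nGenes))
    breadth <- rep(nCellTypes, nGenes)
    breadth[seq_len(n1)] <- 1L
    breadth[n1 + seq_len(min(n2, nGenes - n1))] <- min(2L, nCellTypes)
  }
  new("AtlasDesign",
      nCellTypes = nCellTypes,
      nCellsPerType = as.integer(nCellsPerType),
      nGenes = nGenes,
      breadth = as.integer(breadth),
      onMean = as.numeric(onMean),
      offMean = as.numeric(offMean),
      dispersion = as.numeric(dispersion),
      seed = as.integer(seed))
}

#' Design of a synthetic WT/KO single-cell experiment
#'
#' Describes a multi-replicate wild-type versus knockout experiment with
#' planted cell-type composition shifts, planted induced/repressed gene
#' programs, replicate-specific batch-effect genes, per-cell-type 2D
#' embedding clusters, and optional planted doublets and low-quality cells
#' so the QC cascade has true positives.
#'
#' @slot genotypes condition labels; the first or \code{reference} is the
#'   control.
#' @slot reference the reference (control) genotype label.
#' @slot replicates replicates per genotype.
#' @slot cellsPerSample cells drawn per sample.
#' @slot cellTypes cell-type labels.
#' @slot composition genotype x cell-type matrix of probabilities; each row
#'   sums to 1.
#' @slot nGenes number of genes.
#' @slot baseMean expected mean count per gene (lognormal means are drawn
#'   around this at simulation time).
#' @slot dispersion negative-binomial size; \code{Inf} = Poisson.
#' @slot regulated data.frame with columns \code{gene} (index),
#'   \code{direction} ("induced"/"repressed" by the TF, i.e. lower/higher in
#'   the KO), \code{effect} (positive log2 magnitude) and \code{cell_types}
#'   (list column of affected types, NA = all).
#' @slot batchGenes gene indices given replicate-specific offsets.
#' @slot batchEffect log2 magnitude of the batch offsets.
#' @slot doubletFraction fraction of cells planted as doublets (inflated
#'   totals, doublet score above 0.2).
#' @slot lowQualityFraction fraction of cells planted as damaged (elevated
#'   mitochondrial share).
#' @slot nMitoGenes number of leading genes named "mt-*" acting as the
#'   mitochondrial set.
#' @slot embeddingCenters cell-type x 2 matrix of embedding centroids.
#' @slot embeddingSD per-type Gaussian spread of the embedding.
#' @slot seed integer master seed.
#'
#' @seealso [experimentDesign()], [simulateTECExperiment()]
#' @export
setClass("ExperimentDesign",
  slots = c(
    genotypes = "character",
    reference = "character",
    replicates = "integer",
    cellsPerSample = "integer",
    cellTypes = "character",
    composition = "matrix",
    nGenes = "integer",
    baseMean = "numeric",
    dispersion = "numeric",
    regulated = "data.frame",
    batchGenes = "integer",
    batchEffect = "numeric",
    doubletFraction = "numeric",
    lowQualityFraction = "numeric",
    nMitoGenes = "integer",
    embeddingCenters = "matrix",
    embeddingSD = "numeric",
    seed = "integer"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (length(object@genotypes) < 1L || anyDuplicated(object@genotypes))
    msg <- c(msg, "genotypes: must be a non-empty set of unique labels")
  if (!object@reference %in% object@genotypes)
    msg <- c(msg, "reference: reference genotype absent from genotypes")
  if (length(object@replicates) != 1L || object@replicates < 1L)
    msg <- c(msg, "replicates: must be a single positive integer")
  if (length(object@cellTypes) < 1L || anyDuplicated(object@cellTypes))
    msg <- c(msg, "cellTypes: must be unique labels")
  if (!identical(dim(object@composition),
                 c(length(object@genotypes), length(object@cellTypes))))
    msg <- c(msg, "composition: must be a genotype x cell-type matrix")
  else if (any(abs(rowSums(object@composition) - 1) > 1e-9))
    msg <- c(msg, "composition: each genotype's composition must sum to 1 (tolerance 1e-9)")
  else if (any(object@composition < 0))
    msg <- c(msg, "composition: probabilities must be nonnegative")
  if (nrow(object@regulated)) {
    need <- c("gene", "direction", "effect", "cell_types")
    if (!all(need %in% names(object@regulated)))
      msg <- c(msg, "regulated: needs columns gene, direction, effect, cell_types")
    else {
      if (any(object@regulated$effect == 0))
        msg <- c(msg, "regulated: every regulated gene must have nonzero effect magnitude")
      if (!all(object@regulated$direction %in% c("induced", "repressed")))
        msg <- c(msg, "regulated: direction must be 'induced' or 'repressed'")
      if (any(object@regulated$gene < 1L) ||
          any(object@regulated$gene > object@nGenes))
        msg <- c(msg, "regulated: gene indices out of range")
    }
  }
  if (any(object@batchGenes < 1L) || any(object@batchGenes > object@nGenes))
    msg <- c(msg, "batchGenes: gene indices out of range")
  if (length(object@doubletFraction) != 1L ||
      object@doubletFraction < 0 || object@doubletFraction >= 1)
    msg <- c(msg, "doubletFraction: must lie in [0, 1)")
  if (length(object@lowQualityFraction) != 1L ||
      object@lowQualityFraction < 0 || object@lowQualityFraction >= 1)
    msg <- c(msg, "lowQualityFraction: must lie in [0, 1)")
  if (!identical(dim(object@embeddingCenters),
                 c(length(object@cellTypes), 2L)))
    msg <- c(msg, "embeddingCenters: must be a cell-type x 2 matrix")
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msg <- c(msg, "dispersion: must be > 0 (Inf for Poisson)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a WT/KO experiment simulation design
#'
#' Defaults emulate a modest thymic epithelial experiment: two genotypes
#' with two replicates each, a handful of cell types on a circular
#' embedding, overdispersed counts, and small planted doublet and
#' low-quality fractions so the QC cascade is exercised.
#'
#' @param genotypes condition labels; \code{reference} must be among them.
#' @param reference control genotype (defaults to the first label).
#' @param replicates replicates per genotype.
#' @param cellsPerSample cells per sample.
#' @param cellTypes cell-type labels.
#' @param composition genotype x cell-type probability matrix (rows sum
#'   to 1). Default: uniform composition, identical across genotypes.
#' @param nGenes number of genes.
#' @param baseMean expected per-gene mean count.
#' @param dispersion negative-binomial size (\code{Inf} = Poisson).
#' @param regulated data.frame of planted regulated genes (see
#'   [ExperimentDesign-class]); empty by default.
#' @param batchGenes indices of genes given replicate-specific offsets.
#' @param batchEffect log2 magnitude of batch offsets.
#' @param doubletFraction,lowQualityFraction planted QC-failure fractions.
#' @param nMitoGenes number of leading "mt-*" genes.
#' @param embeddingCenters cell-type x 2 centroid matrix; default places
#'   types on a circle of radius 5.
#' @param embeddingSD Gaussian spread of each type's embedding cluster.
#' @param seed integer master seed.
#' @return An [ExperimentDesign-class] object.
#' @examples
#' experimentDesign(cellsPerSample = 200, nGenes = 50, seed = 7)
#' @export
experimentDesign <- function(genotypes = c("WT", "KO"),
                             reference = genotypes[[1L]],
                             replicates = 2L,
                             cellsPerSample = 1000L,
                             cellTypes = paste0("type", 1:4),
                             composition = NULL,
                             nGenes = 500L,
                             baseMean = 2,
                             dispersion = 2,
                             regulated = emptyRegulated(),
                             batchGenes = integer(),
                             batchEffect = 1.5,
                             doubletFraction = 0.03,
                             lowQualityFraction = 0.02,
                             nMitoGenes = 5L,
                             embeddingCenters = NULL,
                             embeddingSD = 0.6,
                             seed = 1L) {
  nT <- length(cellTypes)
  if (is.null(composition)) {
    composition <- matrix(1 / nT, nrow = length(genotypes), ncol = nT,
                          dimnames = list(genotypes, cellTypes))
  } else {
    dimnames(composition) <- list(genotypes, cellTypes)
  }
  if (is.null(embeddingCenters)) {
    theta <- 2 * pi * (seq_len(nT) - 1L) / nT
    embeddingCenters <- cbind(5 * cos(theta), 5 * sin(theta))
  }
  rownames(embeddingCenters) <- cellTypes
  new("ExperimentDesign",
      genotypes = genotypes, reference = reference,
      replicates = as.integer(replicates),
      cellsPerSample = as.integer(cellsPerSample),
      cellTypes = cellTypes, composition = composition,
      nGenes = as.integer(nGenes), baseMean = as.numeric(baseMean),
      dispersion = as.numeric(dispersion), regulated = regulated,
      batchGenes = as.integer(batchGenes),
      batchEffect = as.numeric(batchEffect),
      doubletFraction = as.numeric(doubletFraction),
      lowQualityFraction = as.numeric(lowQualityFraction),
      nMitoGenes = as.integer(nMitoGenes),
      embeddingCenters = embeddingCenters,
      embeddingSD = as.numeric(embeddingSD),
      seed = as.integer(seed))
}

#' Empty regulated-gene table
#'
#' @return A zero-row data.frame with the regulated-gene columns.
#' @export
emptyRegulated <- function() {
  data.frame(gene = integer(), direction = character(),
             effect = numeric(),
             cell_types = I(list()))
}

#' @describeIn AtlasDesign-class compact design summary
#' @param object an \code{AtlasDesign}
#' @export
setMethod("show", "AtlasDesign", function(object) {
  cat("AtlasDesign:", object@nCellTypes, "cell types x",
      object@nCellsPerType, "cells,", object@nGenes, "genes\n")
  cat("  on/off mean:", object@onMean, "/", object@offMean,
      " dispersion:", object@dispersion, " seed:", object@seed, "\n")
  cat("  breadth: ", sum(object@breadth == 1L), " genes breadth 1, ",
      sum(object@breadth == 2L), " breadth 2, ",
      sum(object@breadth > 2L), " broader\n", sep = "")
})

#' @describeIn ExperimentDesign-class compact design summary
#' @param object an \code{ExperimentDesign}
#' @export
setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", paste(object@genotypes, collapse = "/"),
      sprintf("(reference %s), %d replicate(s) x %d cells",
              object@reference, object@replicates, object@cellsPerSample), "\n")
  cat("  ", length(object@cellTypes), " cell types, ", object@nGenes,
      " genes, ", nrow(object@regulated), " regulated, ",
      length(object@batchGenes), " batch genes\n", sep = "")
})

# ---------------------------------------------------------------------------
# QC thresholds and report
# ---------------------------------------------------------------------------

#' Quality-control thresholds
#'
#' Holds the cut-offs of the cell/gene filter cascade. Comparison
#' semantics follow the wording they implement: cells are removed for
#' doublet score strictly over \code{doubletScoreMax}, mitochondrial
#' percentage strictly over \code{mitoPctMax}, UMI totals strictly over
#' \code{umiMax} or strictly under \code{umiMin}, and detected-gene counts
#' strictly over \code{genesMax} or strictly under \code{genesMin}.
#'
#' @slot doubletScoreMax maximum tolerated doublet score (default 0.2).
#' @slot mitoPctMax maximum mitochondrial percentage (default 5).
#' @slot umiMin,umiMax tolerated UMI window (defaults 1000, 70000).
#' @slot genesMin,genesMax tolerated detected-gene window (1000, 8500).
#' @slot prelimGenesMin preliminary minimum genes per cell (default 100).
#' @slot geneMinCells minimum cells a gene must be detected in (default 20).
#' @export
setClass("QCThresholds",
  slots = c(doubletScoreMax = "numeric", mitoPctMax = "numeric",
            umiMin = "numeric", umiMax = "numeric",
            genesMin = "numeric", genesMax = "numeric",
            prelimGenesMin = "numeric", geneMinCells = "numeric"))

setValidity("QCThresholds", function(object) {
  msg <- character()
  if (object@umiMin >= object@umiMax)
    msg <- c(msg, "umiMin must be < umiMax")
  if (object@genesMin >= object@genesMax)
    msg <- c(msg, "genesMin must be < genesMax")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct QC thresholds
#'
#' @param doubletScoreMax,mitoPctMax,umiMin,umiMax,genesMin,genesMax,prelimGenesMin,geneMinCells
#'   see [QCThresholds-class].
#' @return A [QCThresholds-class] object.
#' @examples
#' qcThresholds()                        # the standard cascade
#' qcThresholds(mitoPctMax = 10)         # relaxed mitochondrial cut
#' @export
qcThresholds <- function(doubletScoreMax = 0.2, mitoPctMax = 5,
                         umiMin = 1000, umiMax = 70000,
                         genesMin = 1000, genesMax = 8500,
                         prelimGenesMin = 100, geneMinCells = 20) {
  new("QCThresholds", doubletScoreMax = doubletScoreMax,
      mitoPctMax = mitoPctMax, umiMin = umiMin, umiMax = umiMax,
      genesMin = genesMin, genesMax = genesMax,
      prelimGenesMin = prelimGenesMin, geneMinCells = geneMinCells)
}

#' @describeIn QCThresholds-class print the thresholds
#' @param object a \code{QCThresholds}
#' @export
setMethod("show", "QCThresholds", function(object) {
  cat("QCThresholds: doublet >", object@doubletScoreMax,
      "| mito% >", object@mitoPctMax,
      "| UMI outside [", object@umiMin, ",", object@umiMax, "]",
      "| genes outside [", object@genesMin, ",", object@genesMax, "]\n")
  cat("  preliminary: cells <", object@prelimGenesMin,
      "genes; genes in <", object@geneMinCells, "cells\n")
})

#' Per-stage quality-control report
#'
#' Records, for each stage of the filter cascade, how many cells (or
#' genes) it removed. Each cell is attributed to the first stage that
#' removed it, so removed counts and the output size partition the input.
#'
#' @slot stages data.frame with columns \code{stage}, \code{what}
#'   ("cells"/"genes") and \code{removed}.
#' @slot cellsIn,cellsOut,genesIn,genesOut cascade totals.
#' @export
setClass("QCReport",
  slots = c(stages = "data.frame",
            cellsIn = "integer", cellsOut = "integer",
            genesIn = "integer", genesOut = "integer"))

setValidity("QCReport", function(object) {
  cellRem <- sum(object@stages$removed[object@stages$what == "cells"])
  geneRem <- sum(object@stages$removed[object@stages$what == "genes"])
  msg <- character()
  if (object@cellsIn != object@cellsOut + cellRem)
    msg <- c(msg, "cell conservation violated: cellsIn != cellsOut + removed")
  if (object@genesIn != object@genesOut + geneRem)
    msg <- c(msg, "gene conservation violated: genesIn != genesOut + removed")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn QCReport-class print the per-stage table
#' @param object a \code{QCReport}
#' @export
setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@cellsIn, "->", object@cellsOut, "cells;",
      object@genesIn, "->", object@genesOut, "genes\n")
  print(object@stages, row.names = FALSE)
})

#' Per-stage removal table of a QC report
#'
#' @param x a [QCReport-class]
#' @return data.frame with one row per cascade stage.
#' @export
qcStages <- function(x) {
  stopifnot(is(x, "QCReport"))
  x@stages
}

# ---------------------------------------------------------------------------
# TRA threshold calibration
# ---------------------------------------------------------------------------

#' Calibrated TRA classification thresholds
#'
#' Couples a chosen Tau threshold with the entropy-score threshold obtained
#' by evaluating the fitted log-model \code{entropy_score = a + b ln(tau)}
#' at that Tau value (clamped to [0, 1]).
#'
#' @slot tauStar the chosen Tau threshold.
#' @slot entropyStar the calibrated entropy-score threshold.
#' @slot intercept,slope fitted (a, b) of the calibration model.
#' @slot nGenes number of genes entering the fit (tau > 0).
#' @export
setClass("TRACalibration",
  slots = c(tauStar = "numeric", entropyStar = "numeric",
            intercept = "numeric", slope = "numeric", nGenes = "integer"))

setValidity("TRACalibration", function(object) {
  if (object@entropyStar < 0 || object@entropyStar > 1)
    "entropyStar must lie in [0, 1] after clamping"
  else TRUE
})

#' @describeIn TRACalibration-class print the calibration
#' @param object a \code{TRACalibration}
#' @export
setMethod("show", "TRACalibration", function(object) {
  cat(sprintf(
    "TRACalibration: tau* = %g -> entropy* = %.6g  [E = %.4g + %.4g ln(tau), n = %d]\n",
    object@tauStar, object@entropyStar, object@intercept, object@slope,
    object@nGenes))
})

#' @rdname TRACalibration-class
#' @param x a \code{TRACalibration}
#' @export
tauStar <- function(x) x@tauStar

#' @rdname TRACalibration-class
#' @export
entropyStar <- function(x) x@entropyStar

# ---------------------------------------------------------------------------
# DE thresholds
# ---------------------------------------------------------------------------

#' Differential-expression threshold set
#'
#' A gene passes when its Bayes factor is strictly over \code{bfMin}, its
#' absolute mean log2 fold change strictly over \code{lfcAbsMin}, its
#' nonzero-expression fraction at least \code{fracMin} (inclusive), and —
#' when \code{peakMin} is finite — its peak (99th percentile) normalised
#' expression strictly over \code{peakMin}.
#'
#' @slot bfMin Bayes-factor cut (strict).
#' @slot lfcAbsMin absolute log2 fold-change cut (strict).
#' @slot fracMin detection-fraction cut (inclusive).
#' @slot peakMin peak-expression cut (strict); \code{NA} disables it.
#' @slot fracRule which group anchors the detection fraction: "max" uses
#'   the larger of the two groups' fractions, "groupA" the group of
#'   interest.
#' @export
setClass("DEThresholds",
  slots = c(bfMin = "numeric", lfcAbsMin = "numeric", fracMin = "numeric",
            peakMin = "numeric", fracRule = "character"))

setValidity("DEThresholds", function(object) {
  msg <- character()
  vals <- c(object@bfMin, object@lfcAbsMin, object@fracMin)
  if (any(vals < 0)) msg <- c(msg, "thresholds must be >= 0")
  if (!is.na(object@peakMin) && object@peakMin < 0)
    msg <- c(msg, "peakMin must be >= 0 or NA")
  if (!object@fracRule %in% c("max", "groupA"))
    msg <- c(msg, "fracRule must be 'max' or 'groupA'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a DE threshold set
#'
#' Three presets mirror the three filtering variants used across the
#' analysis: \describe{
#'   \item{"genotype"}{WT-vs-KO contrasts: Bayes factor > 2.5,
#'     |log2 FC| > 1, detection fraction >= 5% (in the better-detected
#'     group), peak normalised expression > 0.5.}
#'   \item{"marker"}{subcluster marker genes: Bayes factor > 3,
#'     |log FC| > 1, detection >= 10% of the group of interest, no peak
#'     requirement.}
#'   \item{"mimetic"}{mimetic-subset-vs-rest contrasts: Bayes factor >
#'     2.5, |log FC| > 1, detection >= 10% of the population of interest,
#'     no peak requirement.}
#' }
#'
#' @param variant one of "genotype", "marker", "mimetic".
#' @param bfMin,lfcAbsMin,fracMin,peakMin,fracRule explicit overrides of
#'   the preset values.
#' @return A [DEThresholds-class] object.
#' @examples
#' deThresholds("genotype")
#' deThresholds("marker", bfMin = 4)
#' @export
deThresholds <- function(variant = c("genotype", "marker", "mimetic"),
                         bfMin = NULL, lfcAbsMin = NULL, fracMin = NULL,
                         peakMin = NULL, fracRule = NULL) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    genotype = list(bfMin = 2.5, lfcAbsMin = 1, fracMin = 0.05,
                    peakMin = 0.5, fracRule = "max"),
    marker   = list(bfMin = 3,   lfcAbsMin = 1, fracMin = 0.10,
                    peakMin = NA_real_, fracRule = "groupA"),
    mimetic  = list(bfMin = 2.5, lfcAbsMin = 1, fracMin = 0.10,
                    peakMin = NA_real_, fracRule = "groupA"))
  new("DEThresholds",
      bfMin = if (is.null(bfMin)) preset$bfMin else bfMin,
      lfcAbsMin = if (is.null(lfcAbsMin)) preset$lfcAbsMin else lfcAbsMin,
      fracMin = if (is.null(fracMin)) preset$fracMin else fracMin,
      peakMin = if (is.null(peakMin)) preset$peakMin else peakMin,
      fracRule = if (is.null(fracRule)) preset$fracRule else fracRule)
}

#' @describeIn DEThresholds-class print the thresholds
#' @param object a \code{DEThresholds}
#' @export
setMethod("show", "DEThresholds", function(object) {
  cat("DEThresholds: BF >", object@bfMin, "| |log2FC| >", object@lfcAbsMin,
      "| frac >=", object@fracMin,
      if (!is.na(object@peakMin)) paste("| peak >", object@peakMin) else "",
      "| frac rule:", object@fracRule, "\n")
})

# ---------------------------------------------------------------------------
# 2D Gaussian KDE
# ---------------------------------------------------------------------------

#' Product-Gaussian kernel density estimate in 2D
#'
#' A fitted two-dimensional KDE with a diagonal (per-dimension) bandwidth.
#' The density integrates to 1, so genotype-conditional fits reflect
#' relative composition rather than absolute cell numbers.
#'
#' @slot points n x 2 matrix of training coordinates.
#' @slot bandwidth per-dimension bandwidths (length 2, positive).
#' @seealso [gaussianKDE2D()], [kdeLogDensity()]
#' @export
setClass("GaussianKDE2D",
  slots = c(points = "matrix", bandwidth = "numeric"))

setValidity("GaussianKDE2D", function(object) {
  msg <- character()
  if (ncol(object@points) != 2L)
    msg <- c(msg, "points must have exactly 2 columns")
  if (length(object@bandwidth) != 2L || any(object@bandwidth <= 0))
    msg <- c(msg, "bandwidth must be two positive values")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn GaussianKDE2D-class print a fitted KDE
#' @param object a \code{GaussianKDE2D}
#' @export
setMethod("show", "GaussianKDE2D", function(object) {
  cat(sprintf("GaussianKDE2D: %d points, bandwidth (%.4g, %.4g)\n",
              nrow(object@points), object@bandwidth[1L],
              object@bandwidth[2L]))
})
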