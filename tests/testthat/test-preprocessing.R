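test_that("protein-coding filter keeps only annotated genes", {
  counts <- randomCounts(10, 5)
  sce <- makeSCE(counts, biotype = c(rep("protein_coding", 4),
                                     rep("lncRNA", 6)))
  expect_equal(nrow(filterProteinCoding(sce)), 4)
  expect_equal(ncol(filterProteinCoding(sce)), 5)

  all_pc <- makeSCE(counts)
  expect_identical(dim(filterProteinCoding(all_pc)), dim(all_pc))

  mixed <- makeSCE(counts, biotype = c("Protein_Coding",
                                       rep("protein_coding", 9)))
  expect_equal(nrow(filterProteinCoding(mixed)), 9)          # exact match
  expect_equal(nrow(filterProteinCoding(mixed, ignoreCase = TRUE)), 10)
  expect_warning(filterProteinCoding(makeSCE(counts, biotype = "rRNA")),
                 "retained")
})

test_that("QC cascade removes the expected toy cells", {
  # 6 cells x 5 genes: one at 80000 UMIs, one at 500, one doublet, 3 clean
  counts <- matrix(400, nrow = 5, ncol = 6,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  counts[, 1] <- 16000   # 80000 UMIs
  counts[, 2] <- 100     # 500 UMIs
  score <- c(0, 0, 0.25, 0, 0, 0.1)
  sce <- makeSCE(counts, cellMeta = list(doublet_score = score))
  t <- qcThresholds(prelimGenesMin = 1, geneMinCells = 1, genesMin = 1,
                    genesMax = 100)
  res <- qcFilter(sce, t)
  expect_equal(ncol(res$sce), 3)
  expect_setequal(colnames(res$sce), c("c4", "c5", "c6"))
  st <- qcStages(res$report)
  expect_equal(st$removed[st$stage == "doublet_score"], 1)
  expect_equal(st$removed[st$stage == "umi_window"], 2)
})

test_that("a cell with exactly 1000 UMIs survives the strict boundary", {
  counts <- matrix(c(rep(200, 5), rep(199, 5)), nrow = 5,
                   dimnames = list(paste0("g", 1:5), c("at", "below")))
  sce <- makeSCE(counts, cellMeta = list(doublet_score = c(0, 0)))
  res <- qcFilter(sce, qcThresholds(prelimGenesMin = 1, geneMinCells = 1,
                                    genesMin = 1, genesMax = 100))
  expect_identical(colnames(res$sce), "at")   # 995 < 1000 removed
})

test_that("non-binding thresholds are the identity and doublets are required", {
  sce <- makeSCE(randomCounts(30, 20, lambda = 5),
                 cellMeta = list(doublet_score = rep(0, 20)))
  res <- qcFilter(sce, qcThresholds(doubletScoreMax = 1, mitoPctMax = 100,
                                    umiMin = 0, umiMax = 1e9, genesMin = 0,
                                    genesMax = 1e9, prelimGenesMin = 0,
                                    geneMinCells = 0))
  expect_identical(dim(res$sce), dim(sce))

  bare <- makeSCE(randomCounts(5, 3))
  expect_error(qcFilter(bare), "doublet")
})

test_that("QC report conserves cells and the cascade is idempotent", {
  ed <- experimentDesign(cellsPerSample = 250, nGenes = 300, seed = 21)
  sce <- simulateTECExperiment(ed)
  t <- qcThresholds(umiMin = 200, genesMin = 50, prelimGenesMin = 20)
  res1 <- qcFilter(sce, t)
  st <- qcStages(res1$report)
  expect_equal(res1$report@cellsIn,
               res1$report@cellsOut + sum(st$removed[st$what == "cells"]))
  # planted doublets and damaged cells are the removals
  expect_gt(st$removed[st$stage == "doublet_score"], 0)
  expect_gt(st$removed[st$stage == "mito_pct"], 0)
  res2 <- qcFilter(res1$sce, t)
  expect_identical(dim(res2$sce), dim(res1$sce))
  expect_identical(colnames(res2$sce), colnames(res1$sce))
})

test_that("library-size normalisation scales each cell to the target", {
  m <- matrix(c(1, 1, 2), nrow = 3)
  expect_equal(as.vector(normalizeCells(m)), c(2500, 2500, 5000))

  withZero <- cbind(c(1, 1, 2), c(0, 0, 0))
  expect_warning(norm <- normalizeCells(withZero), "all-zero")
  expect_equal(norm[, 2], c(0, 0, 0))

  r <- randomCounts(50, 20, lambda = 3, seed = 3)
  expect_true(all(abs(colSums(normalizeCells(r)) - 10000) < 1e-6))

  # scale equivariance: multiplying a cell's counts leaves its row unchanged
  r2 <- r; r2[, 1] <- r2[, 1] * 7
  expect_equal(normalizeCells(r2)[, 1], normalizeCells(r)[, 1])

  # log1p mode
  sce <- makeSCE(r)
  sce <- normalizeCells(sce, log1p = TRUE)
  expect_equal(assay(sce, "logcounts"), log1p(assay(sce, "normcounts")))
})

test_that("atlas detection filter honours inclusive boundaries", {
  # gene with count 2 in exactly 100 cells -> retained
  counts <- matrix(0L, nrow = 2, ncol = 120)
  counts[1, 1:100] <- 2L
  counts[2, ] <- 1L          # count 1 everywhere -> removed
  rownames(counts) <- c("boundary", "ubiquitous1")
  colnames(counts) <- sprintf("c%03d", 1:120)
  out <- atlasDetectionFilter(counts, minGenesPerCell = 1)
  expect_identical(rownames(out), "boundary")
})

test_that("atlas detection filter matches brute-force enumeration", {
  counts <- randomCounts(40, 60, lambda = 1, seed = 11)
  out <- atlasDetectionFilter(counts, minGenesPerCell = 25, minCount = 2,
                              minCells = 10)
  oracle <- bruteAtlasDetection(counts, 25, 2, 10)
  expect_identical(colnames(out), oracle$cells)
  expect_identical(rownames(out), oracle$genes)
})

test_that("display clipping winsorises to the interpolated percentiles", {
  expect_identical(clipForDisplay(rep(3, 10)), rep(3, 10))
  expect_identical(clipForDisplay(42), 42)
  v <- 0:100
  q <- quantile(v, c(0.01, 0.99), names = FALSE)
  expect_equal(range(clipForDisplay(v)), q)
  expect_equal(clipForDisplay(v)[50], 49)   # interior untouched
})
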