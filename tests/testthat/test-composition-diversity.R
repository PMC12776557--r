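test_that("composition fractions are per-sample proportions", {
  cells <- data.frame(sample_id = "s1",
                      cell_type = rep(c("X", "Y"), c(4, 6)))
  frac <- compositionFractions(cells)
  expect_equal(unname(frac["s1", c("X", "Y")]), c(0.4, 0.6))

  single <- data.frame(sample_id = c("s1", "s2"), cell_type = "only")
  expect_equal(unname(compositionFractions(single)[, "only"]), c(1, 1))

  # brute-force oracle on a random table
  set.seed(4)
  cells <- data.frame(sample_id = sample(c("s1", "s2"), 200, TRUE),
                      cell_type = sample(letters[1:4], 200, TRUE))
  frac <- compositionFractions(cells)
  for (s in c("s1", "s2")) {
    expect_equal(sum(frac[s, ]), 1, tolerance = 1e-9)
    for (ct in letters[1:4])
      expect_equal(frac[s, ct],
                   sum(cells$sample_id == s & cells$cell_type == ct) /
                     sum(cells$sample_id == s))
  }

  # an empty sample (unused factor level) is an error
  bad <- data.frame(sample_id = factor("s1", levels = c("s1", "s2")),
                    cell_type = "X")
  expect_error(compositionFractions(bad), "empty sample")
})

test_that("composition log2 fold changes recover the planted shift scenario", {
  frac <- rbind(WT_r1 = c(0.10, 0.90), WT_r2 = c(0.10, 0.90),
                KO_r1 = c(0.30, 0.70), KO_r2 = c(0.30, 0.70))
  colnames(frac) <- c("grow", "rest")
  gt <- setNames(c("WT", "WT", "KO", "KO"), rownames(frac))
  out <- compositionLog2FC(frac, gt, reference = "WT")
  grow <- out[out$cell_type == "grow", ]
  expect_equal(grow$mean_log2fc, log2(3), tolerance = 1e-4)
  expect_true(grow$flagged)

  # small shifts are not flagged at the 0.5 reporting rule
  frac2 <- rbind(WT = c(0.10, 0.90), KO = c(0.12, 0.88))
  colnames(frac2) <- c("a", "b")
  out2 <- compositionLog2FC(frac2, setNames(c("WT", "KO"), rownames(frac2)))
  expect_equal(out2$mean_log2fc[out2$cell_type == "a"], log2(0.12 / 0.1),
               tolerance = 1e-4)
  expect_false(out2$flagged[out2$cell_type == "a"])

  # identical composition -> all zero, none flagged
  frac3 <- rbind(WT = c(0.5, 0.5), KO = c(0.5, 0.5))
  colnames(frac3) <- c("a", "b")
  out3 <- compositionLog2FC(frac3, setNames(c("WT", "KO"), rownames(frac3)))
  expect_true(all(out3$mean_log2fc == 0) && !any(out3$flagged))
})

test_that("swapping reference and test negates paired log2 fold changes", {
  set.seed(9)
  frac <- matrix(runif(8, 0.1, 0.5), nrow = 4)
  frac <- sweep(frac, 1, rowSums(frac), "/")
  dimnames(frac) <- list(c("WT_r1", "WT_r2", "KO_r1", "KO_r2"),
                         c("a", "b"))
  gt <- setNames(c("WT", "WT", "KO", "KO"), rownames(frac))
  ab <- compositionLog2FC(frac, gt, reference = "WT", perPair = TRUE)
  ba <- compositionLog2FC(frac, gt, reference = "KO", perPair = TRUE)
  expect_equal(ab$mean_log2fc, -ba$mean_log2fc, tolerance = 1e-12)
})

test_that("expressed-gene counts use a strict threshold", {
  norm <- matrix(c(0.05, 0.1, 0.2), nrow = 3)
  expect_equal(unname(genesPerCell(norm)), 1L)
  expect_equal(unname(genesPerCell(matrix(0, nrow = 5))), 0L)

  set.seed(6)
  r <- matrix(rexp(40 * 15, rate = 5), nrow = 40)
  expect_equal(unname(genesPerCell(r)),
               vapply(seq_len(15), function(j) sum(r[, j] > 0.1),
                      integer(1)))
})

test_that("per-cell TRA fraction counts TRAs among expressed genes", {
  norm <- matrix(1, nrow = 10, ncol = 2,
                 dimnames = list(sprintf("g%02d", 1:10), c("c1", "c2")))
  tra <- sprintf("g%02d", 1:4)
  frac <- traFractionPerCell(norm, tra)
  expect_equal(as.vector(frac), c(0.4, 0.4))

  expect_equal(as.vector(traFractionPerCell(norm, character())), c(0, 0))

  # no expressed genes -> 0 with a flag
  zero <- matrix(0, nrow = 10, ncol = 1,
                 dimnames = list(rownames(norm), "dead"))
  fz <- traFractionPerCell(zero, tra)
  expect_equal(as.vector(fz), 0)
  expect_true(attr(fz, "no_expressed")[["dead"]])

  # permutation invariance of gene order
  perm <- sample(10)
  expect_equal(as.vector(traFractionPerCell(norm[perm, ], tra)),
               as.vector(frac))

  # calls covering only part of the universe warn
  calls <- S4Vectors::DataFrame(gene = sprintf("g%02d", 1:5),
                                is_tra = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_warning(traFractionPerCell(norm, calls), "not covered")
})

test_that("cells expressing only restricted genes have TRA fraction near 1", {
  d <- atlasDesign(nCellTypes = 6, nCellsPerType = 120, nGenes = 600,
                   breadth = c(rep(1L, 100), rep(6L, 500)),
                   onMean = 5, offMean = 0.02, dispersion = 2, seed = 17)
  sce <- normalizeCells(simulateAtlas(d))
  res <- scoreTRA(sce, "cell_type", tauStar = 0.85)
  truthTra <- rownames(sce)[rowData(sce)$is_tra]
  norm <- assay(sce, "normcounts")
  onlyTra <- norm
  onlyTra[!rownames(norm) %in% truthTra, ] <- 0
  frac <- traFractionPerCell(onlyTra, res$calls)
  keep <- !attr(frac, "no_expressed")
  expect_gte(mean(frac[keep]), 0.95)
})

test_that("mean log expression sits on the diagonal for identical groups", {
  norm <- matrix(rexp(30 * 20), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  both <- cbind(norm, norm)
  gt <- rep(c("WT", "KO"), each = 20)
  out <- meanLogExpression(both, gt)
  expect_equal(out$WT, out$KO, tolerance = 1e-12)

  # analytic single-gene case: values e-1 everywhere -> mean log = 1
  one <- matrix(exp(1) - 1, nrow = 1, ncol = 10)
  o <- meanLogExpression(one, rep(c("WT", "KO"), each = 5))
  expect_equal(o$WT, 1)

  expect_error(meanLogExpression(norm, rep("WT", 20), subset = rep(FALSE, 20)))

  # planted silenced genes fall below the diagonal in the KO column
  silenced <- both
  silenced[1:5, 21:40] <- 0
  o2 <- meanLogExpression(silenced, gt)
  expect_true(all(o2$KO[1:5] < o2$WT[1:5]))
})
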