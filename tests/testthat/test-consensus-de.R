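cellTable <- function(counts) {
  # counts: named list sample -> named vector cell_type -> n
  do.call(rbind, lapply(names(counts), function(s) {
    tab <- counts[[s]]
    data.frame(sample_id = s,
               cell_type = rep(names(tab), tab))
  }))
}

test_that("cell-type eligibility uses an inclusive 30-cell boundary", {
  cells <- cellTable(list(s1 = c(a = 30, b = 29, c = 100),
                          s2 = c(a = 45, b = 80, c = 100)))
  expect_setequal(eligibleCellTypes(cells, minCells = 30), c("a", "c"))

  # brute-force oracle on a random table
  set.seed(2)
  cells <- data.frame(
    sample_id = sample(c("s1", "s2", "s3"), 400, replace = TRUE),
    cell_type = sample(letters[1:5], 400, replace = TRUE))
  got <- eligibleCellTypes(cells, minCells = 25)
  oracle <- Filter(function(ct) {
    all(vapply(c("s1", "s2", "s3"), function(s)
      sum(cells$sample_id == s & cells$cell_type == ct) >= 25,
      logical(1)))
  }, letters[1:5])
  expect_setequal(got, oracle)
})

test_that("gene statistics behave at their degenerate limits", {
  norm <- matrix(runif(20 * 40, 0, 5), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  norm[1, ] <- 0     # all-zero gene
  idx <- 1:20
  st <- estimateGeneStats(norm, idx, idx, nBoot = 50, seed = 1)
  expect_true(all(st$lfc_mean == 0))      # identical groups
  expect_equal(unname(st$frac_nonzero_A[1]), 0)
  expect_equal(unname(st$lfc_mean[1]), 0)
  expect_error(estimateGeneStats(norm, integer(), idx), "nonempty")

  # determinism for a fixed seed
  a <- estimateGeneStats(norm, 1:20, 21:40, nBoot = 50, seed = 9)
  b <- estimateGeneStats(norm, 1:20, 21:40, nBoot = 50, seed = 9)
  expect_identical(a, b)
})

test_that("a planted four-fold shift is estimated with strong evidence", {
  set.seed(7)
  nPlanted <- 40
  A <- matrix(rpois(nPlanted * 500, 8), nrow = nPlanted)
  B <- matrix(rpois(nPlanted * 500, 2), nrow = nPlanted)
  norm <- cbind(A, B)
  rownames(norm) <- sprintf("g%02d", seq_len(nPlanted))
  st <- estimateGeneStats(norm, seq_len(500), 500 + seq_len(500),
                          nBoot = 500, seed = 3)
  ok <- abs(st$lfc_mean - 2) < 0.3 & st$bayes_factor > 2.5
  expect_gte(mean(ok), 0.95)
})

test_that("DE filter applies strict/inclusive boundaries as stated", {
  stats <- S4Vectors::DataFrame(
    gene = c("bfBoundary", "clean", "fracBoundary", "peakBoundary"),
    bayes_factor = c(2.5, 3.0, 4, 4),
    lfc_mean = c(2, 1.5, 2, 2),
    frac_nonzero_A = c(0.5, 0.5, 0.05, 0.5),
    frac_nonzero_B = c(0.5, 0.5, 0.01, 0.5),
    peak_expr = c(2, 2, 2, 0.5))
  out <- applyDEFilter(stats, deThresholds("genotype"))
  # BF exactly 2.5 fails (strict); frac exactly 5% passes (inclusive);
  # peak exactly 0.5 fails (strict)
  expect_setequal(out$gene, c("clean", "fracBoundary"))
  expect_identical(out$direction, c("up", "up"))

  noPeak <- stats[, setdiff(colnames(stats), "peak_expr")]
  expect_error(applyDEFilter(noPeak, deThresholds("genotype")),
               "peak_expr")
  expect_silent(applyDEFilter(noPeak, deThresholds("marker")))
})

test_that("the detection-fraction rule can anchor on either group", {
  stats <- S4Vectors::DataFrame(
    gene = "silencedInA", bayes_factor = 4, lfc_mean = -2,
    frac_nonzero_A = 0.01, frac_nonzero_B = 0.6, peak_expr = 2)
  expect_equal(nrow(applyDEFilter(stats, deThresholds("genotype"))), 1)
  expect_equal(nrow(applyDEFilter(
    stats, deThresholds("genotype", fracRule = "groupA"))), 0)
})

test_that("random toy tables match brute-force threshold enumeration", {
  set.seed(11)
  for (variant in c("genotype", "marker", "mimetic")) {
    t <- deThresholds(variant)
    df <- data.frame(
      gene = sprintf("g%03d", 1:200),
      bayes_factor = runif(200, 0, 6),
      lfc_mean = rnorm(200, sd = 1.5),
      frac_nonzero_A = runif(200),
      frac_nonzero_B = runif(200),
      peak_expr = rexp(200))
    got <- applyDEFilter(df, t)
    oracle <- bruteDEPass(df, t@bfMin, t@lfcAbsMin, t@fracMin, t@peakMin,
                          t@fracRule)
    expect_identical(got$gene, df$gene[oracle])
  }
})

test_that("raising any threshold never enlarges the passing set", {
  set.seed(12)
  df <- data.frame(
    gene = sprintf("g%03d", 1:300),
    bayes_factor = runif(300, 0, 6), lfc_mean = rnorm(300, sd = 1.5),
    frac_nonzero_A = runif(300), frac_nonzero_B = runif(300),
    peak_expr = rexp(300))
  base <- applyDEFilter(df, deThresholds("genotype"))$gene
  for (arg in list(list(bfMin = 4), list(lfcAbsMin = 1.5),
                   list(fracMin = 0.3), list(peakMin = 1.5))) {
    t <- do.call(deThresholds, c(list("genotype"), arg))
    expect_true(all(applyDEFilter(df, t)$gene %in% base))
  }
})

callSet <- function(gene, cell_type, direction, lfc = NULL) {
  S4Vectors::DataFrame(
    gene = gene, cell_type = cell_type, direction = direction,
    lfc_mean = if (is.null(lfc)) ifelse(direction == "up", 2, -2) else lfc,
    bayes_factor = 4)
}

test_that("consensus keeps replicated, batch-free, direction-consistent calls", {
  r1 <- callSet(c("keep", "flip", "batchy", "r1only"), "t",
                c("up", "up", "down", "up"))
  r2 <- callSet(c("keep", "flip", "batchy"), "t", c("up", "down", "down"))
  batch <- callSet("batchy", "t", "down")
  out <- consensusAcrossReplicates(list(r1, r2), list(batch))
  expect_identical(out$gene, "keep")
  expect_identical(out$direction, "up")
  expect_identical(out$regulation, "repressed")   # higher in KO

  # absent batch sets: batchy survives intersection
  out2 <- consensusAcrossReplicates(list(r1, r2), list())
  expect_setequal(out2$gene, c("keep", "batchy"))
  expect_identical(out2$regulation[out2$gene == "batchy"], "induced")

  expect_error(consensusAcrossReplicates(list()), "at least one")
})

test_that("batch matching is per gene and cell type", {
  r1 <- callSet("g", c("t1", "t2"), c("up", "up"))
  r2 <- callSet("g", c("t1", "t2"), c("up", "up"))
  batch <- callSet("g", "t2", "up")
  out <- consensusAcrossReplicates(list(r1, r2), list(batch))
  expect_identical(out$cell_type, "t1")
})

test_that("volcano collapse keeps the record with the largest |LFC|", {
  calls <- callSet(c("solo", "multi", "multi", "tie", "tie"),
                   c("a", "a", "b", "a", "b"),
                   c("up", "up", "down", "up", "up"),
                   lfc = c(1.5, 1.2, -2.0, 1.5, 1.5))
  calls$bayes_factor <- c(4, 4, 3, 2, 5)
  out <- collapseForVolcano(calls)
  expect_equal(nrow(out), 3)
  expect_equal(out$lfc_mean[out$gene == "multi"], -2.0)
  expect_equal(out$bayes_factor[out$gene == "multi"], 3)
  expect_equal(out$bayes_factor[out$gene == "tie"], 5)   # tie-break
  expect_equal(out$cell_type[out$gene == "tie"], "b")
})

test_that("direction tallies count up and down calls", {
  empty <- callSet("a", "t", "up")[0, ]
  expect_equal(countDirections(empty), c(up = 0, down = 0))
  calls <- callSet(letters[1:5], "t", c("up", "up", "up", "down", "down"))
  expect_equal(countDirections(calls), c(up = 3, down = 2))
})
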