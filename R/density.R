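#' Normal-reference bandwidth for a 2D product-Gaussian KDE
#'
#' Plug-in rule assuming Gaussian data: per dimension,
#' \eqn{h_d = \sigma_d (4 / ((d + 2) m))^{1/(d+4)}} with \eqn{d = 2}
#' dimensions and \eqn{m} observations, i.e. \eqn{h_d = \sigma_d m^{-1/6}}.
#'
#' @param coords m x 2 matrix of coordinates.
#' @return Length-2 vector of bandwidths.
#' @export
normalReferenceBandwidth <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  m <- nrow(coords)
  d <- 2
  sds <- apply(coords, 2L, sd)
  if (m < 2L) sds <- pmax(sds, 1, na.rm = TRUE)
  if (any(sds == 0))
    stop("zero variance in an embedding dimension; jitter the ",
         "coordinates before density estimation")
  sds * (4 / ((d + 2) * m))^(1 / (d + 4))
}

#' Fit a genotype-conditional 2D Gaussian KDE
#'
#' Product-Gaussian kernel density estimate over embedding coordinates
#' with the normal-reference bandwidth (or an explicit one). The estimate
#' is a conditional density: it integrates to 1, so two genotypes' fits
#' compare relative composition over the embedding, not cell numbers.
#'
#' @param coords m x 2 coordinate matrix (cells of one genotype).
#' @param bandwidth optional explicit length-2 bandwidth; default
#'   [normalReferenceBandwidth()].
#' @return A [GaussianKDE2D-class].
#' @export
gaussianKDE2D <- function(coords, bandwidth = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L)
  if (is.null(bandwidth)) bandwidth <- normalReferenceBandwidth(coords)
  new("GaussianKDE2D", points = coords, bandwidth = as.numeric(bandwidth))
}

#' Evaluate a fitted KDE (log density)
#'
#' @param kde a [GaussianKDE2D-class].
#' @param at n x 2 matrix of evaluation points.
#' @param log return log density (default TRUE).
#' @param chunkSize evaluation points per block, bounding memory for large
#'   inputs.
#' @return Numeric vector of (log) densities; strictly positive densities
#'   are guaranteed by the Gaussian kernel, so log values are finite.
#' @export
kdeLogDensity <- function(kde, at, log = TRUE, chunkSize = 1000L) {
  stopifnot(is(kde, "GaussianKDE2D"))
  at <- as.matrix(at)
  stopifnot(ncol(at) == 2L)
  pts <- kde@points; h <- kde@bandwidth
  m <- nrow(pts)
  normConst <- log(2 * pi) + log(h[1L]) + log(h[2L]) + log(m)
  out <- numeric(nrow(at))
  for (start in seq(1L, nrow(at), by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, nrow(at))
    d1 <- outer(at[idx, 1L], pts[, 1L], "-") / h[1L]
    d2 <- outer(at[idx, 2L], pts[, 2L], "-") / h[2L]
    expo <- -0.5 * (d1 * d1 + d2 * d2)
    # log-sum-exp across training points
    mx <- apply(expo, 1L, max)
    out[idx] <- mx + log(rowSums(exp(expo - mx))) - normConst
  }
  if (log) out else exp(out)
}

#' Per-cell log ratio of genotype-conditional densities
#'
#' The differential-abundance statistic behind per-cell density plots: at
#' every cell's embedding coordinates, the natural-log ratio of the test
#' genotype's conditional kernel density to the reference genotype's.
#' Positive values mark regions relatively enriched for test (KO) cells,
#' negative values regions enriched for reference (WT) cells, and values
#' near 0 regions where both genotypes are equally dense.
#'
#' @param x a SingleCellExperiment carrying a 2D \code{reducedDim} and a
#'   genotype column, or an n x 2 coordinate matrix.
#' @param genotype per-cell genotype labels (ignored for a
#'   SingleCellExperiment, where the colData column named by
#'   \code{genotypeCol} is used).
#' @param reference,test genotype labels contrasted as log(f_test /
#'   f_reference).
#' @param bandwidth \code{NULL} for the normal-reference rule, or a
#'   length-2 numeric used for both genotypes.
#' @param minCells minimum cells required per genotype (default 50).
#' @param genotypeCol,dimred colData column / reducedDim name for the
#'   SingleCellExperiment interface.
#' @return A [S4Vectors::DataFrame] with one row per cell of \code{x}
#'   (all genotypes) and columns \code{cell}, \code{genotype},
#'   \code{log_ratio}; the per-genotype bandwidths are in
#'   \code{metadata()$bandwidths}.
#' @export
logDensityRatio <- function(x, genotype = NULL, reference = "WT",
                            test = "KO", bandwidth = NULL, minCells = 50L,
                            genotypeCol = "genotype", dimred = "UMAP") {
  if (is(x, "SingleCellExperiment")) {
    coords <- SingleCellExperiment::reducedDim(x, dimred)
    genotype <- colData(x)[[genotypeCol]]
  } else coords <- as.matrix(x)
  stopifnot(ncol(coords) == 2L, length(genotype) == nrow(coords))
  for (g in c(reference, test)) {
    if (!g %in% genotype)
      stop("unknown genotype label '", g, "'")
    if (sum(genotype == g) < minCells)
      stop("genotype '", g, "' has fewer than ", minCells, " cells")
  }
  kdeRef <- gaussianKDE2D(coords[genotype == reference, , drop = FALSE],
                          bandwidth)
  kdeTest <- gaussianKDE2D(coords[genotype == test, , drop = FALSE],
                           bandwidth)
  lr <- kdeLogDensity(kdeTest, coords) - kdeLogDensity(kdeRef, coords)
  out <- DataFrame(
    cell = if (!is.null(rownames(coords))) rownames(coords)
           else seq_len(nrow(coords)),
    genotype = genotype, log_ratio = lr)
  S4Vectors::metadata(out) <- list(
    reference = reference, test = test,
    bandwidths = list(reference = kdeRef@bandwidth,
                      test = kdeTest@bandwidth))
  out
}

#' Diagnostic differential-density scatter
#'
#' Cells coloured by log density ratio on a symmetric diverging scale
#' (red = enriched in test genotype, blue = enriched in reference).
#' Requires ggplot2.
#'
#' @param coords n x 2 coordinates for the plotted cells.
#' @param logRatio per-cell log density ratio (from [logDensityRatio()]).
#' @return A ggplot object.
#' @export
plotDensityRatio <- function(coords, logRatio) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(x = coords[, 1L], y = coords[, 2L], lr = logRatio)
  lim <- max(abs(df$lr))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = lr)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90",
                                    high = "red", limits = c(-lim, lim)) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "log ratio") +
    ggplot2::theme_minimal()
}
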