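#' Mean expression profile per group
#'
#' Averages linear normalised expression over cells within each
#' tissue/cell-type annotation, the input to specificity scoring.
#'
#' @param x a SingleCellExperiment with a \code{normcounts} assay, or a
#'   genes x cells matrix of linear normalised expression.
#' @param labels per-cell group annotation; for a SingleCellExperiment the
#'   name of a colData column (default \code{"cell_type"}) or a vector.
#' @param assayName assay holding linear normalised expression.
#' @return A genes x groups matrix of mean expression. Empty groups are
#'   dropped with a warning.
#' @export
groupMeanProfile <- function(x, labels = "cell_type",
                             assayName = "normcounts") {
  norm <- .normOf(x, assayName)
  if (is(x, "SummarizedExperiment") && is.character(labels) &&
      length(labels) == 1L) {
    labels <- colData(x)[[labels]]
    if (is.null(labels)) stop("colData column with group labels not found")
  }
  stopifnot(length(labels) == ncol(norm))
  if (anyNA(labels)) stop("every cell must be labelled")
  labels <- droplevels(as.factor(labels))
  ind <- matrix(0, nrow = ncol(norm), ncol = nlevels(labels),
                dimnames = list(NULL, levels(labels)))
  ind[cbind(seq_along(labels), as.integer(labels))] <- 1
  sums <- norm %*% ind
  n <- as.vector(table(labels))
  profile <- sweep(as.matrix(sums), 2L, n, "/")
  rownames(profile) <- rownames(norm)
  profile
}

#' Squared-probability transform of an expression profile
#'
#' Squares each gene's mean-expression vector and rescales it to sum to 1,
#' yielding the probability distribution on which both the Shannon entropy
#' and the Tau index are computed. All-zero genes cannot be transformed
#' (0/0) and are returned as \code{NA} rows; they are excluded from
#' calibration and classification downstream.
#'
#' @param profile genes x groups matrix of mean expression (or a single
#'   gene's vector).
#' @return Matrix (or vector) of per-gene probability distributions.
#' @examples
#' squaredProbability(c(1, 2, 3))   # (1, 4, 9)/14
#' @export
squaredProbability <- function(profile) {
  if (is.null(dim(profile))) {
    sq <- profile^2
    tot <- sum(sq)
    return(if (tot == 0) rep(NA_real_, length(sq)) else sq / tot)
  }
  sq <- profile^2
  tot <- rowSums(sq)
  p <- sq / tot
  p[tot == 0, ] <- NA_real_
  p
}

.entropyBits <- function(p) {
  terms <- ifelse(p > 0, p * log2(p), 0)
  -sum(terms)
}

#' Shannon entropy and entropy score of a probability vector
#'
#' Computes \eqn{H = -\sum_i p_i \log_2 p_i} (with \eqn{0 \log 0 = 0}) and
#' the normalised entropy score \eqn{1 - H / \log_2 n}, which runs from 0
#' (equal expression in all groups) to 1 (expression confined to a single
#' group).
#'
#' @param p probability vector over \code{n >= 2} groups.
#' @return Named list with \code{H} (bits) and \code{score}.
#' @examples
#' entropyScore(c(0.5, 0.5, 0, 0))   # H = 1 bit, score = 0.5
#' @export
entropyScore <- function(p) {
  n <- length(p)
  if (n < 2L) stop("entropy score needs at least 2 groups")
  stopifnot(all(p >= -1e-12), abs(sum(p) - 1) < 1e-6)
  H <- .entropyBits(p)
  list(H = H, score = 1 - H / log2(n))
}

#' Tau specificity index
#'
#' The standard Tau index on a nonnegative profile: with
#' \eqn{\hat x_i = x_i / \max_j x_j},
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (n - 1)}; 0 for a uniform profile,
#' 1 when a single group carries all expression.
#'
#' @param p nonnegative vector (here: the squared-probability
#'   distribution, but any profile works).
#' @return Tau in [0, 1].
#' @examples
#' tauIndex(c(0.5, 0.25, 0.25))   # 0.5
#' @export
tauIndex <- function(p) {
  n <- length(p)
  if (n < 2L) stop("tau needs at least 2 groups")
  xhat <- p / max(p)
  sum(1 - xhat) / (n - 1L)
}

#' Score every gene's expression restriction
#'
#' Applies the squared-probability transform to a group mean-expression
#' profile and computes, per gene, the Shannon entropy (bits), the
#' normalised entropy score, and the Tau index — both statistics on the
#' transformed probability distribution. All-zero genes are flagged
#' unscoreable (\code{scoreable = FALSE}, scores \code{NA}).
#'
#' @param profile genes x groups matrix of mean normalised expression
#'   (from [groupMeanProfile()]), \code{n >= 2} groups.
#' @return A [S4Vectors::DataFrame] with columns \code{gene}, \code{tau},
#'   \code{H_bits}, \code{entropy_score}, \code{n_groups},
#'   \code{scoreable}.
#' @export
scoreSpecificity <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) >= 2L)
  if (any(profile < 0)) stop("expression profile must be nonnegative")
  n <- ncol(profile)
  p <- squaredProbability(profile)
  scoreable <- !is.na(p[, 1L])
  H <- rep(NA_real_, nrow(profile))
  tau <- rep(NA_real_, nrow(profile))
  for (g in which(scoreable)) {
    H[g] <- .entropyBits(p[g, ])
    tau[g] <- tauIndex(p[g, ])
  }
  DataFrame(
    gene = if (!is.null(rownames(profile))) rownames(profile)
           else sprintf("gene%05d", seq_len(nrow(profile))),
    tau = tau, H_bits = H,
    entropy_score = 1 - H / log2(n),
    n_groups = n, scoreable = scoreable)
}

#' Calibrate the entropy-score threshold from a Tau threshold
#'
#' Fits the logarithmic model \code{entropy_score = a + b ln(tau)} by least
#' squares over scoreable genes with \code{tau > 0} and evaluates it at the
#' chosen Tau threshold, clamping to [0, 1]. Both thresholds then define
#' TRA classification.
#'
#' @param scores output of [scoreSpecificity()] (needs >= 10 usable genes).
#' @param tauStar the Tau threshold (0.85, 0.9 and 0.95 are the standard
#'   operating points; 0.85 is the default used throughout).
#' @return A [TRACalibration-class].
#' @export
calibrateEntropyThreshold <- function(scores, tauStar = 0.85) {
  use <- scores$scoreable & !is.na(scores$tau) & scores$tau > 0
  if (sum(use) < 10L)
    stop("calibration needs at least 10 genes with tau > 0")
  tau <- scores$tau[use]
  if (diff(range(tau)) < 1e-12)
    stop("degenerate calibration: all tau values are equal")
  fit <- lm(entropy_score ~ log(tau),
            data = data.frame(entropy_score = scores$entropy_score[use],
                              tau = tau))
  a <- unname(coef(fit)[1L]); b <- unname(coef(fit)[2L])
  eStar <- min(max(a + b * log(tauStar), 0), 1)
  new("TRACalibration", tauStar = tauStar, entropyStar = eStar,
      intercept = a, slope = b, nGenes = as.integer(sum(use)))
}

#' Classify genes as tissue-restricted antigens
#'
#' A gene is a TRA when it passes either the Tau threshold or the
#' calibrated entropy-score threshold (inclusive boundaries); genes called
#' by only one metric are retained, as singly-called genes are still
#' largely restricted. Unscoreable genes get \code{NA} calls.
#'
#' @param scores output of [scoreSpecificity()].
#' @param calibration a [TRACalibration-class] from
#'   [calibrateEntropyThreshold()].
#' @return A [S4Vectors::DataFrame] with columns \code{gene},
#'   \code{passed_tau}, \code{passed_entropy}, \code{is_tra}.
#' @export
classifyTRA <- function(scores, calibration) {
  stopifnot(is(calibration, "TRACalibration"))
  passedTau <- scores$tau >= calibration@tauStar
  passedEntropy <- scores$entropy_score >= calibration@entropyStar
  DataFrame(gene = scores$gene,
            passed_tau = passedTau,
            passed_entropy = passedEntropy,
            is_tra = passedTau | passedEntropy)
}

#' One-call TRA scoring pipeline
#'
#' Convenience wrapper: group mean profile, specificity scores, threshold
#' calibration and classification in one step.
#'
#' @inheritParams groupMeanProfile
#' @inheritParams calibrateEntropyThreshold
#' @return List with \code{scores}, \code{calibration}, \code{calls}.
#' @export
scoreTRA <- function(x, labels = "cell_type", tauStar = 0.85,
                     assayName = "normcounts") {
  profile <- groupMeanProfile(x, labels, assayName)
  scores <- scoreSpecificity(profile)
  calibration <- calibrateEntropyThreshold(scores, tauStar)
  calls <- classifyTRA(scores, calibration)
  list(scores = scores, calibration = calibration, calls = calls)
}
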