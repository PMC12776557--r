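# mTECtools

Tools for single-cell analysis of medullary thymic epithelial cells
(mTECs) and the transcription-factor programs — Aire, Fezf2 — that drive
promiscuous gene expression. mTECs present peripheral self-antigens to
developing T cells; the genes involved, tissue-restricted antigens
(TRAs), are expressed in only one or a few peripheral cell types, and
asking *which* genes are TRAs, *where* a knockout shifts the mTEC
compartment, and *which* gene programs a factor induces or represses are
the recurring computational problems this package solves. It is aimed at
computational immunologists working with `SingleCellExperiment` count
data.

## What it computes

**TRA scoring.** From a genes × groups profile of mean normalised
expression, each gene's profile is squared and rescaled to a probability
vector *p*; restriction is scored by the entropy score
1 − H(g)/log₂ n (H the Shannon entropy of *p* in bits, n the number of
groups) and the Tau index τ = Σᵢ(1 − x̂ᵢ)/(n − 1), x̂ᵢ = pᵢ/maxⱼ pⱼ. Both
run from 0 (ubiquitous) to 1 (single-group). A least-squares fit of
entropy score = a + b·ln τ converts a chosen Tau threshold (0.85/0.9/0.95)
into an entropy threshold, and a gene is a TRA when it passes either.

**Differential abundance.** Per genotype, a product-Gaussian KDE over the
2D embedding with the normal-reference bandwidth
h_d = σ_d·(4/((d+2)m))^{1/(d+4)}; the per-cell statistic is
ln f_KO(x)/f_WT(x) — positive where KO cells are relatively denser,
negative where WT dominates.

**Consensus differential expression.** Per cell type (≥ 30 cells in every
sample), per-gene Bayes factors, mean log2 fold changes, detection
fractions and peak (99th-percentile) expression feed threshold filters
(e.g. BF > 2.5, |log2 FC| > 1, detection ≥ 5%, peak > 0.5); calls must
replicate across KO-vs-WT contrasts with consistent direction, and
anything also called in WT-vs-WT / KO-vs-KO batch controls is removed.

**QC, composition, diversity.** The standard filter cascade (doublet
score > 0.2, mito > 5%, UMI and gene-count windows), library-size
normalisation to 10,000 counts, per-sample cell-type composition with
mean log2 fold changes against the WT mean, genes-per-cell and
TRA-fraction-per-cell metrics.

**Synthetic data.** Negative-binomial generators with planted TRAs,
regulated programs, batch genes, composition shifts, doublets and damaged
cells, so every procedure is testable against known ground truth.

## Worked example

```r
library(mTECtools)
library(SummarizedExperiment)

design <- atlasDesign(nCellTypes = 10, nCellsPerType = 100,
                      nGenes = 1000, seed = 1)
atlas  <- normalizeCells(simulateAtlas(design))
res    <- scoreTRA(atlas, labels = "cell_type", tauStar = 0.85)
res$calibration
#> TRACalibration: tau* = 0.85 -> entropy* = 0.675821  [E = 0.7544 + 0.4837 ln(tau), n = 1000]
table(truth = rowData(atlas)$is_tra, called = res$calls$is_tra)
#>        called
#> truth   FALSE TRUE
#>   FALSE   800    0
#>   TRUE      0  200
head(as.data.frame(res$scores), 3)
#>        gene       tau     H_bits entropy_score n_groups scoreable
#> 1 gene00001 0.9997139 0.03356841     0.9898949       10      TRUE
#> 2 gene00002 0.9992700 0.07525465     0.9773461       10      TRUE
#> 3 gene00003 0.9994632 0.05819778     0.9824807       10      TRUE
```

The simulated atlas plants 200 restricted genes (breadth 1–2 of 10 cell
types) among 800 broadly expressed ones. Calibration maps the Tau
threshold 0.85 to an entropy-score threshold of 0.676 on this atlas, and
the union classification recovers the planted TRA set exactly — the first
three genes, planted as breadth-1, score τ ≈ 0.999 and entropy score
≈ 0.98.

For the experiment side, `simulateTECExperiment()` → `qcFilter()` →
`normalizeCells()` → `geneStatsByCellType()` → `applyDEFilter()` →
`consensusAcrossReplicates()` runs the full consensus DE pipeline, and
`logDensityRatio()` / `compositionLog2FC()` quantify abundance shifts;
see the methods vignette (`vignettes/mTECtools-methods.Rmd`) for the
statistical details and design rationale.

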