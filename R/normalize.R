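#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors for library-composition normalization.
#' The reference sample is the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile fraction; per sample, M (log2
#' relative abundance vs the reference) and A (mean log abundance) are
#' computed over genes with nonzero counts in both, the top/bottom
#' `trimM` of M and `trimA` of A are excluded, and the factor is 2 to the
#' precision-weighted mean of the remaining M values (weights = inverse
#' binomial asymptotic variance of M), rescaled so the factors have
#' geometric mean 1. Computation is delegated to [edgeR::calcNormFactors()],
#' whose published algorithm this is.
#'
#' Genes with zero counts in every sample are dropped first: they carry no
#' information and break the M/A computation.
#'
#' @param counts gene x sample count matrix with >= 2 columns, each with
#'   positive library size.
#' @param trimM,trimA trim fractions for M (default 0.30) and A (default
#'   0.05), the method's published defaults.
#' @return named per-sample factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stopInput("TMM needs >= 2 samples")
  if (any(colSums(counts) <= 0))
    stopInput("sample '%s' has zero library size",
              colnames(counts)[which(colSums(counts) <= 0)[1]])
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trimM, sumTrim = trimA)
  if (any(!is.finite(f) | f <= 0)) {
    bad <- colnames(counts)[which(!is.finite(f) | f <= 0)[1]]
    stopInput("sample '%s' shares no nonzero gene with the reference", bad)
  }
  names(f) <- colnames(counts)
  f
}

#' log2 counts-per-million
#'
#' The logCPM transform used ahead of linear modelling of counts:
#' `log2((count + 0.5) / (libSize * factor + 1) * 1e6)` with the
#' TMM-scaled effective library size.
#'
#' @param counts gene x sample count matrix.
#' @param normFactors per-sample TMM factors (default all 1).
#' @param libSizes per-sample library sizes (default column sums).
#' @return gene x sample logCPM matrix.
#' @export
logCpm <- function(counts, normFactors = rep(1, ncol(counts)),
                   libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  eff <- libSizes * normFactors + 1
  t(log2(t(counts + 0.5) / eff * 1e6))
}

#' Adjusted RPKM from logCPM and gene model lengths
#'
#' `rpkm = 2^logcpm / (length / 1000)` with length the summed exon length
#' of the gene model. The expression-relevance threshold is the square
#' root of the mean of the resulting matrix over all genes and samples.
#'
#' @param logcpm gene x sample logCPM matrix.
#' @param geneLengthsBp named per-gene lengths in bp covering the rows.
#' @return list with `rpkm` (matrix) and `relevanceThreshold` (scalar).
#' @export
rpkmFromLogcpm <- function(logcpm, geneLengthsBp) {
  logcpm <- as.matrix(logcpm)
  len <- geneLengthsBp[rownames(logcpm)]
  if (any(is.na(len)))
    stopInput("no gene length for '%s'",
              rownames(logcpm)[which(is.na(len))[1]])
  if (any(len <= 0))
    stopInput("non-positive length for gene '%s'",
              names(len)[which(len <= 0)[1]])
  r <- 2^logcpm / (len / 1000)
  list(rpkm = r, relevanceThreshold = sqrt(mean(r)))
}

#' Normalize a coverage table's gene counts
#'
#' Runs the full normalization stage: drops genes with zero counts in all
#' samples, computes TMM factors, logCPM, adjusted RPKM and the relevance
#' threshold, over the whole dataset handed in (all timepoints of a
#' tissue; combine per-timepoint tables first with
#' [combineCoverageTables()]).
#'
#' @param cov a [CoverageTable] (or a bare count matrix plus `design` and
#'   `geneLengthsBp`).
#' @param models a [GeneModels] giving gene lengths; alternatively pass
#'   `geneLengthsBp` directly.
#' @param geneLengthsBp optional named lengths overriding `models`.
#' @param trimM,trimA TMM trim fractions.
#' @return a [NormalizedExpression].
#' @export
normalizeExpression <- function(cov, models = NULL, geneLengthsBp = NULL,
                                trimM = 0.30, trimA = 0.05) {
  if (methods::is(cov, "CoverageTable")) {
    counts <- geneCounts(cov)
    design <- sampleDesign(cov)
  } else stopInput("normalizeExpression expects a CoverageTable")
  if (is.null(geneLengthsBp)) {
    if (is.null(models)) stopInput("need gene models or gene lengths")
    geneLengthsBp <- geneLengths(models)
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  f <- tmmFactors(counts, trimM = trimM, trimA = trimA)
  lib <- colSums(counts)
  lc <- logCpm(counts, normFactors = f, libSizes = lib)
  rk <- rpkmFromLogcpm(lc, geneLengthsBp)
  methods::new("NormalizedExpression", logcpm = lc, rpkm = rk$rpkm,
               normFactors = unname(f) / exp(mean(log(f))),
               libSizes = unname(lib),
               geneLengths = geneLengthsBp[rownames(lc)],
               relevanceThreshold = rk$relevanceThreshold,
               design = design)
}
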