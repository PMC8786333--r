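#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList
NULL

#' GeneModels: representative exon/intron structure per gene
#'
#' Holds one representative transcript model per gene as a
#' [GenomicRanges::GRangesList] of exons (1-based, closed, the Bioconductor
#' convention) together with the derived introns (the gaps between
#' consecutive exons). Strand affects only the labelling of 5'/3' splice
#' sites downstream, never the interval arithmetic.
#'
#' @slot exons GRangesList, one element per gene, exons sorted by start,
#'   non-overlapping.
#' @slot introns GRangesList parallel to `exons`; element i has
#'   `length(exons[[i]]) - 1` ranges, each of width >= 1.
#' @export
setClass("GeneModels", representation(exons = "GRangesList",
                                      introns = "GRangesList"))

setValidity("GeneModels", function(object) {
  ex <- object@exons
  if (length(ex) != length(object@introns))
    return("exons and introns must be parallel")
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("gene ids (names of exons) must be unique and non-NULL")
  if (!identical(names(ex), names(object@introns)))
    return("exons and introns must share gene ids")
  nex <- lengths(ex)
  if (any(nex == 0L))
    return(sprintf("gene '%s' has no exons", names(ex)[which(nex == 0L)[1]]))
  if (!identical(unname(lengths(object@introns)), unname(nex - 1L)))
    return("intron count must be exon count - 1 for every gene")
  us <- unlist(GenomicRanges::start(ex), use.names = FALSE)
  ue <- unlist(GenomicRanges::end(ex), use.names = FALSE)
  grp <- rep.int(seq_along(ex), nex)
  within <- which(diff(grp) == 0L)
  if (length(within)) {
    gap <- us[within + 1L] - ue[within]
    if (any(gap < 2L)) {
      g <- names(ex)[grp[within[which(gap < 2L)[1]]]]
      return(sprintf("exons of '%s' are unsorted, overlapping or book-ended", g))
    }
  }
  TRUE
})

#' CoverageTable: per-sample feature-level read signals
#'
#' The defined stand-in for the output of a feature-level read counter:
#' gene read counts plus mean read depths (reads/bp) over annotated exons
#' and introns, and read counts over splice junctions and exon skips.
#' Feature rows are keyed `gene:index` for exons/introns/skips and
#' `gene:donor:acceptor` (genomic positions of the last exonic base before
#' and the first after the junction) for junctions.
#'
#' @slot geneCounts integer-valued matrix, genes x samples.
#' @slot exonDepth,intronDepth numeric matrices, feature rows x samples,
#'   mean read depth per bp.
#' @slot junctionCounts,skipCounts numeric matrices of read counts.
#' @slot design data.frame with columns sample_id, condition
#'   (treated/control), timepoint, replicate, tissue; rows parallel to the
#'   matrix columns.
#' @export
setClass("CoverageTable", representation(geneCounts = "matrix",
                                         exonDepth = "matrix",
                                         intronDepth = "matrix",
                                         junctionCounts = "matrix",
                                         skipCounts = "matrix",
                                         design = "data.frame"))

setValidity("CoverageTable", function(object) {
  sams <- object@design$sample_id
  if (is.null(sams) || anyDuplicated(sams))
    return("design must have unique sample_id")
  need <- c("sample_id", "condition", "timepoint", "replicate", "tissue")
  if (!all(need %in% colnames(object@design)))
    return(paste("design must have columns:", paste(need, collapse = ", ")))
  if (!all(object@design$condition %in% c("treated", "control")))
    return("condition must be 'treated' or 'control'")
  for (nm in c("geneCounts", "exonDepth", "intronDepth", "junctionCounts",
               "skipCounts")) {
    m <- slot(object, nm)
    if (nrow(m) > 0L || ncol(m) > 0L) {
      if (!identical(colnames(m), sams))
        return(sprintf("%s columns must match design sample_id", nm))
      if (any(!is.finite(m)) || any(m < 0))
        return(sprintf("%s must be finite and non-negative", nm))
    }
  }
  TRUE
})

#' NormalizedExpression: TMM-normalized expression with relevance threshold
#'
#' @slot logcpm gene x sample matrix of log2 counts-per-million.
#' @slot rpkm gene x sample matrix of adjusted RPKM derived from logCPM and
#'   gene model length (summed exon length).
#' @slot normFactors,libSizes per-sample TMM factors (geometric mean 1) and
#'   library sizes.
#' @slot geneLengths per-gene summed exon length in bp.
#' @slot relevanceThreshold square root of the mean of the RPKM matrix;
#'   genes must exceed it to count as relevantly expressed.
#' @slot design sample annotation as in [CoverageTable].
#' @export
setClass("NormalizedExpression", representation(logcpm = "matrix",
                                                rpkm = "matrix",
                                                normFactors = "numeric",
                                                libSizes = "numeric",
                                                geneLengths = "numeric",
                                                relevanceThreshold = "numeric",
                                                design = "data.frame"))

setValidity("NormalizedExpression", function(object) {
  if (any(object@normFactors <= 0)) return("norm factors must be positive")
  gm <- exp(mean(log(object@normFactors)))
  if (abs(gm - 1) > 1e-6) return("norm factors must have geometric mean 1")
  if (any(object@rpkm < 0)) return("rpkm must be non-negative")
  if (!identical(dim(object@logcpm), dim(object@rpkm)))
    return("logcpm and rpkm must be conformable")
  TRUE
})

#' AsEventSet: alternative-splicing events with per-sample ratios
#'
#' One row per candidate event: intron retention (IR, per annotated
#' intron), alternative donor/acceptor (DA, junction matching the
#' annotation on exactly one side) or exon skipping (ES, per skipped
#' annotated exon). `ratios` holds the per-sample event ratio (IR: intron
#' depth over mean flanking-exon depth; DA/ES: event reads over gene
#' reads), NA where the denominator is zero. `signal` holds the raw event
#' signal used for the replicate-presence rule.
#'
#' @slot info data.frame with event_id, gene_id, type, feature.
#' @slot ratios,signal numeric matrices, events x samples.
#' @slot design sample annotation as in [CoverageTable].
#' @export
setClass("AsEventSet", representation(info = "data.frame",
                                      ratios = "matrix",
                                      signal = "matrix",
                                      design = "data.frame"))

setValidity("AsEventSet", function(object) {
  if (nrow(object@info) != nrow(object@ratios) ||
      nrow(object@info) != nrow(object@signal))
    return("info, ratios and signal must have one row per event")
  if (!all(object@info$type %in% c("IR", "DA", "ES")))
    return("event type must be IR, DA or ES")
  if (any(object@ratios < 0, na.rm = TRUE))
    return("ratios must be non-negative where present")
  TRUE
})

#' SyntheticConfig: parameters of the ground-truth data generator
#'
#' Defaults emulate the study design the pipeline targets: 3 treated vs 3
#' control replicates at three timepoints, negative-binomial counts
#' (variance mu + dispersion * mu^2), mean exonic read depth 50x, baseline
#' intron-retention ratio 0.05, junction background rate 0.01 reads per
#' gene read, and injected effect sizes of 4-fold.
#'
#' @slot nGenes number of genes to simulate.
#' @slot intronMean mean intron count per gene (negative-binomially
#'   distributed across genes, size `intronSize`).
#' @slot exonLengthMean,intronLengthMean mean feature lengths in bp.
#' @slot replicates replicates per condition (>= 2).
#' @slot timepoints character vector of timepoint labels.
#' @slot tissue tissue label.
#' @slot baselineDepth mean exonic read depth (reads/bp) across genes.
#' @slot dispersion negative-binomial dispersion alpha.
#' @slot deFraction,deEffect fraction of genes with injected differential
#'   expression per timepoint and their fold-change (direction random).
#' @slot irFraction,irEffect,daFraction,daEffect,esFraction,esEffect
#'   per-timepoint injection fractions and ratio effect sizes of the three
#'   event types.
#' @slot baselineIrRatio control-condition intron/exon depth ratio.
#' @slot junctionBgRate background junction (and skip) reads per gene read.
#' @slot couplingBeta length-3 numeric (beta0 offset, beta1 on centred
#'   intron count, beta2 on centred average splice-site strength) steering
#'   the logistic gene-level propensity of IR injection; c(0,0,0) makes
#'   injection independent of architecture at rate `irFraction`.
#' @slot readLength read length in bp used to convert depths to counts.
#' @slot seed integer seed; fully determines the output.
#' @export
setClass("SyntheticConfig", representation(
  nGenes = "numeric", intronMean = "numeric", intronSize = "numeric",
  exonLengthMean = "numeric", intronLengthMean = "numeric",
  replicates = "numeric", timepoints = "character", tissue = "character",
  baselineDepth = "numeric", dispersion = "numeric",
  deFraction = "numeric", deEffect = "numeric",
  irFraction = "numeric", irEffect = "numeric",
  daFraction = "numeric", daEffect = "numeric",
  esFraction = "numeric", esEffect = "numeric",
  baselineIrRatio = "numeric", junctionBgRate = "numeric",
  couplingBeta = "numeric", readLength = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  fr <- c(object@deFraction, object@irFraction, object@daFraction,
          object@esFraction)
  if (any(fr < 0 | fr > 1)) return("injection fractions must lie in [0,1]")
  ef <- c(object@deEffect, object@irEffect, object@daEffect, object@esEffect)
  if (any(ef <= 1)) return("effect sizes must exceed 1")
  if (object@replicates < 2) return("need >= 2 replicates per condition")
  if (length(object@couplingBeta) != 3L)
    return("couplingBeta must be length 3")
  if (object@nGenes < 1) return("nGenes must be positive")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  if (object@baselineIrRatio <= 0 || object@junctionBgRate <= 0)
    return("baseline ratios must be positive")
  TRUE
})
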