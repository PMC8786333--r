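#' @include AllClasses.R
NULL

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @export
setGeneric("intronCounts", function(x) standardGeneric("intronCounts"))
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))
#' @export
setGeneric("exonDepth", function(x) standardGeneric("exonDepth"))
#' @export
setGeneric("intronDepth", function(x) standardGeneric("intronDepth"))
#' @export
setGeneric("junctionCounts", function(x) standardGeneric("junctionCounts"))
#' @export
setGeneric("skipCounts", function(x) standardGeneric("skipCounts"))
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))
#' @export
setGeneric("logCPM", function(x) standardGeneric("logCPM"))
#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
#' @export
setGeneric("relevanceThreshold", function(x) standardGeneric("relevanceThreshold"))
#' @export
setGeneric("eventInfo", function(x) standardGeneric("eventInfo"))
#' @export
setGeneric("eventRatios", function(x) standardGeneric("eventRatios"))
#' @export
setGeneric("eventSignal", function(x) standardGeneric("eventSignal"))

## --- GeneModels accessors ---------------------------------------------------

#' @describeIn GeneModels-class gene identifiers
#' @param x a GeneModels object
#' @export
setMethod("geneIds", "GeneModels", function(x) names(x@exons))

#' @describeIn GeneModels-class exon ranges per gene (GRangesList)
#' @export
setMethod("exons", "GeneModels", function(x) x@exons)

#' @describeIn GeneModels-class derived intron ranges per gene
#' @export
setMethod("introns", "GeneModels", function(x) x@introns)

#' @describeIn GeneModels-class summed exon length per gene (bp); invariant
#'   under strand
#' @export
setMethod("geneLengths", "GeneModels", function(x) {
  len <- vapply(GenomicRanges::width(x@exons), sum, numeric(1))
  names(len) <- names(x@exons)
  len
})

#' @describeIn GeneModels-class number of introns per gene
#' @export
setMethod("intronCounts", "GeneModels", function(x) {
  n <- lengths(x@introns)
  names(n) <- names(x@introns)
  n
})

setMethod("length", "GeneModels", function(x) length(x@exons))

setMethod("show", "GeneModels", function(object) {
  ic <- intronCounts(object)
  cat("GeneModels with", length(object), "genes;",
      sum(ic), "introns (", sum(ic == 0), "single-exon genes )\n")
})

## --- CoverageTable accessors ------------------------------------------------

#' @describeIn CoverageTable-class gene x sample count matrix
#' @param x a CoverageTable object
#' @export
setMethod("geneCounts", "CoverageTable", function(x) x@geneCounts)
#' @describeIn CoverageTable-class exon mean-depth matrix (rows `gene:index`)
#' @export
setMethod("exonDepth", "CoverageTable", function(x) x@exonDepth)
#' @describeIn CoverageTable-class intron mean-depth matrix
#' @export
setMethod("intronDepth", "CoverageTable", function(x) x@intronDepth)
#' @describeIn CoverageTable-class junction read counts (rows
#'   `gene:donor:acceptor`)
#' @export
setMethod("junctionCounts", "CoverageTable", function(x) x@junctionCounts)
#' @describeIn CoverageTable-class exon-skip read counts (rows `gene:index`)
#' @export
setMethod("skipCounts", "CoverageTable", function(x) x@skipCounts)
#' @describeIn CoverageTable-class sample annotation data.frame
#' @export
setMethod("sampleDesign", "CoverageTable", function(x) x@design)

setMethod("show", "CoverageTable", function(object) {
  cat("CoverageTable:", nrow(object@geneCounts), "genes x",
      ncol(object@geneCounts), "samples;",
      nrow(object@intronDepth), "introns,",
      nrow(object@junctionCounts), "junction keys,",
      nrow(object@skipCounts), "skip keys\n")
  cat("timepoints:", paste(unique(object@design$timepoint), collapse = ", "),
      "\n")
})

## --- NormalizedExpression accessors -----------------------------------------

#' @describeIn NormalizedExpression-class log2 counts-per-million matrix
#' @param x a NormalizedExpression object
#' @export
setMethod("logCPM", "NormalizedExpression", function(x) x@logcpm)
#' @describeIn NormalizedExpression-class adjusted RPKM matrix
#' @export
setMethod("rpkm", "NormalizedExpression", function(x) x@rpkm)
#' @describeIn NormalizedExpression-class per-sample TMM factors
#' @export
setMethod("normFactors", "NormalizedExpression", function(x) x@normFactors)
#' @describeIn NormalizedExpression-class expression-relevance threshold,
#'   sqrt of the mean RPKM over the whole matrix
#' @export
setMethod("relevanceThreshold", "NormalizedExpression",
          function(x) x@relevanceThreshold)
#' @describeIn NormalizedExpression-class sample annotation
#' @export
setMethod("sampleDesign", "NormalizedExpression", function(x) x@design)
#' @describeIn NormalizedExpression-class gene model lengths used for RPKM
#' @export
setMethod("geneLengths", "NormalizedExpression", function(x) x@geneLengths)

setMethod("show", "NormalizedExpression", function(object) {
  cat("NormalizedExpression:", nrow(object@logcpm), "genes x",
      ncol(object@logcpm), "samples\n")
  cat("TMM factors:", paste(sprintf("%.3f", object@normFactors),
                            collapse = " "), "\n")
  cat("relevance threshold (RPKM):",
      sprintf("%.3f", object@relevanceThreshold), "\n")
})

## --- AsEventSet accessors ---------------------------------------------------

#' @describeIn AsEventSet-class event annotation (event_id, gene_id, type,
#'   feature)
#' @param x an AsEventSet object
#' @export
setMethod("eventInfo", "AsEventSet", function(x) x@info)
#' @describeIn AsEventSet-class per-sample event ratios (NA = undefined)
#' @export
setMethod("eventRatios", "AsEventSet", function(x) x@ratios)
#' @describeIn AsEventSet-class raw per-sample event signal
#' @export
setMethod("eventSignal", "AsEventSet", function(x) x@signal)
#' @describeIn AsEventSet-class sample annotation
#' @export
setMethod("sampleDesign", "AsEventSet", function(x) x@design)

setMethod("show", "AsEventSet", function(object) {
  tb <- table(object@info$type)
  cat("AsEventSet with", nrow(object@info), "events (",
      paste(names(tb), as.integer(tb), collapse = ", "), ")\n")
})
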