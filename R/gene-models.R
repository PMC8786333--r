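#' Construct gene models from exon ranges
#'
#' Builds a [GeneModels] object from per-gene exon ranges, sorting exons by
#' start and deriving introns as the gaps between consecutive exons.
#' Overlapping (or book-ended, i.e. zero-length-intron) exons within a gene
#' are an error here; [readGeneModels()] instead drops such genes with a
#' warning.
#'
#' @param exonsByGene a named [GenomicRanges::GRangesList], one element per
#'   gene.
#' @return a [GeneModels] object.
#' @examples
#' gr <- GenomicRanges::GRangesList(
#'   G1 = GenomicRanges::GRanges("Chr1",
#'     IRanges::IRanges(c(101, 301), c(200, 400)), strand = "+"))
#' gm <- geneModels(gr)
#' intronCounts(gm)   # G1: 1
#' @export
geneModels <- function(exonsByGene) {
  if (!methods::is(exonsByGene, "GRangesList"))
    exonsByGene <- GenomicRanges::GRangesList(exonsByGene)
  if (is.null(names(exonsByGene)))
    stopInput("gene models require named exon ranges")
  exonsByGene <- GenomicRanges::sort(exonsByGene)
  ir <- derivedIntrons(exonsByGene, onBad = "error")
  methods::new("GeneModels", exons = exonsByGene, introns = ir$introns)
}

## Introns = per-gene gaps between consecutive exons. onBad controls what
## happens to genes whose exons overlap or touch: "error" stops, "drop"
## removes them (returning the kept names) with a warning per gene.
derivedIntrons <- function(exonsByGene, onBad = c("error", "drop")) {
  onBad <- match.arg(onBad)
  nex <- lengths(exonsByGene)
  us <- unlist(GenomicRanges::start(exonsByGene), use.names = FALSE)
  ue <- unlist(GenomicRanges::end(exonsByGene), use.names = FALSE)
  grp <- rep.int(seq_along(exonsByGene), nex)
  within <- which(diff(grp) == 0L)
  badIdx <- unique(grp[within[us[within + 1L] - ue[within] < 2L]])
  bad <- seq_along(exonsByGene) %in% badIdx
  if (any(bad)) {
    msg <- sprintf("rejecting %d gene model(s) with overlapping or book-ended exons: %s",
                   sum(bad), paste(names(exonsByGene)[bad], collapse = ", "))
    if (onBad == "error") stopInput("%s", msg)
    warning(msg, call. = FALSE)
    exonsByGene <- exonsByGene[!bad]
  }
  introns <- GenomicRanges::psetdiff(
    unlist(range(exonsByGene), use.names = FALSE), exonsByGene)
  names(introns) <- names(exonsByGene)
  list(exons = exonsByGene, introns = introns)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features and keeps one representative transcript
#' per gene: the mRNA whose ID sorts first. Exons are merged per chosen
#' transcript and introns derived. GFF3 coordinates (1-based, closed) are
#' kept as-is in the Bioconductor range containers. Genes whose
#' representative transcript has overlapping exons are rejected with a
#' warning naming the gene; unparseable input is a hard error (from the
#' GFF3 parser, with position information).
#'
#' @param path path to a GFF3 file.
#' @return a [GeneModels] object.
#' @seealso [writeGeneModels()] for the inverse; the round trip is the
#'   identity on coordinates and strand.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gr$type))
  mrna <- gr[type %in% c("mrna", "transcript")]
  ex <- gr[type == "exon"]
  if (length(mrna) == 0L || length(ex) == 0L)
    stopInput("GFF3 '%s' has no mRNA/exon features", path)
  mrnaParent <- vapply(mrna$Parent, function(p) p[1L], character(1))
  ## representative transcript per gene: first mRNA ID alphabetically
  ord <- order(mrnaParent, mrna$ID)
  keep <- ord[!duplicated(mrnaParent[ord])]
  repId <- mrna$ID[keep]
  names(repId) <- mrnaParent[keep]
  exParent <- vapply(ex$Parent, function(p) p[1L], character(1))
  ex <- ex[exParent %in% repId]
  exParent <- exParent[exParent %in% repId]
  geneOfTx <- names(repId)
  names(geneOfTx) <- repId
  geneId <- unname(geneOfTx[exParent])
  S4Vectors::mcols(ex) <- NULL
  grl <- GenomicRanges::split(ex, factor(geneId, levels = sort(unique(geneId))))
  grl <- GenomicRanges::sort(grl)
  fixed <- derivedIntrons(grl, onBad = "drop")
  methods::new("GeneModels", exons = fixed$exons, introns = fixed$introns)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA (one per gene, `<gene>.1`) and exon features, in
#' deterministic order (genes sorted by id). Coordinates and strand
#' round-trip through [readGeneModels()] unchanged.
#'
#' @param models a [GeneModels] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeGeneModels <- function(models, path) {
  ids <- sort(geneIds(models))
  ex <- exons(models)[ids]
  rng <- unlist(range(ex), use.names = FALSE)
  nex <- lengths(ex)
  geneGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rng),
                                   IRanges::ranges(rng),
                                   strand = GenomicRanges::strand(rng))
  geneGr$type <- "gene"; geneGr$ID <- ids; geneGr$Parent <- NA_character_
  txGr <- geneGr
  txGr$type <- "mRNA"; txGr$ID <- paste0(ids, ".1"); txGr$Parent <- ids
  exGr <- unlist(ex, use.names = FALSE)
  S4Vectors::mcols(exGr) <- NULL
  exGr$type <- "exon"; exGr$ID <- NA_character_
  exGr$Parent <- rep(paste0(ids, ".1"), nex)
  all <- c(geneGr, txGr, exGr)
  all$type <- factor(all$type, levels = c("gene", "mRNA", "exon"))
  all <- all[order(match(all$Parent, c(NA, ids)), all$type,
                   GenomicRanges::start(all))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
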