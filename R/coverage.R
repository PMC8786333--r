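#' @importFrom utils read.delim write.table
NULL

featureKey <- function(gene, index) paste(gene, index, sep = ":")

#' Construct a CoverageTable
#'
#' Assembles the per-sample feature signals into a validated
#' [CoverageTable]. All matrices must share column order with
#' `design$sample_id`; missing matrices may be passed as zero-row
#' matrices.
#'
#' @param geneCounts gene x sample read-count matrix.
#' @param exonDepth,intronDepth mean-depth matrices with `gene:index` rows.
#' @param junctionCounts junction count matrix with `gene:donor:acceptor`
#'   rows.
#' @param skipCounts skip count matrix with `gene:index` rows (index = the
#'   skipped exon).
#' @param design sample annotation data.frame (sample_id, condition,
#'   timepoint, replicate, tissue).
#' @return a [CoverageTable].
#' @export
coverageTable <- function(geneCounts, exonDepth, intronDepth,
                          junctionCounts = emptySignal(design),
                          skipCounts = emptySignal(design), design) {
  methods::new("CoverageTable", geneCounts = as.matrix(geneCounts),
               exonDepth = as.matrix(exonDepth),
               intronDepth = as.matrix(intronDepth),
               junctionCounts = as.matrix(junctionCounts),
               skipCounts = as.matrix(skipCounts),
               design = design)
}

emptySignal <- function(design) {
  matrix(numeric(0), nrow = 0, ncol = nrow(design),
         dimnames = list(NULL, design$sample_id))
}

#' Read a feature-level coverage TSV
#'
#' The coverage dialect has five tab-separated columns:
#' `gene_id  feature_type  feature_key  sample_id  value` where
#' `feature_type` is one of gene/exon/intron/junction/skip, `feature_key`
#' is a 1-based integer index for exon/intron/skip, `donor:acceptor`
#' genomic positions for junction, and empty for gene. Cells absent from
#' the file are 0. Exon and intron matrices cover every annotated feature
#' of every gene in `models`; junction and skip rows cover the keys
#' observed in the file.
#'
#' @param path TSV path (with header).
#' @param models a [GeneModels] object used to resolve feature keys.
#' @param design sample annotation; samples in the file must be a subset.
#' @return a [CoverageTable].
#' @export
readCoverageTable <- function(path, models, design) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character",
                                   "character", "numeric"))
  need <- c("gene_id", "feature_type", "feature_key", "sample_id", "value")
  if (!identical(colnames(tab), need))
    stopInput("coverage TSV '%s' must have columns: %s", path,
              paste(need, collapse = ", "))
  if (any(tab$value < 0) || any(!is.finite(tab$value)))
    stopInput("coverage TSV '%s' contains negative or non-finite values", path)
  bad <- !tab$feature_type %in% c("gene", "exon", "intron", "junction", "skip")
  if (any(bad))
    stopInput("unknown feature_type '%s'", tab$feature_type[which(bad)[1]])
  unknownSample <- setdiff(tab$sample_id, design$sample_id)
  if (length(unknownSample))
    stopInput("sample '%s' not in design", unknownSample[1])
  ids <- geneIds(models)
  unknownGene <- setdiff(tab$gene_id, ids)
  if (length(unknownGene))
    stopInput("gene '%s' not in gene models", unknownGene[1])

  sams <- design$sample_id
  nex <- lengths(exons(models))
  nint <- intronCounts(models)

  fill <- function(sub, rows) {
    m <- matrix(0, nrow = length(rows), ncol = length(sams),
                dimnames = list(rows, sams))
    if (nrow(sub)) {
      key <- sub$row
      m[cbind(match(key, rows), match(sub$sample_id, sams))] <- sub$value
    }
    m
  }
  checkIndex <- function(sub, nFeat, what) {
    idx <- suppressWarnings(as.integer(sub$feature_key))
    bad <- is.na(idx) | idx < 1L | idx > nFeat[sub$gene_id]
    if (any(bad)) {
      i <- which(bad)[1]
      stopInput("feature key %s:%s:%s does not resolve against the gene models",
                sub$gene_id[i], what, sub$feature_key[i])
    }
    idx
  }

  g <- tab[tab$feature_type == "gene", ]
  g$row <- g$gene_id
  geneCounts <- fill(g, ids)

  e <- tab[tab$feature_type == "exon", ]
  e$row <- featureKey(e$gene_id, checkIndex(e, nex, "exon"))
  exonRows <- unlist(lapply(ids, function(gid)
    featureKey(gid, seq_len(nex[gid]))), use.names = FALSE)
  exonDepth <- fill(e, exonRows)

  i <- tab[tab$feature_type == "intron", ]
  i$row <- featureKey(i$gene_id, checkIndex(i, nint, "intron"))
  intronRows <- unlist(lapply(ids[nint > 0], function(gid)
    featureKey(gid, seq_len(nint[gid]))), use.names = FALSE)
  intronDepth <- fill(i, intronRows)

  j <- tab[tab$feature_type == "junction", ]
  if (nrow(j)) {
    ok <- grepl("^[0-9]+:[0-9]+$", j$feature_key)
    if (any(!ok))
      stopInput("feature key %s:junction:%s is not donor:acceptor",
                j$gene_id[which(!ok)[1]], j$feature_key[which(!ok)[1]])
  }
  j$row <- if (nrow(j)) featureKey(j$gene_id, j$feature_key) else character(0)
  junctionCounts <- fill(j, sort(unique(j$row)))

  s <- tab[tab$feature_type == "skip", ]
  s$row <- featureKey(s$gene_id, checkIndex(s, nex, "skip"))
  skipCounts <- fill(s, sort(unique(s$row)))

  coverageTable(geneCounts, exonDepth, intronDepth, junctionCounts,
                skipCounts, design = design)
}

#' Write a CoverageTable in the coverage TSV dialect
#'
#' Rows are emitted in deterministic order (feature type, then gene, then
#' key, then sample); zero cells of the dense exon/intron matrices are
#' kept so the round trip through [readCoverageTable()] is exact.
#'
#' @param cov a [CoverageTable].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeCoverageTable <- function(cov, path) {
  long <- function(m, type, splitKey = FALSE) {
    if (nrow(m) == 0L) return(NULL)
    key <- rownames(m)
    gene <- sub(":.*$", "", key)
    feat <- sub("^[^:]+:", "", key)
    if (type == "gene") feat <- ""
    data.frame(gene_id = rep(gene, ncol(m)),
               feature_type = type,
               feature_key = rep(feat, ncol(m)),
               sample_id = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }
  gc <- cov@geneCounts
  rownames(gc) <- paste0(rownames(gc), ":")
  parts <- rbind(long(gc, "gene"), long(cov@exonDepth, "exon"),
                 long(cov@intronDepth, "intron"),
                 long(cov@junctionCounts, "junction"),
                 long(cov@skipCounts, "skip"))
  parts$gene_id <- sub(":$", "", parts$gene_id)
  ord <- order(match(parts$feature_type,
                     c("gene", "exon", "intron", "junction", "skip")),
               parts$gene_id, parts$feature_key, parts$sample_id)
  writeResults(parts[ord, , drop = FALSE], path, sort = FALSE)
}

#' Write a results table deterministically
#'
#' Tab-separated, UTF-8, LF line endings, no quoting, no row names.
#' By default rows are sorted by all columns left to right so that equal
#' inputs serialize byte-identically.
#'
#' @param records a data.frame.
#' @param path output path.
#' @param sort sort rows deterministically before writing.
#' @return invisibly, `path`.
#' @export
writeResults <- function(records, path, sort = TRUE) {
  records <- as.data.frame(records)
  if (sort && nrow(records) > 1L) {
    ord <- do.call(order, unname(as.list(records)))
    records <- records[ord, , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#'
#' @param path TSV path.
#' @return a data.frame with types inferred per column.
#' @export
readResults <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Combine per-timepoint coverage tables into one
#'
#' Binds the sample columns of several [CoverageTable]s that share the
#' same gene models (e.g. one table per timepoint) so that normalization
#' can operate on the whole dataset of a tissue.
#'
#' @param covList list of [CoverageTable] objects.
#' @return a single [CoverageTable].
#' @export
combineCoverageTables <- function(covList) {
  if (length(covList) == 1L) return(covList[[1L]])
  design <- do.call(rbind, lapply(covList, function(x) x@design))
  if (anyDuplicated(design$sample_id))
    stopInput("coverage tables to combine share sample ids")
  bindBy <- function(get) {
    rows <- sort(unique(unlist(lapply(covList, function(x) rownames(get(x))))))
    out <- matrix(0, nrow = length(rows), ncol = nrow(design),
                  dimnames = list(rows, design$sample_id))
    for (x in covList) {
      m <- get(x)
      if (nrow(m)) out[rownames(m), colnames(m)] <- m
    }
    out
  }
  coverageTable(bindBy(geneCounts), bindBy(exonDepth), bindBy(intronDepth),
                bindBy(junctionCounts), bindBy(skipCounts), design = design)
}
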