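#' Intron-retention ratio
#'
#' Average read depth of an intron divided by the mean average depth of
#' its two neighbouring (flanking) exons, weighted equally. Undefined
#' (NA) when both flanking exons have zero depth. Scale-invariant:
#' multiplying all depths of a sample by a constant leaves it unchanged.
#'
#' @param intronDepth,upstreamExonDepth,downstreamExonDepth numeric
#'   vectors of mean read depths (reads/bp), recycled to a common length.
#' @return numeric vector of IR ratios, NA where the denominator is 0.
#' @examples
#' irRatio(10, 20, 20)   # 0.5
#' irRatio(5, 0, 0)      # NA
#' @export
irRatio <- function(intronDepth, upstreamExonDepth, downstreamExonDepth) {
  den <- (upstreamExonDepth + downstreamExonDepth) / 2
  out <- intronDepth / den
  out[den == 0] <- NA_real_
  out
}

#' Background-normalized event ratio
#'
#' Read counts supporting an alternative donor/acceptor junction or an
#' exon skip are divided by the gene's expression level (read count) as
#' background, removing expression confounding. Undefined (NA) when the
#' gene count is zero.
#'
#' @param eventReads,geneReads numeric vectors of read counts.
#' @return numeric vector of ratios.
#' @export
backgroundRatio <- function(eventReads, geneReads) {
  out <- eventReads / geneReads
  out[geneReads == 0] <- NA_real_
  out
}

## Annotated junction boundaries of a GeneModels object: per gene, the
## last base of each upstream exon (left) and the first base of each
## downstream exon (right), with the adjacency index.
annotatedJunctions <- function(models) {
  ids <- geneIds(models)
  en <- GenomicRanges::end(exons(models))
  st <- GenomicRanges::start(exons(models))
  do.call(rbind, lapply(ids, function(g) {
    e <- en[[g]]; s <- st[[g]]
    n <- length(s)
    if (n < 2L) return(NULL)
    data.frame(gene_id = g, upstream_exon = seq_len(n - 1L),
               left = e[-n], right = s[-1L], stringsAsFactors = FALSE)
  }))
}

#' Extract alternative-splicing events from a coverage table
#'
#' Three event classes are produced. IR: one event per annotated intron
#' with intron signal in any sample; the per-sample ratio is the IR ratio
#' against the flanking exons. DA: one event per observed junction whose
#' (donor, acceptor) positions match the annotated exon boundaries of the
#' gene on exactly one side; ratio = junction reads over gene reads.
#' Junctions matching both sides are annotated splicing and are not
#' events; junctions matching neither side are logged (message) and
#' ignored. ES: one event per skip-count row, the skipped exon being an
#' internal annotated exon; ratio = skip reads over gene reads.
#'
#' @param cov a [CoverageTable].
#' @param models the matching [GeneModels].
#' @return an [AsEventSet].
#' @export
extractEvents <- function(cov, models) {
  design <- sampleDesign(cov)
  infos <- list(); ratios <- list(); signals <- list()

  ## --- IR -------------------------------------------------------------
  idm <- intronDepth(cov)
  if (nrow(idm)) {
    seen <- rowSums(idm) > 0
    idm <- idm[seen, , drop = FALSE]
  }
  if (nrow(idm)) {
    gene <- sub(":[^:]+$", "", rownames(idm))
    idx <- as.integer(sub("^.*:", "", rownames(idm)))
    edm <- exonDepth(cov)
    up <- edm[featureKey(gene, idx), , drop = FALSE]
    dn <- edm[featureKey(gene, idx + 1L), , drop = FALSE]
    rat <- irRatio(idm, up, dn)
    infos$IR <- data.frame(event_id = paste0(gene, ":IR:", idx),
                           gene_id = gene, type = "IR",
                           feature = as.character(idx),
                           stringsAsFactors = FALSE)
    ratios$IR <- rat
    signals$IR <- idm
  }

  gcm <- geneCounts(cov)

  ## --- DA -------------------------------------------------------------
  jcm <- junctionCounts(cov)
  if (nrow(jcm)) {
    parts <- strsplit(rownames(jcm), ":", fixed = TRUE)
    gene <- vapply(parts, `[`, character(1), 1L)
    donor <- as.integer(vapply(parts, `[`, character(1), 2L))
    acceptor <- as.integer(vapply(parts, `[`, character(1), 3L))
    ann <- annotatedJunctions(models)
    annBy <- split(ann, ann$gene_id)
    leftHit <- rightHit <- bothAdj <- rep(FALSE, nrow(jcm))
    esHit <- rep(NA_integer_, nrow(jcm))
    for (i in seq_len(nrow(jcm))) {
      a <- annBy[[gene[i]]]
      if (is.null(a) || !nrow(a)) next
      leftHit[i] <- donor[i] %in% a$left
      rightHit[i] <- acceptor[i] %in% a$right
      if (leftHit[i] && rightHit[i]) {
        iL <- a$upstream_exon[match(donor[i], a$left)]
        iR <- a$upstream_exon[match(acceptor[i], a$right)]
        if (iL == iR) bothAdj[i] <- TRUE          # annotated junction
        else if (iR > iL) esHit[i] <- iL + 1L     # skip junction
      }
    }
    isDa <- xor(leftHit, rightHit)
    unmatched <- !isDa & !bothAdj & is.na(esHit)
    if (any(unmatched))
      message(sum(unmatched),
              " junction key(s) match no annotated boundary; ignored")
    if (any(isDa)) {
      sub <- which(isDa)
      rat <- backgroundRatio(jcm[sub, , drop = FALSE],
                             gcm[gene[sub], , drop = FALSE])
      infos$DA <- data.frame(
        event_id = paste0(gene[sub], ":DA:", donor[sub], ":", acceptor[sub]),
        gene_id = gene[sub], type = "DA",
        feature = paste0(donor[sub], ":", acceptor[sub]),
        stringsAsFactors = FALSE)
      ratios$DA <- rat
      signals$DA <- jcm[sub, , drop = FALSE]
    }
    ## junction-encoded exon skips are folded into ES below
    if (any(!is.na(esHit))) {
      sub <- which(!is.na(esHit))
      rat <- backgroundRatio(jcm[sub, , drop = FALSE],
                             gcm[gene[sub], , drop = FALSE])
      infos$ESJ <- data.frame(
        event_id = paste0(gene[sub], ":ES:", esHit[sub]),
        gene_id = gene[sub], type = "ES",
        feature = as.character(esHit[sub]), stringsAsFactors = FALSE)
      ratios$ESJ <- rat
      signals$ESJ <- jcm[sub, , drop = FALSE]
    }
  }

  ## --- ES (skip-count rows) ---------------------------------------------
  scm <- skipCounts(cov)
  if (nrow(scm)) {
    gene <- sub(":[^:]+$", "", rownames(scm))
    idx <- as.integer(sub("^.*:", "", rownames(scm)))
    nex <- lengths(exons(models))[gene]
    if (any(idx < 2L | idx >= nex))
      stopInput("skip key %s does not name an internal exon",
                rownames(scm)[which(idx < 2L | idx >= nex)[1]])
    rat <- backgroundRatio(scm, gcm[gene, , drop = FALSE])
    infos$ES <- data.frame(event_id = paste0(gene, ":ES:", idx),
                           gene_id = gene, type = "ES",
                           feature = as.character(idx),
                           stringsAsFactors = FALSE)
    ratios$ES <- rat
    signals$ES <- scm
  }

  info <- do.call(rbind, unname(infos))
  if (is.null(info)) {
    info <- data.frame(event_id = character(0), gene_id = character(0),
                       type = character(0), feature = character(0))
    ratM <- sigM <- emptySignal(design)
  } else {
    dedup <- !duplicated(info$event_id)
    ratM <- do.call(rbind, unname(ratios))[dedup, , drop = FALSE]
    sigM <- do.call(rbind, unname(signals))[dedup, , drop = FALSE]
    info <- info[dedup, , drop = FALSE]
    rownames(ratM) <- rownames(sigM) <- info$event_id
    rownames(info) <- NULL
  }
  methods::new("AsEventSet", info = info, ratios = ratM, signal = sigM,
               design = design)
}

#' Call differential alternative splicing
#'
#' Per timepoint, event ratios of treated and control replicates are
#' compared with a two-sided two-sample t-test. An event is called DAS
#' when (i) its raw signal is present (> 0) in all replicates of at least
#' one condition and its ratio is defined in all samples of the
#' timepoint, (ii) p < `alpha` (strict), and (iii) the ratio of group
#' mean ratios exceeds `minFC`-fold in either direction. Direction is
#' `enhanced` when the treated mean ratio exceeds the control mean.
#' Events with fewer than two defined ratios in a group are skipped with
#' the reason recorded.
#'
#' @param events an [AsEventSet].
#' @param alpha p-value threshold (default 0.05, strict).
#' @param minFC fold-change threshold on ratio means (default 2, strict).
#' @param varEqual pooled (default) or Welch t-test.
#' @return data.frame with one row per event and timepoint: event_id,
#'   gene_id, type, timepoint, mean_ratio_treated, mean_ratio_control,
#'   fold_change, p_value, observed_all_replicates, is_das, direction,
#'   reason (NA unless skipped).
#' @export
callDas <- function(events, alpha = 0.05, minFC = 2, varEqual = TRUE) {
  design <- sampleDesign(events)
  info <- eventInfo(events)
  rat <- eventRatios(events)
  sig <- eventSignal(events)
  out <- lapply(unique(design$timepoint), function(tp) {
    ti <- designColumns(design, tp, "treated")
    ci <- designColumns(design, tp, "control")
    if (length(ti) < 2L || length(ci) < 2L)
      stopInput("timepoint '%s' needs >= 2 replicates per condition", tp)
    rt <- rat[, ti, drop = FALSE]; rc <- rat[, ci, drop = FALSE]
    st <- sig[, ti, drop = FALSE]; sc <- sig[, ci, drop = FALSE]
    tt <- rowTTest(rt, rc, varEqual = varEqual)
    fc <- tt$mean_x / tt$mean_y
    present <- rowSums(st > 0) == length(ti) | rowSums(sc > 0) == length(ci)
    defined <- rowSums(is.na(rt)) + rowSums(is.na(rc)) == 0
    observed <- present & defined
    testable <- tt$n_x >= 2 & tt$n_y >= 2
    isDas <- observed & testable & !is.na(tt$p_value) &
      tt$p_value < alpha & fcPasses(fc, minFC)
    data.frame(event_id = info$event_id, gene_id = info$gene_id,
               type = info$type, timepoint = tp,
               mean_ratio_treated = tt$mean_x,
               mean_ratio_control = tt$mean_y,
               fold_change = fc, p_value = tt$p_value,
               observed_all_replicates = observed,
               is_das = isDas,
               direction = ifelse(tt$mean_x > tt$mean_y, "enhanced",
                                  "reduced"),
               reason = ifelse(testable, NA_character_,
                               "fewer than 2 defined ratios in a group"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Gene-level DAS flags by event type
#'
#' A gene is DAS of a given type when it carries at least one significant
#' event of that type at any timepoint; a gene may carry several types.
#'
#' @param calls output of [callDas()].
#' @param timepoint optional filter; default pools timepoints.
#' @return data.frame gene_id, DIR, DDA, DES (logical), das (any).
#' @export
dasGeneFlags <- function(calls, timepoint = NULL) {
  if (!is.null(timepoint)) calls <- calls[calls$timepoint %in% timepoint, ]
  sig <- calls[calls$is_das, , drop = FALSE]
  genes <- sort(unique(sig$gene_id))
  flag <- function(type) genes %in% sig$gene_id[sig$type == type]
  data.frame(gene_id = genes, DIR = flag("IR"), DDA = flag("DA"),
             DES = flag("ES"), das = rep_len(TRUE, length(genes)),
             stringsAsFactors = FALSE)
}

#' Composition of DAS genes by event type
#'
#' Gene counts and fractions per differential-splicing type; genes
#' carrying several types are counted once per type, so fractions can sum
#' to more than 1.
#'
#' @param calls output of [callDas()].
#' @return data.frame type (DIR/DDA/DES), n_genes, fraction (over DAS
#'   genes).
#' @export
dasTypeSummary <- function(calls) {
  fl <- dasGeneFlags(calls)
  n <- nrow(fl)
  data.frame(type = c("DIR", "DDA", "DES"),
             n_genes = c(sum(fl$DIR), sum(fl$DDA), sum(fl$DES)),
             fraction = if (n == 0) c(0, 0, 0)
                        else c(sum(fl$DIR), sum(fl$DDA), sum(fl$DES)) / n,
             stringsAsFactors = FALSE)
}
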