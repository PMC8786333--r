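#' Call differential expression per timepoint
#'
#' For every timepoint in the design, treated and control RPKM values are
#' compared gene-wise with a two-sided two-sample t-test (pooled-variance
#' Student's t by default; Welch via `varEqual = FALSE`). Fold-change is
#' the ratio of group mean RPKM (treated over control); a zero control
#' mean with nonzero treated mean gives an infinite fold-change, which
#' passes the filter. A gene is differentially expressed when it is
#' relevantly expressed, p <= `alpha`, and the fold-change exceeds
#' `minFC`-fold in either direction. Relevance requires the group mean
#' RPKM to exceed the dataset threshold in at least one group
#' (`relevance = "either"`, default) or in both.
#'
#' No multiple-testing correction is applied by default (raw p-values are
#' filtered jointly with the fold-change); `adjust = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param expr a [NormalizedExpression].
#' @param alpha p-value threshold (default 0.05, inclusive).
#' @param minFC fold-change threshold (default 2, strict).
#' @param relevance `"either"` or `"both"` group means above threshold.
#' @param varEqual pooled (TRUE, default) or Welch t-test.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per gene and timepoint: gene_id,
#'   tissue, timepoint, mean_rpkm_treated, mean_rpkm_control, fold_change,
#'   log2_fc, p_value, relevant, is_de, direction (up/down).
#' @export
callDE <- function(expr, alpha = 0.05, minFC = 2,
                   relevance = c("either", "both"), varEqual = TRUE,
                   adjust = c("none", "BH")) {
  relevance <- match.arg(relevance)
  adjust <- match.arg(adjust)
  design <- sampleDesign(expr)
  r <- rpkm(expr)
  thr <- relevanceThreshold(expr)
  out <- lapply(unique(design$timepoint), function(tp) {
    ti <- designColumns(design, tp, "treated")
    ci <- designColumns(design, tp, "control")
    if (length(ti) < 2L || length(ci) < 2L)
      stopInput("timepoint '%s' needs >= 2 replicates per condition", tp)
    tt <- rowTTest(r[, ti, drop = FALSE], r[, ci, drop = FALSE],
                   varEqual = varEqual)
    p <- if (adjust == "BH") stats::p.adjust(tt$p_value, "BH") else tt$p_value
    fc <- tt$mean_x / tt$mean_y
    rel <- if (relevance == "either") pmax(tt$mean_x, tt$mean_y) > thr
           else pmin(tt$mean_x, tt$mean_y) > thr
    isDe <- rel & !is.na(p) & p <= alpha & fcPasses(fc, minFC)
    data.frame(gene_id = rownames(r),
               tissue = design$tissue[c(ti, ci)][1],
               timepoint = tp,
               mean_rpkm_treated = tt$mean_x,
               mean_rpkm_control = tt$mean_y,
               fold_change = fc,
               log2_fc = log2(fc),
               p_value = p,
               relevant = rel,
               is_de = isDe,
               direction = ifelse(fc > 1, "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Genes called differentially expressed
#'
#' @param calls output of [callDE()].
#' @param timepoint optional timepoint filter; default pools all.
#' @return character vector of gene ids.
#' @export
deGenes <- function(calls, timepoint = NULL) {
  if (!is.null(timepoint)) calls <- calls[calls$timepoint %in% timepoint, ]
  sort(unique(calls$gene_id[calls$is_de]))
}

#' Overlap (Venn) counts of gene sets across timepoints
#'
#' Counts genes by exact membership pattern across the supplied sets.
#' Exclusive subset counts sum to the size of the union.
#'
#' @param sets named list of character vectors (e.g. DE genes per
#'   timepoint).
#' @return data.frame with one logical membership column per set, the
#'   pattern label, and `count`.
#' @export
setOverlap <- function(sets) {
  if (length(sets) < 2L) stopInput("overlap needs >= 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  memb <- matrix(memb, nrow = length(genes),
                 dimnames = list(genes, names(sets)))
  pat <- apply(memb, 1L, function(z) paste(names(sets)[z], collapse = "&"))
  tb <- table(pat)
  out <- data.frame(pattern = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  for (nm in names(sets))
    out[[nm]] <- vapply(strsplit(out$pattern, "&", fixed = TRUE),
                        function(z) nm %in% z, logical(1))
  out[order(out$pattern), c(names(sets), "pattern", "count")]
}
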