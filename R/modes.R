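#' Classify genes by regulatory mode
#'
#' Partitions the expressed-gene universe into DE_only, DAS_only, both,
#' and neither from the two call sets. The summary attached as attribute
#' `"summary"` reports set sizes, the observed overlap, the fraction of
#' DAS genes that are also DE, and the overlap enrichment
#' observed/expected with expected = |DE| * |DAS| / |universe| (the
#' independence expectation).
#'
#' @param deSet,dasSet character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector, the expressed genes.
#' @return data.frame gene_id, mode; attribute `"summary"` is a one-row
#'   data.frame (n_universe, n_de, n_das, n_both, frac_das_also_de,
#'   expected_both, enrichment_both).
#' @export
classifyModes <- function(deSet, dasSet, universe) {
  outside <- setdiff(c(deSet, dasSet), universe)
  if (length(outside))
    stopInput("gene '%s' in calls but not in universe", outside[1])
  de <- universe %in% deSet
  das <- universe %in% dasSet
  mode <- ifelse(de & das, "both",
          ifelse(de, "DE_only", ifelse(das, "DAS_only", "neither")))
  out <- data.frame(gene_id = universe, mode = mode,
                    stringsAsFactors = FALSE)
  nDe <- sum(de); nDas <- sum(das); nBoth <- sum(de & das)
  expected <- nDe * nDas / length(universe)
  attr(out, "summary") <- data.frame(
    n_universe = length(universe), n_de = nDe, n_das = nDas,
    n_both = nBoth,
    frac_das_also_de = if (nDas > 0) nBoth / nDas else NA_real_,
    expected_both = expected,
    enrichment_both = if (expected > 0) nBoth / expected else NA_real_)
  out
}

#' Correlate DE and DAS fold-changes
#'
#' Pairs, per gene and timepoint, the DE log2 fold-change with the log2
#' fold-change of the gene's most significant DAS event of the requested
#' type, and reports Pearson and Spearman coefficients. Infinite
#' fold-changes (zero denominators) are excluded from the pairing.
#'
#' @param deCalls output of [callDE()].
#' @param dasCalls output of [callDas()].
#' @param type event type to pair: "IR", "DA" or "ES".
#' @param significantOnly restrict to is_de and is_das rows (default
#'   FALSE: all finite pairs).
#' @return list with `pairs` (data.frame gene_id, timepoint, log2_fc_de,
#'   log2_fc_das), `pearson`, `spearman`, `n`; coefficients NA when n < 3.
#' @export
fcCorrelation <- function(deCalls, dasCalls, type = c("IR", "DA", "ES"),
                          significantOnly = FALSE) {
  type <- match.arg(type)
  das <- dasCalls[dasCalls$type == type, , drop = FALSE]
  de <- deCalls
  if (significantOnly) {
    das <- das[das$is_das, , drop = FALSE]
    de <- de[de$is_de, , drop = FALSE]
  }
  ## most significant event per gene x timepoint
  das <- das[order(das$gene_id, das$timepoint, das$p_value), , drop = FALSE]
  das <- das[!duplicated(das[c("gene_id", "timepoint")]), , drop = FALSE]
  key <- function(d) paste(d$gene_id, d$timepoint, sep = "\r")
  i <- match(key(das), key(de))
  ok <- !is.na(i)
  pairs <- data.frame(gene_id = das$gene_id[ok],
                      timepoint = das$timepoint[ok],
                      log2_fc_de = log2(de$fold_change[i[ok]]),
                      log2_fc_das = log2(das$fold_change[ok]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[is.finite(pairs$log2_fc_de) & is.finite(pairs$log2_fc_das), ,
                 drop = FALSE]
  n <- nrow(pairs)
  list(pairs = pairs,
       pearson = if (n >= 3) stats::cor(pairs$log2_fc_de, pairs$log2_fc_das)
                 else NA_real_,
       spearman = if (n >= 3) stats::cor(pairs$log2_fc_de,
                                         pairs$log2_fc_das,
                                         method = "spearman") else NA_real_,
       n = n)
}

#' Regulatory-mode composition over time
#'
#' Among the responsive genes (mode not `neither`) of each timepoint,
#' the proportions of DE_only, DAS_only and both; they sum to 1 where the
#' responsive subset is non-empty and are NA otherwise.
#'
#' @param modeCallsByTimepoint named list of [classifyModes()] outputs,
#'   one per timepoint.
#' @param geneSubset optional character vector restricting the genes
#'   considered (e.g. one functional category).
#' @return data.frame timepoint, n_responsive, prop_de_only,
#'   prop_das_only, prop_both.
#' @export
modeComposition <- function(modeCallsByTimepoint, geneSubset = NULL) {
  out <- lapply(names(modeCallsByTimepoint), function(tp) {
    mc <- modeCallsByTimepoint[[tp]]
    if (!is.null(geneSubset)) mc <- mc[mc$gene_id %in% geneSubset, ,
                                       drop = FALSE]
    resp <- mc[mc$mode != "neither", , drop = FALSE]
    n <- nrow(resp)
    if (n == 0)
      return(data.frame(timepoint = tp, n_responsive = 0L,
                        prop_de_only = NA_real_, prop_das_only = NA_real_,
                        prop_both = NA_real_, stringsAsFactors = FALSE))
    data.frame(timepoint = tp, n_responsive = n,
               prop_de_only = mean(resp$mode == "DE_only"),
               prop_das_only = mean(resp$mode == "DAS_only"),
               prop_both = mean(resp$mode == "both"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
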