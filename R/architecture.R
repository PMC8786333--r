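#' Average splice-site strength
#'
#' Per gene, the mean of the minimum 5' and the minimum 3' splice-site
#' strength over its introns: `(min5 + min3) / 2`. Scores are
#' log-odds-like and may be negative; the scale of the input table is
#' taken as given. Genes without introns have no splice sites and get NA.
#'
#' @param min5,min3 numeric vectors of per-gene minimum 5' and 3' scores.
#' @return numeric vector; NA where either score is missing.
#' @examples
#' averageSpliceSiteStrength(-2, 4)   # 1
#' @export
averageSpliceSiteStrength <- function(min5, min3) (min5 + min3) / 2

#' Assemble per-gene architecture records
#'
#' Joins intron counts and lengths from the gene models with per-intron
#' splice-site strength scores and per-gene promoter annotation. Per gene
#' the minimum 5' and minimum 3' scores over its introns are taken and
#' averaged into the ASS. Genes absent from a table keep NA in the
#' corresponding fields — never silently 0.
#'
#' @param models a [GeneModels].
#' @param spliceScores data.frame `gene_id, intron_index, score_5ss,
#'   score_3ss` (1-based intron index; an index not resolvable against
#'   the gene model is an error).
#' @param promoters data.frame `gene_id, promoter_length, tfbs_count`.
#' @return data.frame gene_id, intron_count, intron_lengths
#'   (comma-separated bp), min_5ss, min_3ss, ass, promoter_length,
#'   tfbs_count.
#' @export
buildArchitecture <- function(models, spliceScores = NULL,
                              promoters = NULL) {
  ids <- geneIds(models)
  ic <- intronCounts(models)
  ilen <- GenomicRanges::width(introns(models))
  out <- data.frame(gene_id = ids, intron_count = as.integer(ic),
                    intron_lengths = vapply(seq_along(ids), function(i)
                      paste(ilen[[i]], collapse = ","), character(1)),
                    min_5ss = NA_real_, min_3ss = NA_real_, ass = NA_real_,
                    promoter_length = NA_real_, tfbs_count = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(spliceScores)) {
    bad <- !spliceScores$gene_id %in% ids |
      spliceScores$intron_index < 1 |
      spliceScores$intron_index > ic[spliceScores$gene_id]
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      i <- which(bad)[1]
      stopInput("splice-score row for unresolvable intron %s:%s",
                spliceScores$gene_id[i], spliceScores$intron_index[i])
    }
    agg5 <- tapply(spliceScores$score_5ss, spliceScores$gene_id, min)
    agg3 <- tapply(spliceScores$score_3ss, spliceScores$gene_id, min)
    out$min_5ss <- as.numeric(agg5[out$gene_id])
    out$min_3ss <- as.numeric(agg3[out$gene_id])
    out$ass <- averageSpliceSiteStrength(out$min_5ss, out$min_3ss)
  }
  if (!is.null(promoters)) {
    i <- match(out$gene_id, promoters$gene_id)
    out$promoter_length <- promoters$promoter_length[i]
    out$tfbs_count <- promoters$tfbs_count[i]
  }
  out
}

#' Intron-number bin enrichment of a gene set
#'
#' Frequency of a gene set across intron-number bins normalized to the
#' genome-wide (background) frequency: per bin, (fraction of the set in
#' the bin) / (fraction of the background in the bin). 1 means the set is
#' distributed like the background; NA where the background fraction is
#' zero. Default bins reflect the saturation of splicing regulation
#' between roughly 10 and 20 introns and the rarity of genes with more
#' than 50.
#'
#' @param geneSet character vector (non-empty; must be drawn from the
#'   background).
#' @param background data.frame with gene_id and intron_count covering
#'   the genome-wide universe, e.g. from [buildArchitecture()].
#' @param breaks integer bin lower edges; default bins 0, 1-5, 6-10,
#'   11-20, 21-50, >50.
#' @return data.frame bin, n_set, n_background, enrichment.
#' @export
intronBinEnrichment <- function(geneSet, background,
                                breaks = c(0, 1, 6, 11, 21, 51)) {
  if (length(geneSet) == 0) stopInput("empty gene set")
  if (!all(geneSet %in% background$gene_id))
    stopInput("gene set contains genes missing from the background")
  edges <- c(breaks - 0.5, Inf)
  labs <- vapply(seq_along(breaks), function(i) {
    lo <- breaks[i]
    hi <- if (i < length(breaks)) breaks[i + 1] - 1 else Inf
    if (lo == hi) as.character(lo)
    else if (is.infinite(hi)) paste0(">", lo - 1) else paste0(lo, "-", hi)
  }, character(1))
  binOf <- cut(background$intron_count, breaks = edges, labels = labs)
  inSet <- background$gene_id %in% geneSet
  nSet <- as.integer(table(binOf[inSet]))
  nBg <- as.integer(table(binOf))
  fracSet <- nSet / sum(inSet)
  fracBg <- nBg / nrow(background)
  enr <- ifelse(fracBg > 0, fracSet / fracBg, NA_real_)
  data.frame(bin = labs, n_set = nSet, n_background = nBg,
             enrichment = enr, stringsAsFactors = FALSE)
}

#' Compare an architecture feature across process groups
#'
#' Two-way ANOVA of one architecture feature with process group and
#' tissue as factors (group-only one-way ANOVA when a single tissue is
#' present), followed by Tukey HSD multiple comparisons on the group
#' factor's marginal means. Groups with fewer than two observations are
#' excluded with a warning; genes with a missing feature value are
#' excluded from the test, never imputed.
#'
#' @param records [buildArchitecture()] output (or any data.frame with
#'   gene_id and the feature column).
#' @param groups data.frame gene_id, group and optionally tissue.
#' @param feature column of `records` to test (e.g. "ass",
#'   "intron_count", "promoter_length", "tfbs_count").
#' @return list with `anova` (data.frame of effects, F and p), `tukey`
#'   (data.frame comparison, diff, lwr, upr, p_adj), `group_stats`
#'   (n, mean, median per group).
#' @importFrom stats aov TukeyHSD median as.formula
#' @export
groupArchitectureTests <- function(records, groups, feature) {
  if (!feature %in% colnames(records))
    stopInput("unknown feature '%s'", feature)
  d <- merge(groups, records[, c("gene_id", feature)], by = "gene_id")
  d$value <- d[[feature]]
  d <- d[!is.na(d$value), , drop = FALSE]
  sizes <- table(d$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!d$group %in% small, , drop = FALSE]
  }
  if (length(unique(d$group)) < 2)
    stopInput("need >= 2 groups with >= 2 observations")
  d$group <- factor(d$group)
  twoWay <- "tissue" %in% colnames(d) && length(unique(d$tissue)) > 1
  fit <- if (twoWay) {
    d$tissue <- factor(d$tissue)
    aov(value ~ group * tissue, data = d)
  } else aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  anova <- data.frame(effect = trimws(rownames(an)), df = an$Df,
                      sum_sq = an$`Sum Sq`, f_value = an$`F value`,
                      p_value = an$`Pr(>F)`, stringsAsFactors = FALSE)
  tk <- TukeyHSD(fit, which = "group")$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  gs <- do.call(rbind, lapply(split(d$value, d$group), function(v)
    data.frame(n = length(v), mean = mean(v), median = median(v))))
  gs <- data.frame(group = rownames(gs), gs, stringsAsFactors = FALSE,
                   row.names = NULL)
  list(anova = anova, tukey = tukey, group_stats = gs)
}

#' Logistic regression of splicing-mode propensity on architecture
#'
#' Fits `dasFlag ~ intron_count + ass` by binomial GLM, quantifying how
#' intron number and average splice-site strength shift a gene's
#' propensity to be regulated by alternative splicing.
#'
#' @param records [buildArchitecture()] output.
#' @param dasGenes character vector of DAS-regulated gene ids.
#' @return data.frame term, estimate, std_error, z_value, p_value.
#' @importFrom stats glm binomial coef
#' @export
architectureModeRegression <- function(records, dasGenes) {
  d <- records[!is.na(records$ass), , drop = FALSE]
  d$das <- d$gene_id %in% dasGenes
  fit <- glm(das ~ intron_count + ass, data = d, family = binomial())
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
             z_value = cf[, 3], p_value = cf[, 4],
             stringsAsFactors = FALSE, row.names = NULL)
}
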