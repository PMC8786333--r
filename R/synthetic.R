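#' @importFrom stats rnbinom rpois rbinom rlnorm rgamma rnorm runif plogis
#'   qlogis
NULL

#' Build a synthetic-data configuration
#'
#' See [SyntheticConfig] for slot semantics. Defaults encode the study
#' conditions the pipeline targets: 3 treated vs 3 control replicates at
#' timepoints 0.5h/6h/12h, negative-binomial counts with dispersion 0.1,
#' mean exonic depth 50 reads/bp, baseline intron-retention ratio 0.05,
#' junction background rate 0.01, and 4-fold injected effects.
#'
#' @param nGenes number of genes (default 500).
#' @param seed integer seed (default 1).
#' @param ... overrides of any other [SyntheticConfig] slot.
#' @return a validated [SyntheticConfig].
#' @export
syntheticConfig <- function(nGenes = 500, seed = 1, ...) {
  defaults <- list(nGenes = nGenes, intronMean = 4, intronSize = 1.2,
                   exonLengthMean = 250, intronLengthMean = 160,
                   replicates = 3, timepoints = c("0.5h", "6h", "12h"),
                   tissue = "root", baselineDepth = 50, dispersion = 0.1,
                   deFraction = 0.1, deEffect = 4,
                   irFraction = 0.1, irEffect = 4,
                   daFraction = 0.05, daEffect = 4,
                   esFraction = 0.03, esEffect = 4,
                   baselineIrRatio = 0.05, junctionBgRate = 0.01,
                   couplingBeta = c(0, 0, 0), readLength = 100,
                   seed = seed)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stopConfig("unknown synthetic-config field(s): %s",
               paste(unknown, collapse = ", "))
  defaults[names(extra)] <- extra
  do.call(methods::new, c("SyntheticConfig", defaults))
}

## negative-binomial draw parameterized by mean and dispersion alpha
## (variance mu + alpha mu^2); alpha = 0 degenerates to Poisson
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

## gamma draw around a mean with squared coefficient of variation = disp;
## disp = 0 degenerates to the mean itself
rdepth <- function(n, mean, dispersion) {
  if (dispersion <= 0) rep_len(mean, n)
  else rgamma(n, shape = 1 / dispersion, scale = mean * dispersion)
}

#' Generate a ground-truth dataset
#'
#' Simulates gene models, per-timepoint coverage tables, architecture
#' tables and the injection truth under the configured design. Gene read
#' counts are negative-binomial around the mean implied by the gene's
#' exonic depth and model length; exon depths are gamma-distributed
#' around the gene's condition mean with squared coefficient of variation
#' equal to the dispersion; the intron depth is the realized mean depth
#' of its flanking exons times the intron-retention ratio times a gamma
#' splicing-efficiency noise (CV^2 = dispersion), so transcription-level
#' fluctuations cancel from the IR ratio and its replicate variability is
#' governed by the dispersion alone. An injected IR event multiplies the
#' treated intron's retention ratio by the effect size.
#' Junction and skip reads are Poisson with a
#' background rate times the gene's sampled count (so event ratios are
#' expression-normalized by construction); injected DA/ES events scale
#' the treated rate. Injected differential expression scales all treated
#' feature signals of the gene. Gene-level IR-injection propensity
#' follows a logistic model on centred intron count and centred ASS with
#' the configured coupling coefficients; with zero coefficients the
#' injections are architecture-independent at rate `irFraction` and DE
#' and DAS injections are mutually independent.
#'
#' The seed in the config fully determines the output.
#'
#' @param config a [SyntheticConfig].
#' @return list with `models` ([GeneModels]), `coverage` (named list of
#'   [CoverageTable], one per timepoint), `design` (all samples),
#'   `spliceScores`, `promoters` (input tables for
#'   [buildArchitecture()]), and `truth` (list of data.frames: `genes`,
#'   `de`, `events`).
#' @export
generateDataset <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  n <- as.integer(config@nGenes)
  reps <- as.integer(config@replicates)
  rl <- config@readLength

  ## --- gene structure ---------------------------------------------------
  nIntrons <- rnbinom(n, mu = config@intronMean, size = config@intronSize)
  nExons <- nIntrons + 1L
  ids <- sprintf("SYNG%05d", seq_len(n))
  exonLens <- lapply(nExons, function(k)
    pmax(30L, as.integer(round(rgamma(k, shape = 2,
                                      scale = config@exonLengthMean / 2)))))
  intronLens <- lapply(nIntrons, function(k)
    if (k == 0L) integer(0)
    else pmax(60L, as.integer(round(rgamma(k, shape = 2,
                                    scale = config@intronLengthMean / 2)))))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  pos <- 1L
  allStarts <- vector("list", n); allEnds <- vector("list", n)
  for (g in seq_len(n)) {
    el <- exonLens[[g]]; il <- c(intronLens[[g]], 0L)
    starts <- pos + c(0L, cumsum(el + il)[-length(el)])
    ends <- starts + el - 1L
    allStarts[[g]] <- starts; allEnds[[g]] <- ends
    pos <- ends[length(ends)] + 1001L
  }
  flat <- GenomicRanges::GRanges("Chr1",
    IRanges::IRanges(unlist(allStarts), unlist(allEnds)),
    strand = rep(strands, nExons))
  models <- geneModels(GenomicRanges::split(
    flat, factor(rep(ids, nExons), levels = ids)))
  geneLen <- geneLengths(models)

  ## --- architecture inputs ---------------------------------------------
  hasIntron <- nIntrons > 0L
  spliceScores <- do.call(rbind, lapply(which(hasIntron), function(g)
    data.frame(gene_id = ids[g], intron_index = seq_len(nIntrons[g]),
               score_5ss = round(rnorm(nIntrons[g], 7, 2.5), 3),
               score_3ss = round(rnorm(nIntrons[g], 7, 2.5), 3),
               stringsAsFactors = FALSE)))
  promLen <- pmax(200L, as.integer(round(rnorm(n, 1595, 400))))
  promoters <- data.frame(gene_id = ids, promoter_length = promLen,
                          tfbs_count = rpois(n, promLen / 47.6),
                          stringsAsFactors = FALSE)
  arch <- buildArchitecture(models, spliceScores, promoters)
  ass <- arch$ass

  ## --- gene-level propensities -----------------------------------------
  depth <- rlnorm(n, log(config@baselineDepth) - 0.5 * 0.7^2, 0.7)
  beta <- config@couplingBeta
  assC <- ifelse(is.na(ass), 0, ass - mean(ass, na.rm = TRUE))
  icC <- nIntrons - mean(nIntrons)
  pIr <- plogis(qlogis(config@irFraction) + beta[1] +
                beta[2] * icC + beta[3] * assC)
  pIr[!hasIntron] <- 0

  ## fixed per-gene event candidates (shared across timepoints)
  daIntron <- ifelse(hasIntron,
                     vapply(nIntrons, function(k)
                       if (k > 0) sample.int(k, 1L) else NA_integer_,
                       integer(1)), NA_integer_)
  canSkip <- nExons >= 3L
  skipExon <- ifelse(canSkip,
                     vapply(nExons, function(k)
                       if (k >= 3L) 1L + sample.int(k - 2L, 1L)
                       else NA_integer_, integer(1)), NA_integer_)
  exonEnds <- GenomicRanges::end(exons(models))
  exonStarts <- GenomicRanges::start(exons(models))
  daKey <- rep(NA_character_, n)
  for (g in which(hasIntron)) {
    j <- daIntron[g]
    daKey[g] <- paste0(exonEnds[[g]][j], ":", exonStarts[[g]][j + 1L] + 12L)
  }

  sampleIds <- function(tp) {
    c(sprintf("%s_%s_trt_r%d", config@tissue, tp, seq_len(reps)),
      sprintf("%s_%s_ctl_r%d", config@tissue, tp, seq_len(reps)))
  }
  designOf <- function(tp) data.frame(
    sample_id = sampleIds(tp),
    condition = rep(c("treated", "control"), each = reps),
    timepoint = tp, replicate = rep(seq_len(reps), 2),
    tissue = config@tissue, stringsAsFactors = FALSE)

  exonRows <- unlist(lapply(seq_len(n), function(g)
    featureKey(ids[g], seq_len(nExons[g]))), use.names = FALSE)
  exonGene <- rep(seq_len(n), nExons)
  exonLenV <- unlist(exonLens, use.names = FALSE)
  intronRows <- unlist(lapply(which(hasIntron), function(g)
    featureKey(ids[g], seq_len(nIntrons[g]))), use.names = FALSE)
  intronGene <- rep(which(hasIntron), nIntrons[hasIntron])
  intronLenV <- unlist(intronLens, use.names = FALSE)
  intronIdxV <- unlist(lapply(nIntrons[hasIntron], seq_len),
                       use.names = FALSE)

  coverage <- list()
  truthDe <- list(); truthEv <- list()
  for (tp in config@timepoints) {
    ## per-timepoint injections
    deFlag <- rbinom(n, 1, config@deFraction) == 1
    deDirUp <- rbinom(n, 1, 0.5) == 1
    deMult <- ifelse(deFlag, ifelse(deDirUp, config@deEffect,
                                    1 / config@deEffect), 1)
    irFlag <- rbinom(n, 1, pIr) == 1
    irIntron <- rep(NA_integer_, n)
    irIntron[irFlag] <- vapply(nIntrons[irFlag], function(k)
      sample.int(k, 1L), integer(1))
    daFlag <- hasIntron & rbinom(n, 1, config@daFraction) == 1
    esFlag <- canSkip & rbinom(n, 1, config@esFraction) == 1

    des <- designOf(tp)
    treatedCol <- des$condition == "treated"
    nc <- nrow(des)

    geneMu <- depth * geneLen[ids] / rl
    gc <- matrix(0, n, nc, dimnames = list(ids, des$sample_id))
    ed <- matrix(0, length(exonRows), nc,
                 dimnames = list(exonRows, des$sample_id))
    idp <- matrix(0, length(intronRows), nc,
                  dimnames = list(intronRows, des$sample_id))
    jc <- matrix(0, sum(hasIntron), nc,
                 dimnames = list(featureKey(ids[hasIntron],
                                            daKey[hasIntron]),
                                 des$sample_id))
    sk <- matrix(0, sum(canSkip), nc,
                 dimnames = list(featureKey(ids[canSkip],
                                            skipExon[canSkip]),
                                 des$sample_id))
    irInjRow <- !is.na(irIntron[intronGene]) &
      intronIdxV == irIntron[intronGene]
    upIdx <- match(featureKey(ids[intronGene], intronIdxV), exonRows)
    dnIdx <- match(featureKey(ids[intronGene], intronIdxV + 1L), exonRows)
    for (s in seq_len(nc)) {
      trt <- treatedCol[s]
      mult <- if (trt) deMult else rep(1, n)
      gc[, s] <- rcounts(n, geneMu * mult, config@dispersion)
      exMean <- depth[exonGene] * mult[exonGene]
      ed[, s] <- rdepth(length(exMean), exMean, config@dispersion)
      irr <- rep(config@baselineIrRatio, length(intronRows))
      if (trt) irr[irInjRow] <- irr[irInjRow] * config@irEffect
      ## intron depth rides on the realized flanking-exon depth, so
      ## transcription-level fluctuation cancels from the IR ratio and
      ## the splicing-efficiency noise alone (CV^2 = dispersion) remains
      flank <- (ed[upIdx, s] + ed[dnIdx, s]) / 2
      idp[, s] <- flank * irr *
        rdepth(length(irr), rep(1, length(irr)), config@dispersion)
      daRate <- rep(config@junctionBgRate, sum(hasIntron))
      if (trt) daRate[daFlag[hasIntron]] <-
          daRate[daFlag[hasIntron]] * config@daEffect
      jc[, s] <- rpois(sum(hasIntron), daRate * gc[hasIntron, s])
      esRate <- rep(config@junctionBgRate, sum(canSkip))
      if (trt) esRate[esFlag[canSkip]] <-
          esRate[esFlag[canSkip]] * config@esEffect
      sk[, s] <- rpois(sum(canSkip), esRate * gc[canSkip, s])
    }
    coverage[[tp]] <- coverageTable(gc, ed, idp, jc, sk, design = des)

    truthDe[[tp]] <- data.frame(gene_id = ids, timepoint = tp,
                                injected = deFlag,
                                fold_change = deMult,
                                stringsAsFactors = FALSE)
    ir <- data.frame(
      event_id = paste0(ids, ":IR:", ifelse(irFlag, irIntron, NA)),
      gene_id = ids, type = "IR",
      feature = as.character(irIntron), timepoint = tp,
      injected = irFlag, effect = ifelse(irFlag, config@irEffect, NA),
      stringsAsFactors = FALSE)[irFlag, , drop = FALSE]
    da <- data.frame(
      event_id = paste0(ids, ":DA:", daKey), gene_id = ids, type = "DA",
      feature = daKey, timepoint = tp, injected = daFlag,
      effect = ifelse(daFlag, config@daEffect, NA),
      stringsAsFactors = FALSE)[daFlag, , drop = FALSE]
    es <- data.frame(
      event_id = paste0(ids, ":ES:", skipExon), gene_id = ids,
      type = "ES", feature = as.character(skipExon), timepoint = tp,
      injected = esFlag, effect = ifelse(esFlag, config@esEffect, NA),
      stringsAsFactors = FALSE)[esFlag, , drop = FALSE]
    truthEv[[tp]] <- rbind(ir, da, es)
  }

  truthGenes <- data.frame(gene_id = ids, mean_depth = depth,
                           gene_length = as.numeric(geneLen[ids]),
                           intron_count = nIntrons, ass = ass,
                           ir_propensity = pIr, stringsAsFactors = FALSE)
  list(models = models, coverage = coverage,
       design = do.call(rbind, lapply(config@timepoints, designOf)),
       spliceScores = spliceScores, promoters = promoters,
       truth = list(genes = truthGenes,
                    de = do.call(rbind, truthDe),
                    events = do.call(rbind, truthEv)))
}

#' Write a synthetic dataset to disk
#'
#' Serializes every component in plain-text formats consumable by the
#' pipeline: `models.gff3`, one `coverage_<timepoint>.tsv` per timepoint,
#' `splice_scores.tsv`, `promoters.tsv`, and the truth tables
#' (`truth_genes.tsv`, `truth_de.tsv`, `truth_events.tsv`). Writing is
#' deterministic: the same dataset serializes byte-identically.
#'
#' @param dataset output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(models = file.path(dir, "models.gff3"))
  writeGeneModels(dataset$models, paths[["models"]])
  for (tp in names(dataset$coverage)) {
    p <- file.path(dir, paste0("coverage_", gsub("[^A-Za-z0-9._-]", "_", tp),
                               ".tsv"))
    writeCoverageTable(dataset$coverage[[tp]], p)
    paths[[paste0("coverage_", tp)]] <- p
  }
  for (nm in c("spliceScores", "promoters")) {
    p <- file.path(dir, paste0(c(spliceScores = "splice_scores",
                                 promoters = "promoters")[[nm]], ".tsv"))
    writeResults(dataset[[nm]], p)
    paths[[nm]] <- p
  }
  for (nm in names(dataset$truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    writeResults(dataset$truth[[nm]], p)
    paths[[paste0("truth_", nm)]] <- p
  }
  invisible(paths)
}

#' Generate a FASTQ file with known trimming truth
#'
#' Reads are built from a quality profile: a list of segments, each
#' `list(len, q)` giving the segment length and its Phred score. Bases
#' are drawn uniformly from ACGT. The per-read truth (expected retained
#' interval) is computed with [trimRead()] from the emitted qualities.
#'
#' @param path output FASTQ path.
#' @param nReads number of reads.
#' @param profile list of `list(len =, q =)` segments, e.g.
#'   `list(list(len = 2, q = 2), list(len = 40, q = 20))`.
#' @param seed integer seed.
#' @param qJitter integer; per-base quality jitter drawn uniformly from
#'   `-qJitter:qJitter` (default 0 = deterministic qualities).
#' @param cutoff,minLength trimming parameters used for the truth.
#' @return data.frame read_id, keep, start, end (1-based closed).
#' @export
generateFastq <- function(path, nReads, profile, seed = 1, qJitter = 0,
                          cutoff = 0.05, minLength = 35) {
  set.seed(seed)
  qs <- unlist(lapply(profile, function(seg) rep(seg$q, seg$len)))
  L <- length(qs)
  if (L == 0L) stopConfig("empty quality profile")
  ids <- sprintf("synread%05d", seq_len(nReads))
  seqs <- character(nReads); quals <- character(nReads)
  truth <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    q <- qs
    if (qJitter > 0)
      q <- pmax(0L, q + sample(-qJitter:qJitter, L, replace = TRUE))
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
    quals[i] <- rawToChar(as.raw(q + 33L))
    tr <- trimRead(q, cutoff = cutoff, minLength = minLength)
    truth[[i]] <- data.frame(read_id = ids[i], keep = tr$keep,
                             start = tr$start, end = tr$end,
                             stringsAsFactors = FALSE)
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  do.call(rbind, truth)
}

#' Generate per-dataset gene lists for consensus voting
#'
#' Assigns each gene a membership count drawn uniformly from 0..n and
#' places it in that many randomly chosen datasets, so vote counts have a
#' known truth.
#'
#' @param dir output directory for `dataset_<i>.tsv` files (NULL = do not
#'   write).
#' @param nDatasets number of datasets (>= 2).
#' @param nGenes number of genes in the universe.
#' @param seed integer seed.
#' @return list with `sets` (named list of character vectors), `truth`
#'   (data.frame gene_id, votes) and `paths` (written files, if any).
#' @export
generateConsensusInputs <- function(dir = NULL, nDatasets = 7,
                                    nGenes = 200, seed = 1) {
  if (nDatasets < 2) stopConfig("need >= 2 datasets")
  set.seed(seed)
  ids <- toupper(sprintf("syng%05d", seq_len(nGenes)))
  votes <- sample(0:nDatasets, nGenes, replace = TRUE)
  sets <- rep(list(character(0)), nDatasets)
  names(sets) <- sprintf("dataset_%d", seq_len(nDatasets))
  for (g in seq_len(nGenes)) {
    if (votes[g] == 0) next
    for (d in sample.int(nDatasets, votes[g]))
      sets[[d]] <- c(sets[[d]], ids[g])
  }
  sets <- lapply(sets, sort)
  paths <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(sets), function(nm) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      writeResults(data.frame(gene_id = sets[[nm]],
                              stringsAsFactors = FALSE), p)
      p
    }, character(1))
  }
  list(sets = sets,
       truth = data.frame(gene_id = ids, votes = votes,
                          stringsAsFactors = FALSE),
       paths = paths)
}
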