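#' Build a pipeline configuration
#'
#' Collects input paths and stage parameters for [runPipeline()]. Unknown
#' fields are rejected. The same structure can be read from YAML with
#' [readPipelineConfig()].
#'
#' @param outDir output directory.
#' @param stages character vector, subset of
#'   `c("trim","normalize","de","das","modes","architecture","ferrome")`;
#'   order of execution is fixed regardless of the order given.
#' @param gff3 path to gene models (needed by normalize/de/das/modes/
#'   architecture).
#' @param coverage named character vector of coverage TSVs, one per
#'   timepoint.
#' @param fastqIn,fastqOut FASTQ paths for the trim stage.
#' @param spliceScores,promoters architecture input TSVs.
#' @param categories optional TSV `gene_id<TAB>group` enabling the
#'   ANOVA comparison of the architecture stage.
#' @param geneLists character vector of gene-list TSVs for consensus
#'   voting.
#' @param alpha,minFC,dasAlpha,dasMinFC,relevance,k,trimCutoff,
#'   trimMinLength stage parameters.
#' @param seed integer seed recorded in the config (the pipeline itself
#'   is deterministic given its inputs).
#' @return a list of class `ironsplice_config`.
#' @export
pipelineConfig <- function(outDir, stages = c("normalize", "de", "das",
                                              "modes", "architecture"),
                           gff3 = NULL, coverage = NULL, fastqIn = NULL,
                           fastqOut = NULL, spliceScores = NULL,
                           promoters = NULL, categories = NULL,
                           geneLists = NULL, alpha = 0.05, minFC = 2,
                           dasAlpha = 0.05, dasMinFC = 2,
                           relevance = "either", k = 4,
                           trimCutoff = 0.05, trimMinLength = 35,
                           seed = 1) {
  known <- c("trim", "normalize", "de", "das", "modes", "architecture",
             "ferrome")
  if (length(setdiff(stages, known)))
    stopConfig("unknown stage(s): %s",
               paste(setdiff(stages, known), collapse = ", "))
  structure(list(outDir = outDir, stages = stages, gff3 = gff3,
                 coverage = coverage, fastqIn = fastqIn,
                 fastqOut = fastqOut, spliceScores = spliceScores,
                 promoters = promoters, categories = categories,
                 geneLists = geneLists, alpha = alpha, minFC = minFC,
                 dasAlpha = dasAlpha, dasMinFC = dasMinFC,
                 relevance = relevance, k = k, trimCutoff = trimCutoff,
                 trimMinLength = trimMinLength, seed = seed),
            class = "ironsplice_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; known keys are passed to
#' [pipelineConfig()].
#'
#' @param path YAML file path.
#' @return a list of class `ironsplice_config`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stopConfig("unknown config key(s) in '%s': %s", path,
               paste(unknown, collapse = ", "))
  if (!is.null(y$coverage)) y$coverage <- unlist(y$coverage)
  do.call(pipelineConfig, y)
}

requireInputs <- function(config, stage, fields) {
  for (f in fields) {
    v <- config[[f]]
    if (is.null(v))
      stopInput("stage '%s' needs config field '%s'", stage, f)
    if (f %in% c("gff3", "coverage", "fastqIn", "spliceScores",
                 "promoters", "categories", "geneLists")) {
      missing <- v[!file.exists(v)]
      if (length(missing))
        stopInput("stage '%s': input file '%s' does not exist", stage,
                  missing[1])
    }
  }
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order
#' trim -> normalize -> de -> das -> modes -> architecture -> ferrome,
#' validating every enabled stage's inputs before anything runs (fail
#' fast). Results are written as TSVs into `outDir`; the returned
#' manifest lists every output file with its data-row count. With
#' identical config and inputs the output files are byte-identical
#' across runs.
#'
#' @param config a `ironsplice_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return list with `manifest` (data.frame file, rows) and `status`
#'   (0 on success; errors are raised as classed conditions:
#'   `ironsplice_config_error`, `ironsplice_input_error`).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "ironsplice_config"))
    stopConfig("config must come from pipelineConfig()")
  order <- c("trim", "normalize", "de", "das", "modes", "architecture",
             "ferrome")
  stages <- order[order %in% config$stages]
  needs <- list(trim = c("fastqIn", "fastqOut"),
                normalize = c("gff3", "coverage"),
                de = c("gff3", "coverage"),
                das = c("gff3", "coverage"),
                modes = c("gff3", "coverage"),
                architecture = c("gff3", "coverage", "spliceScores",
                                 "promoters"),
                ferrome = "geneLists")
  for (st in stages) requireInputs(config, st, needs[[st]])
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(path, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), rows = as.integer(rows),
      stringsAsFactors = FALSE)
  }
  emit <- function(df, name) {
    p <- file.path(config$outDir, name)
    writeResults(df, p)
    note(p, nrow(df))
  }

  if ("trim" %in% stages) {
    ts <- trimFastq(config$fastqIn, config$fastqOut,
                    cutoff = config$trimCutoff,
                    minLength = config$trimMinLength)
    emit(data.frame(n_in = ts$n_in, n_kept = ts$n_kept,
                    n_discarded = ts$n_discarded), "trim_summary.tsv")
  }

  models <- NULL; covs <- NULL; expr <- NULL
  deCalls <- NULL; dasCalls <- NULL
  needCoverage <- any(c("normalize", "de", "das", "modes",
                        "architecture") %in% stages)
  if (needCoverage) {
    models <- readGeneModels(config$gff3)
    covs <- lapply(config$coverage, readCoverageFromFile, models = models)
    combined <- combineCoverageTables(unname(covs))
    expr <- normalizeExpression(combined, models)
    if ("normalize" %in% stages) {
      lc <- logCPM(expr); rk <- rpkm(expr)
      tab <- data.frame(gene_id = rep(rownames(lc), ncol(lc)),
                        sample_id = rep(colnames(lc), each = nrow(lc)),
                        logcpm = as.vector(lc), rpkm = as.vector(rk),
                        relevant = as.vector(rk) > relevanceThreshold(expr),
                        stringsAsFactors = FALSE)
      emit(tab, "expression.tsv")
    }
  }

  if (any(c("de", "modes", "architecture") %in% stages)) {
    deCalls <- callDE(expr, alpha = config$alpha, minFC = config$minFC,
                      relevance = config$relevance)
    if ("de" %in% stages) emit(deCalls, "de_calls.tsv")
  }
  if (any(c("das", "modes", "architecture") %in% stages)) {
    dasCalls <- do.call(rbind, lapply(unname(covs), function(cv)
      callDas(extractEvents(cv, models), alpha = config$dasAlpha,
              minFC = config$dasMinFC)))
    if ("das" %in% stages) {
      emit(dasCalls, "das_calls.tsv")
      emit(dasGeneFlags(dasCalls), "das_genes.tsv")
    }
  }

  if ("modes" %in% stages) {
    universe <- rownames(rpkm(expr))
    mc <- classifyModes(deGenes(deCalls), dasGeneFlags(dasCalls)$gene_id,
                        universe)
    emit(mc, "modes.tsv")
    tps <- unique(sampleDesign(expr)$timepoint)
    byTp <- lapply(tps, function(tp)
      classifyModes(deGenes(deCalls, tp),
                    dasGeneFlags(dasCalls, tp)$gene_id, universe))
    names(byTp) <- tps
    emit(modeComposition(byTp), "mode_composition.tsv")
    fcp <- fcCorrelation(deCalls, dasCalls, "IR")
    emit(fcp$pairs, "fc_pairs.tsv")
  }

  if ("architecture" %in% stages) {
    ss <- read.delim(config$spliceScores, header = TRUE, sep = "\t")
    pr <- read.delim(config$promoters, header = TRUE, sep = "\t")
    arch <- buildArchitecture(models, ss, pr)
    emit(arch, "architecture.tsv")
    dasSet <- dasGeneFlags(dasCalls)$gene_id
    if (length(dasSet))
      emit(intronBinEnrichment(dasSet, arch), "enrichment.tsv")
    if (!is.null(config$categories)) {
      cats <- read.delim(config$categories, header = TRUE, sep = "\t")
      tests <- groupArchitectureTests(arch, cats, "ass")
      emit(tests$anova, "anova.tsv")
      emit(tests$tukey, "tukey.tsv")
    }
  }

  if ("ferrome" %in% stages) {
    sets <- lapply(config$geneLists, readGeneList)
    names(sets) <- basename(config$geneLists)
    vote <- consensusVote(sets, k = config$k)
    emit(vote, "ferrome.tsv")
  }

  list(manifest = if (length(manifest)) do.call(rbind, manifest)
                  else data.frame(file = character(0), rows = integer(0)),
       status = 0L)
}

## Read a coverage TSV, deriving the sample design from the sample ids
## (pattern <tissue>_<timepoint>_<trt|ctl>_r<rep> as emitted by the
## synthetic generator); falls back to a single-cell design otherwise.
readCoverageFromFile <- function(path, models) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  sams <- sort(unique(tab$sample_id))
  m <- regmatches(sams, regexec("^(.+)_([^_]+)_(trt|ctl)_r([0-9]+)$", sams))
  parsed <- lengths(m) == 5L
  design <- if (all(parsed)) {
    data.frame(sample_id = sams,
               condition = ifelse(vapply(m, `[`, character(1), 4L) == "trt",
                                  "treated", "control"),
               timepoint = vapply(m, `[`, character(1), 3L),
               replicate = as.integer(vapply(m, `[`, character(1), 5L)),
               tissue = vapply(m, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    stopInput("cannot derive a sample design from sample ids in '%s'", path)
  }
  readCoverageTable(path, models, design)
}
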