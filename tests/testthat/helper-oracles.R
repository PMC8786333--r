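# Independent oracles used by the tests. These re-derive expected values
# from first principles and must stay independent of the package's own
# code paths.

# Literal position-by-position transcription of the running-sum trimming
# rule: error probability from Q, value = cutoff - p, running sum reset
# at zero, retained region between the first positive value of the
# running sum and its (first) highest value, minimum retained length.
oracleTrim <- function(q, cutoff = 0.05, minLength = 35) {
  n <- length(q)
  if (n == 0L) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  S <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + (cutoff - 10^(-q[i] / 10))
    if (s < 0) s <- 0
    S[i] <- s
  }
  m <- max(S)
  if (m <= 0) return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  end <- which(S == m)[1L]
  start <- which(S > 0)[1L]
  if (end - start + 1L < minLength)
    return(list(keep = FALSE, start = NA_integer_, end = NA_integer_))
  list(keep = TRUE, start = as.integer(start), end = as.integer(end))
}

# Trimmed mean of M-values, transcribed from the published method:
# reference = sample whose upper-quartile fraction is closest to the
# mean; M/A over genes nonzero in both; double trim by M and A ranks;
# factor = 2^(precision-weighted mean M) with inverse asymptotic
# binomial variance weights; factors rescaled to geometric mean 1.
oracleTmm <- function(counts, trimM = 0.30, trimA = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    obs <- counts[, k]; rfc <- counts[, ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]; rfc <- rfc[keep]
    M <- log2((obs / lib[k]) / (rfc / lib[ref]))
    A <- 0.5 * log2((obs / lib[k]) * (rfc / lib[ref]))
    w <- (lib[k] - obs) / (lib[k] * obs) + (lib[ref] - rfc) / (lib[ref] * rfc)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
             rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# brute-force k-of-n membership counting
oracleVote <- function(sets, k) {
  genes <- sort(unique(toupper(unlist(sets))))
  votes <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% toupper(s), logical(1))), integer(1))
  genes[votes >= k]
}

# a tiny deterministic two-timepoint design
makeDesign <- function(timepoints = "6h", reps = 3, tissue = "root") {
  do.call(rbind, lapply(timepoints, function(tp) data.frame(
    sample_id = c(sprintf("%s_%s_trt_r%d", tissue, tp, seq_len(reps)),
                  sprintf("%s_%s_ctl_r%d", tissue, tp, seq_len(reps))),
    condition = rep(c("treated", "control"), each = reps),
    timepoint = tp, replicate = rep(seq_len(reps), 2), tissue = tissue,
    stringsAsFactors = FALSE)))
}

# two-gene toy models: G1 = exons [101,200],[301,400],[501,640];
# G2 single exon [1001,1500]
makeToyModels <- function() {
  geneModels(GenomicRanges::GRangesList(
    G1 = GenomicRanges::GRanges("Chr1",
      IRanges::IRanges(c(101, 301, 501), c(200, 400, 640)), strand = "+"),
    G2 = GenomicRanges::GRanges("Chr1",
      IRanges::IRanges(1001, 1500), strand = "-")))
}
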