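#' Quality-score running-sum read trimming
#'
#' For every base the Phred score Q is converted to an error probability
#' p = 10^(-Q/10) and scored v = cutoff - p, negative for low-quality
#' bases. A running sum of v is kept, reset to zero whenever it drops
#' below zero. The retained region runs from the first position where the
#' running sum becomes positive through the position attaining its
#' maximum (ties broken at the first maximum); everything before and
#' after is trimmed, and reads whose retained region is shorter than
#' `minLength` are discarded.
#'
#' When the running sum resets more than once, "first positive value" is
#' ambiguous. The default (`firstPositive = "segment"`) anchors it to the
#' maximal segment: the first positive position after the last reset
#' preceding the chosen maximum, so exactly one contiguous high-quality
#' region is retained. `firstPositive = "global"` takes the first positive
#' position of the whole read, the literal global reading.
#'
#' @param quals integer vector of per-base Phred scores (>= 0).
#' @param cutoff error-probability cutoff (default 0.05).
#' @param minLength minimum retained length in bp (default 35).
#' @param firstPositive `"segment"` (default) or `"global"`; see Details.
#' @return list with `keep` (logical), and when kept, `start` and `end`,
#'   the 1-based closed retained interval. Discarded reads have
#'   `start = end = NA`.
#' @examples
#' trimRead(rep(40L, 50))                    # keep whole read
#' trimRead(c(2L, 2L, rep(20L, 40), 2L, 2L, 2L))  # keep positions 3..42
#' @export
trimRead <- function(quals, cutoff = 0.05, minLength = 35,
                     firstPositive = c("segment", "global")) {
  firstPositive <- match.arg(firstPositive)
  no <- list(keep = FALSE, start = NA_integer_, end = NA_integer_)
  n <- length(quals)
  if (n == 0L) return(no)
  v <- cutoff - 10^(-quals / 10)
  ## running sum with a floor at zero: S_i = C_i - min(0, min_{j<=i} C_j)
  cs <- cumsum(v)
  s <- cs - pmin(cummin(cs), 0)
  m <- max(s)
  if (m <= 0) return(no)
  e <- which.max(s)                      # first index attaining the max
  if (firstPositive == "segment") {
    ## nearest reset (S == 0) at or before the maximum; zero is exact here
    ## because a reset sets S to 0 by construction
    zeros <- which(s[seq_len(e)] == 0)
    start <- if (length(zeros)) max(zeros) + 1L else 1L
  } else {
    start <- which(s > 0)[1L]
  }
  if (e - start + 1L < minLength) return(no)
  list(keep = TRUE, start = as.integer(start), end = as.integer(e))
}

#' Trim a FASTQ file with the running-sum algorithm
#'
#' Reads Sanger FASTQ (Phred+33 by default), applies [trimRead()] to every
#' read and writes the kept reads with trimmed sequence and quality
#' strings. Mate synchronization is available via `dropIds`: ids listed
#' there are discarded regardless of quality, so a paired run can drop
#' both mates when either fails.
#'
#' @param inPath,outPath input and output FASTQ paths.
#' @param cutoff,minLength,firstPositive passed to [trimRead()].
#' @param qualityOffset Phred encoding offset, 33 (default) or 64.
#' @param dropIds optional character vector of read ids to discard.
#' @return list with `n_in`, `n_kept`, `n_discarded` (kept + discarded =
#'   input count) and `trim`, a data.frame of per-read decisions
#'   (read_id, keep, start, end).
#' @export
trimFastq <- function(inPath, outPath, cutoff = 0.05, minLength = 35,
                      firstPositive = c("segment", "global"),
                      qualityOffset = 33, dropIds = character(0)) {
  firstPositive <- match.arg(firstPositive)
  reads <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(inPath),
      error = function(e) stopInput("malformed FASTQ '%s': %s", inPath,
                                    conditionMessage(e))),
    warning = function(w) {
      # Biostrings warns when it drops read-description metadata columns
      # during coercion; irrelevant here, the headers are kept in names()
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qstr <- as(Biostrings::quality(reads), "BStringSet")
  offs <- as.integer(qualityOffset)
  dec <- lapply(seq_along(reads), function(i) {
    q <- as.integer(charToRaw(as.character(qstr[[i]]))) - offs
    trimRead(q, cutoff = cutoff, minLength = minLength,
             firstPositive = firstPositive)
  })
  ids <- sub("\\s.*$", "", names(reads))
  keep <- vapply(dec, `[[`, logical(1), "keep") & !(ids %in% dropIds)
  start <- vapply(dec, `[[`, integer(1), "start")
  end <- vapply(dec, `[[`, integer(1), "end")
  if (any(keep)) {
    sqAll <- as(reads, "DNAStringSet")
    S4Vectors::mcols(sqAll) <- NULL
    sq <- Biostrings::subseq(sqAll[keep], start = start[keep],
                             end = end[keep])
    qq <- Biostrings::subseq(qstr[keep], start = start[keep], end = end[keep])
    out <- Biostrings::QualityScaledDNAStringSet(
      sq, Biostrings::PhredQuality(qq))
    names(out) <- names(reads)[keep]
    Biostrings::writeQualityScaledXStringSet(out, outPath)
  } else {
    file.create(outPath)
  }
  list(n_in = length(reads), n_kept = sum(keep),
       n_discarded = length(reads) - sum(keep),
       trim = data.frame(read_id = ids, keep = keep, start = start,
                         end = end, stringsAsFactors = FALSE))
}
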