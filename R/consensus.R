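#' k-of-n consensus vote over differential-expression gene sets
#'
#' A gene enters the consensus ("ferrome"-style) set when it is reported
#' as differentially expressed in at least `k` of the `n` input datasets.
#' Gene identifiers are normalized to uppercase locus ids before voting.
#' By default voting is direction-agnostic; with
#' `directionConsistent = TRUE` each input must be a data.frame with a
#' `direction` column and a gene needs >= `k` datasets agreeing on the
#' same direction.
#'
#' @param geneSets named list of n datasets: character vectors of gene
#'   ids, or data.frames with `gene_id` (and `direction` for the
#'   direction-consistent mode).
#' @param k vote threshold, 1 <= k <= n; k = 1 gives the union, k = n the
#'   n-way intersection.
#' @param label optional label (e.g. "root") carried into the output.
#' @param directionConsistent require directional agreement.
#' @return data.frame gene_id, votes, selected, label; the consensus set
#'   is `gene_id[selected]`.
#' @export
consensusVote <- function(geneSets, k, label = "",
                          directionConsistent = FALSE) {
  n <- length(geneSets)
  if (k < 1 || k > n)
    stopInput("k = %s out of range [1, %d]", format(k), n)
  norm <- function(x) {
    if (is.data.frame(x)) {
      data.frame(gene_id = toupper(x$gene_id),
                 direction = if ("direction" %in% colnames(x)) x$direction
                             else NA_character_, stringsAsFactors = FALSE)
    } else data.frame(gene_id = toupper(x), direction = NA_character_,
                      stringsAsFactors = FALSE)
  }
  sets <- lapply(geneSets, function(x) unique(norm(x)))
  all <- do.call(rbind, sets)
  votes <- table(all$gene_id)
  genes <- sort(names(votes))
  nv <- as.integer(votes[genes])
  if (directionConsistent) {
    if (any(is.na(all$direction)))
      stopInput("direction-consistent voting needs a direction column in every dataset")
    dirVotes <- table(paste(all$gene_id, all$direction, sep = "\r"))
    best <- vapply(genes, function(g) {
      hits <- dirVotes[startsWith(names(dirVotes), paste0(g, "\r"))]
      max(as.integer(hits))
    }, integer(1))
    selected <- best >= k
  } else {
    selected <- nv >= k
  }
  data.frame(gene_id = genes, votes = nv, selected = selected,
             label = label, stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect two consensus sets
#'
#' Genes selected in both consensus votes (e.g. robust in roots and in
#' shoots), with per-side vote counts as provenance.
#'
#' @param a,b outputs of [consensusVote()].
#' @return data.frame gene_id, votes_a, votes_b, label_a, label_b.
#' @export
consensusIntersection <- function(a, b) {
  ga <- a[a$selected, , drop = FALSE]
  gb <- b[b$selected, , drop = FALSE]
  common <- sort(intersect(ga$gene_id, gb$gene_id))
  data.frame(gene_id = common,
             votes_a = ga$votes[match(common, ga$gene_id)],
             votes_b = gb$votes[match(common, gb$gene_id)],
             label_a = rep_len(if (nrow(ga)) ga$label[1] else
                               NA_character_, length(common)),
             label_b = rep_len(if (nrow(gb)) gb$label[1] else
                               NA_character_, length(common)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a dataset gene list for consensus voting
#'
#' One gene per line: `gene_id` optionally followed by a tab and a
#' direction (up/down). A header line is detected and skipped.
#'
#' @param path TSV path.
#' @return data.frame gene_id, direction (NA when absent).
#' @export
readGeneList <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(tab) && tolower(tab[1, 1]) == "gene_id")
    tab <- tab[-1, , drop = FALSE]
  data.frame(gene_id = as.character(tab[[1]]),
             direction = if (ncol(tab) >= 2) as.character(tab[[2]])
                         else NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}
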