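# coverage with hand-set signals on the toy models (G1: 3 exons, 2 introns)
makeToyCoverage <- function(intron1 = NULL, gene = NULL, junction = NULL,
                            skip = NULL, design = makeDesign()) {
  sams <- design$sample_id
  gc <- matrix(600, 2, 6, dimnames = list(c("G1", "G2"), sams))
  if (!is.null(gene)) gc["G1", ] <- gene
  ed <- matrix(20, 4, 6, dimnames = list(c("G1:1", "G1:2", "G1:3", "G2:1"),
                                         sams))
  idp <- matrix(0, 2, 6, dimnames = list(c("G1:1", "G1:2"), sams))
  if (!is.null(intron1)) idp["G1:1", ] <- intron1
  jc <- if (is.null(junction)) {
    matrix(numeric(0), 0, 6, dimnames = list(NULL, sams))
  } else matrix(junction$counts, 1, 6,
                dimnames = list(junction$key, sams))
  sk <- if (is.null(skip)) {
    matrix(numeric(0), 0, 6, dimnames = list(NULL, sams))
  } else matrix(skip$counts, 1, 6, dimnames = list(paste0("G1:", skip$exon),
                                                   sams))
  coverageTable(gc, ed, idp, jc, sk, design = design)
}

test_that("IR and background ratios follow their closed forms", {
  expect_equal(irRatio(10, 20, 20), 0.5)
  expect_equal(irRatio(0, 20, 20), 0)
  expect_true(is.na(irRatio(5, 0, 0)))
  expect_equal(backgroundRatio(6, 600), 0.01)
  expect_equal(backgroundRatio(0, 600), 0)
  expect_true(is.na(backgroundRatio(4, 0)))
  # scale invariance of the IR ratio
  expect_equal(irRatio(10 * 7, 20 * 7, 20 * 7), irRatio(10, 20, 20))
})

test_that("event extraction classifies IR, DA and ES correctly", {
  # annotated junctions of G1: 200->301 (intron 1), 400->501 (intron 2)
  cov <- makeToyCoverage(intron1 = 10,
                         junction = list(key = "G1:200:316", counts = 6),
                         skip = list(exon = 2, counts = 3))
  ev <- extractEvents(cov, makeToyModels())
  info <- eventInfo(ev)
  expect_setequal(info$event_id[info$type == "IR"], "G1:IR:1")
  expect_equal(info$event_id[info$type == "DA"], "G1:DA:200:316")
  expect_equal(info$event_id[info$type == "ES"], "G1:ES:2")
  expect_equal(unname(eventRatios(ev)["G1:IR:1", 1]), 10 / 20)
  expect_equal(unname(eventRatios(ev)["G1:DA:200:316", 1]), 6 / 600)
  # an exon-skipping junction (exon1 donor -> exon3 acceptor) becomes ES
  cov2 <- makeToyCoverage(junction = list(key = "G1:200:501", counts = 4))
  info2 <- eventInfo(extractEvents(cov2, makeToyModels()))
  expect_equal(info2$event_id[info2$type == "ES"], "G1:ES:2")
  # an annotated junction is not an event; an unmatched one is ignored
  cov3 <- makeToyCoverage(junction = list(key = "G1:200:301", counts = 50))
  expect_equal(nrow(eventInfo(extractEvents(cov3, makeToyModels()))), 0L)
  cov4 <- makeToyCoverage(junction = list(key = "G1:777:888", counts = 5))
  expect_message(ev4 <- extractEvents(cov4, makeToyModels()),
                 "no annotated boundary")
  expect_equal(nrow(eventInfo(ev4)), 0L)
})

test_that("a strict 2-fold boundary is not called, a clear effect is", {
  # treated 0.5 vs control 0.25: FC exactly 2 fails the strict filter
  cov <- makeToyCoverage(intron1 = c(10, 10, 10, 5, 5, 5))
  calls <- callDas(extractEvents(cov, makeToyModels()))
  expect_equal(calls$fold_change, 2)
  expect_false(calls$is_das)
  expect_equal(calls$direction, "enhanced")
  # clear effect matches an independent t-test and is called
  tr <- c(0.6, 0.5, 0.55) * 20; ct <- c(0.1, 0.12, 0.11) * 20
  cov2 <- makeToyCoverage(intron1 = c(tr, ct))
  calls2 <- callDas(extractEvents(cov2, makeToyModels()))
  ref <- t.test(tr / 20, ct / 20, var.equal = TRUE)
  expect_equal(calls2$p_value, ref$p.value)
  expect_true(calls2$is_das)
  expect_gt(calls2$fold_change, 4)
  expect_equal(calls2$direction, "enhanced")
})

test_that("presence and definedness gate the DAS call", {
  # signal present in only 2/3 treated replicates and absent in control
  cov <- makeToyCoverage(intron1 = c(12, 12, 0, 0, 0, 0))
  calls <- callDas(extractEvents(cov, makeToyModels()))
  expect_false(calls$observed_all_replicates)
  expect_false(calls$is_das)
  # present in all control replicates only: reduced events are callable
  cov2 <- makeToyCoverage(intron1 = c(0, 0, 0, 12, 11, 13))
  calls2 <- callDas(extractEvents(cov2, makeToyModels()))
  expect_true(calls2$observed_all_replicates)
  expect_equal(calls2$direction, "reduced")
  expect_true(calls2$is_das)
})

test_that("direction flips under group swap and expression scaling is absorbed", {
  cov <- makeToyCoverage(intron1 = c(12, 11, 13, 3, 3.5, 2.5))
  call1 <- callDas(extractEvents(cov, makeToyModels()))
  swapped <- makeToyCoverage(intron1 = c(3, 3.5, 2.5, 12, 11, 13))
  call2 <- callDas(extractEvents(swapped, makeToyModels()))
  expect_equal(call1$p_value, call2$p_value)
  expect_equal(call1$fold_change, 1 / call2$fold_change)
  expect_equal(call1$direction, "enhanced")
  expect_equal(call2$direction, "reduced")
  # doubling gene expression in treated leaves DA ratios unchanged
  cov3 <- makeToyCoverage(gene = c(1200, 1200, 1200, 600, 600, 600),
                          junction = list(key = "G1:200:316",
                                          counts = c(12, 12, 12, 6, 6, 6)))
  calls3 <- callDas(extractEvents(cov3, makeToyModels()))
  da <- calls3[calls3$type == "DA", ]
  expect_equal(da$fold_change, 1)
  expect_false(da$is_das)
})

test_that("gene-level type summary counts multi-type genes once per type", {
  calls <- data.frame(
    event_id = sprintf("E%d", 1:12),
    gene_id = c(paste0("g", 1:8), "g9", "g9", "g10", "g11"),
    type = c(rep("IR", 8), "DA", "IR", "DA", "ES"),
    timepoint = "6h", is_das = TRUE, stringsAsFactors = FALSE)
  s <- dasTypeSummary(calls)
  expect_equal(s$n_genes[s$type == "DIR"], 9L)   # g1..g8, g9
  expect_equal(s$n_genes[s$type == "DDA"], 2L)   # g9, g10
  expect_equal(s$n_genes[s$type == "DES"], 1L)
  expect_equal(s$fraction[s$type == "DIR"], 9 / 11)
  expect_equal(s$fraction[s$type == "DDA"], 2 / 11)
  # no calls at all
  s0 <- dasTypeSummary(calls[calls$type == "none", ])
  expect_true(all(s0$n_genes == 0) && all(s0$fraction == 0))
})
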