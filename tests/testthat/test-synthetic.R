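test_that("the generator is deterministic under a fixed seed", {
  cfg <- syntheticConfig(nGenes = 40, seed = 123, timepoints = c("0.5h", "6h"))
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_equal(geneCounts(d1$coverage[["6h"]]), geneCounts(d2$coverage[["6h"]]))
  expect_equal(intronDepth(d1$coverage[["0.5h"]]),
               intronDepth(d2$coverage[["0.5h"]]))
  expect_identical(d1$truth$de, d2$truth$de)
  expect_identical(d1$truth$events, d2$truth$events)
  # and serialized output is byte-identical
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- writeSyntheticDataset(d1, dir1)
  p2 <- writeSyntheticDataset(d2, dir2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  # a different seed changes the data
  d3 <- generateDataset(syntheticConfig(nGenes = 40, seed = 124,
                                        timepoints = c("0.5h", "6h")))
  expect_false(identical(geneCounts(d3$coverage[["6h"]]),
                         geneCounts(d1$coverage[["6h"]])))
})

test_that("emitted tables pass the package validators and round-trip", {
  ds <- generateDataset(syntheticConfig(nGenes = 30, seed = 15,
                                        timepoints = "6h"))
  expect_true(methods::validObject(ds$models))
  expect_true(methods::validObject(ds$coverage[["6h"]]))
  dir <- withr::local_tempdir()
  paths <- writeSyntheticDataset(ds, dir)
  gm <- readGeneModels(paths[["models"]])
  expect_equal(geneIds(gm), geneIds(ds$models))
  cov <- readCoverageTable(paths[["coverage_6h"]], gm,
                           sampleDesign(ds$coverage[["6h"]]))
  expect_equal(geneCounts(cov), geneCounts(ds$coverage[["6h"]]))
  # every injected event exists in the emitted coverage table
  ev <- extractEvents(ds$coverage[["6h"]], ds$models)
  expect_true(all(ds$truth$events$event_id %in% eventInfo(ev)$event_id))
})

test_that("generated gene counts match the configured mean and dispersion", {
  cfg <- syntheticConfig(nGenes = 2000, seed = 16, timepoints = "6h",
                         replicates = 10, deFraction = 0, irFraction = 0,
                         daFraction = 0, esFraction = 0)
  ds <- generateDataset(cfg)
  gc <- geneCounts(ds$coverage[["6h"]])
  mu <- ds$truth$genes$mean_depth * ds$truth$genes$gene_length / 100
  m <- rowMeans(gc)
  expect_lt(abs(mean(m / mu) - 1), 0.05)
  # moment estimate of the dispersion: mean over genes of (var-mu)/mu^2
  v <- apply(gc, 1, var)
  alphaHat <- mean((v - m) / m^2)
  expect_lt(abs(alphaHat - 0.1) / 0.1, 0.05)
})

test_that("infeasible configurations are rejected before any output", {
  expect_error(syntheticConfig(nGenes = 10, irFraction = 1.5), "fraction")
  expect_error(syntheticConfig(nGenes = 10, irEffect = 0.5), "effect")
  expect_error(syntheticConfig(nGenes = 10, replicates = 1), "replicates")
  expect_error(syntheticConfig(nGenes = 10, bogus = 1), "bogus")
})

test_that("FASTQ generation encodes the designed quality profile", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- generateFastq(fq, nReads = 10,
                         profile = list(list(len = 2, q = 2),
                                        list(len = 40, q = 20),
                                        list(len = 3, q = 2)), seed = 17)
  expect_true(all(truth$keep))
  expect_true(all(truth$start == 3 & truth$end == 42))
  # all-good and all-bad profiles
  tGood <- generateFastq(fq, 5, list(list(len = 50, q = 35)), seed = 18)
  expect_true(all(tGood$start == 1 & tGood$end == 50))
  tBad <- generateFastq(fq, 5, list(list(len = 50, q = 3)), seed = 19)
  expect_false(any(tBad$keep))
})

test_that("consensus input generator truth matches its own files", {
  gen <- generateConsensusInputs(nDatasets = 7, nGenes = 100, seed = 20)
  counted <- vapply(gen$truth$gene_id, function(g)
    sum(vapply(gen$sets, function(s) g %in% s, logical(1))), integer(1))
  expect_equal(unname(counted), gen$truth$votes)
})
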