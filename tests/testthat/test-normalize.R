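test_that("TMM factors are 1 for identical and globally scaled columns", {
  set.seed(21)
  base <- rnbinom(200, mu = 100, size = 10) + 1
  counts <- cbind(s1 = base, s2 = base)
  expect_equal(unname(tmmFactors(counts)), c(1, 1))
  # column scaled 2x: scale absorbed by library size, factors stay 1
  counts2 <- cbind(s1 = base, s2 = 2 * base)
  expect_equal(unname(tmmFactors(counts2)), c(1, 1))
  # invariance under global rescaling of any column (up to the
  # count-precision weights, which depend on absolute depth)
  counts3 <- cbind(s1 = base, s2 = rnbinom(200, mu = 100, size = 10) + 1,
                   s3 = rnbinom(200, mu = 80, size = 10) + 1)
  f <- tmmFactors(counts3)
  counts3[, 2] <- counts3[, 2] * 5
  expect_equal(unname(tmmFactors(counts3)), unname(f), tolerance = 0.01)
})

test_that("toy-table TMM factor equals the hand-computed weighted trimmed mean", {
  # 10 genes, 3 inflated 8x in sample B
  counts <- cbind(A = c(100, 200, 300, 150, 80, 120, 250, 90, 60, 400),
                  B = c(100, 200, 300, 150, 80, 120, 8 * 250, 8 * 90,
                        8 * 60, 400))
  expect_equal(unname(tmmFactors(counts)), unname(oracleTmm(counts)),
               tolerance = 1e-8)
  # and on a random table without zeros
  set.seed(22)
  r <- matrix(rnbinom(600, mu = 200, size = 5) + 1, ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(tmmFactors(r)), unname(oracleTmm(r)),
               tolerance = 1e-8)
})

test_that("logCPM matches its closed form and is increasing in count", {
  # count 0 at effective library 1e6: log2(0.5) = -1
  m <- matrix(0, 1, 1, dimnames = list("g", "s"))
  expect_equal(logCpm(m, normFactors = 1, libSizes = 1e6 - 1)[1, 1], -1)
  # count + 0.5 = 1024 at effective library 1e6: log2(1024) = 10
  m[1, 1] <- 1023.5
  expect_equal(logCpm(m, normFactors = 1, libSizes = 1e6 - 1)[1, 1], 10)
  # doubling (count + 0.5) adds exactly 1
  m2 <- matrix(c(41, 82.5), 2, 1, dimnames = list(c("a", "b"), "s"))
  lc <- logCpm(m2, normFactors = 1, libSizes = 5e5)
  expect_equal(lc[2, 1] - lc[1, 1], 1)
  # agreement with the voom transform on a realistic matrix
  skip_if_not_installed("limma")
  set.seed(23)
  cm <- matrix(rnbinom(400, mu = 150, size = 5), ncol = 4,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  f <- tmmFactors(cm)
  v <- limma::voom(cm, lib.size = colSums(cm) * f)
  expect_equal(unname(logCpm(cm, f)), unname(v$E), tolerance = 1e-10)
})

test_that("RPKM follows 2^logcpm scaled by length, threshold is sqrt of mean", {
  lc <- matrix(3, 1, 1, dimnames = list("g", "s"))   # CPM 8
  r <- rpkmFromLogcpm(lc, c(g = 2000))
  expect_equal(r$rpkm[1, 1], 4)                      # 8 / 2
  expect_equal(r$relevanceThreshold, 2)              # sqrt(4)
  set.seed(24)
  lc2 <- matrix(rnorm(60), 20, 3,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  len <- setNames(sample(500:3000, 20), paste0("g", 1:20))
  r2 <- rpkmFromLogcpm(lc2, len)
  expect_equal(r2$relevanceThreshold, sqrt(mean(2^lc2 / (len / 1000))))
  # RPKM strictly decreasing in gene length
  r3 <- rpkmFromLogcpm(lc, c(g = 4000))
  expect_lt(r3$rpkm[1, 1], r$rpkm[1, 1])
  expect_error(rpkmFromLogcpm(lc, c(g = 0)), "g")
})

test_that("normalizeExpression drops all-zero genes and validates", {
  ds <- generateDataset(syntheticConfig(nGenes = 60, seed = 25,
                                        timepoints = "6h"))
  cov <- ds$coverage[["6h"]]
  gcz <- geneCounts(cov)
  gcz[3, ] <- 0
  covz <- coverageTable(gcz, exonDepth(cov), intronDepth(cov),
                        junctionCounts(cov), skipCounts(cov),
                        design = sampleDesign(cov))
  expr <- normalizeExpression(covz, ds$models)
  expect_false(rownames(gcz)[3] %in% rownames(rpkm(expr)))
  expect_equal(exp(mean(log(normFactors(expr)))), 1, tolerance = 1e-9)
  expect_true(all(rpkm(expr) >= 0))
})
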