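# small NormalizedExpression built directly for caller-level tests
makeExpr <- function(rpkmMat, threshold = 1, design = makeDesign()) {
  lc <- log2(rpkmMat + 1e-9)
  methods::new("NormalizedExpression", logcpm = lc, rpkm = rpkmMat,
               normFactors = rep(1, ncol(rpkmMat)),
               libSizes = rep(1e6, ncol(rpkmMat)),
               geneLengths = setNames(rep(1000, nrow(rpkmMat)),
                                      rownames(rpkmMat)),
               relevanceThreshold = threshold, design = design)
}

test_that("identical groups give p = 1 and no DE call", {
  r <- matrix(4, 1, 6, dimnames = list("g1", makeDesign()$sample_id))
  calls <- callDE(makeExpr(r))
  expect_equal(calls$p_value, 1)
  expect_false(calls$is_de)
})

test_that("a clear 4-fold difference is called DE and matches t.test", {
  r <- matrix(c(8, 8.1, 7.9, 2, 2.05, 1.95), 1, 6,
              dimnames = list("g1", makeDesign()$sample_id))
  calls <- callDE(makeExpr(r, threshold = 1))
  ref <- t.test(c(8, 8.1, 7.9), c(2, 2.05, 1.95), var.equal = TRUE)
  expect_equal(calls$p_value, ref$p.value)
  expect_lt(calls$p_value, 0.05)
  expect_equal(calls$fold_change, mean(c(8, 8.1, 7.9)) / 2, tolerance = 0.05)
  expect_true(calls$is_de)
  expect_equal(calls$direction, "up")
  # Welch flag agrees with t.test default
  callsW <- callDE(makeExpr(r, threshold = 1), varEqual = FALSE)
  expect_equal(callsW$p_value, t.test(c(8, 8.1, 7.9),
                                      c(2, 2.05, 1.95))$p.value)
})

test_that("swapping group labels flips direction and inverts fold-change", {
  set.seed(31)
  r <- matrix(rgamma(30, 4), 5, 6,
              dimnames = list(paste0("g", 1:5), makeDesign()$sample_id))
  a <- callDE(makeExpr(r))
  design2 <- makeDesign()
  design2$condition <- rev(design2$condition)
  r2 <- r[, c(4:6, 1:3)]
  colnames(r2) <- colnames(r)
  b <- callDE(makeExpr(r2))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold_change, 1 / b$fold_change)
  expect_equal(a$direction == "up", b$direction == "down")
})

test_that("relevance gate and infinite fold-change behave per the rule", {
  des <- makeDesign()
  r <- rbind(lowxp = c(0.4, 0.5, 0.45, 0.1, 0.12, 0.11),
             zeroctl = c(5, 6, 5.5, 0, 0, 0))
  colnames(r) <- des$sample_id
  calls <- callDE(makeExpr(r, threshold = 1))
  expect_false(calls$relevant[calls$gene_id == "lowxp"])
  expect_false(calls$is_de[calls$gene_id == "lowxp"])
  z <- calls[calls$gene_id == "zeroctl", ]
  expect_equal(z$fold_change, Inf)
  expect_true(z$is_de)   # infinite FC passes the filter
  # requiring relevance in both groups excludes the zero-control gene
  both <- callDE(makeExpr(r, threshold = 1), relevance = "both")
  expect_false(both$is_de[both$gene_id == "zeroctl"])
})

test_that("overlap counts partition the union", {
  ov <- setOverlap(list(t1 = c("A", "B"), t2 = c("B", "C")))
  expect_equal(sum(ov$count), 3)
  expect_equal(ov$count[ov$pattern == "t1&t2"], 1L)
  expect_equal(ov$count[ov$pattern == "t1"], 1L)
  # identical sets: all mass in the intersection
  ov2 <- setOverlap(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_equal(ov2$count[ov2$pattern == "a&b"], 2L)
  expect_equal(nrow(ov2), 1L)
  # three random sets match brute-force enumeration
  set.seed(32)
  sets <- lapply(1:3, function(i) sample(LETTERS, 10))
  names(sets) <- c("x", "y", "z")
  ov3 <- setOverlap(sets)
  expect_equal(sum(ov3$count), length(unique(unlist(sets))))
  for (g in unique(unlist(sets))) {
    pat <- paste(names(sets)[vapply(sets, function(s) g %in% s,
                                    logical(1))], collapse = "&")
    expect_true(pat %in% ov3$pattern)
  }
})
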