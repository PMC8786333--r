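test_that("ASS is exactly the mean of the two minima", {
  expect_identical(averageSpliceSiteStrength(-2, 4), 1)
  expect_identical(averageSpliceSiteStrength(0, 0), 0)
  expect_equal(averageSpliceSiteStrength(-6.3, -1.1), -3.7)
  expect_true(is.na(averageSpliceSiteStrength(NA_real_, 3)))
})

test_that("architecture records join scores and promoters, keep NA for gaps", {
  gm <- makeToyModels()   # G1: 2 introns, G2: none
  scores <- data.frame(gene_id = c("G1", "G1"), intron_index = 1:2,
                       score_5ss = c(2, -1), score_3ss = c(3, 0.5))
  prom <- data.frame(gene_id = "G2", promoter_length = 1200L,
                     tfbs_count = 20L)
  rec <- buildArchitecture(gm, scores, prom)
  g1 <- rec[rec$gene_id == "G1", ]
  expect_equal(g1$min_5ss, -1)
  expect_equal(g1$min_3ss, 0.5)
  expect_equal(g1$ass, -0.25)
  expect_equal(g1$intron_count, 2L)
  expect_equal(g1$intron_lengths, "100,100")
  expect_true(is.na(g1$promoter_length))  # absent from promoter table
  g2 <- rec[rec$gene_id == "G2", ]
  expect_true(is.na(g2$ass))              # no introns, no splice sites
  expect_equal(g2$promoter_length, 1200L)
  # ass == (min5+min3)/2 to machine precision on generated data
  ds <- generateDataset(syntheticConfig(nGenes = 50, seed = 8,
                                        timepoints = "6h"))
  arch <- buildArchitecture(ds$models, ds$spliceScores, ds$promoters)
  ok <- !is.na(arch$ass)
  expect_identical(arch$ass[ok], (arch$min_5ss[ok] + arch$min_3ss[ok]) / 2)
  # unknown intron index is an error
  badScores <- data.frame(gene_id = "G2", intron_index = 1,
                          score_5ss = 1, score_3ss = 1)
  expect_error(buildArchitecture(gm, badScores, NULL), "G2")
})

test_that("intron-bin enrichment is 1 when the set is the background", {
  set.seed(51)
  bg <- data.frame(gene_id = paste0("g", 1:300),
                   intron_count = rnbinom(300, mu = 6, size = 2))
  enr <- intronBinEnrichment(bg$gene_id, bg)
  expect_true(all(abs(enr$enrichment[enr$n_background > 0] - 1) < 1e-12))
  # set concentrated in one bin
  one <- bg$gene_id[bg$intron_count == 0]
  enr2 <- intronBinEnrichment(one, bg)
  expect_equal(enr2$enrichment[enr2$bin == "0"],
               nrow(bg) / sum(bg$intron_count == 0))
  expect_true(all(enr2$enrichment[enr2$bin != "0" & enr2$n_background > 0]
                  == 0))
  expect_error(intronBinEnrichment(character(0), bg), "empty")
  # weighted average of enrichment by background fractions is 1
  w <- enr$n_background / sum(enr$n_background)
  expect_equal(sum(w * enr$enrichment, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("group tests match aov/TukeyHSD and flag clear group effects", {
  # groups with identical value sets: zero group effect, nothing significant
  rec <- data.frame(gene_id = paste0("g", 1:20), ass = rep(1:10, 2))
  grp <- data.frame(gene_id = paste0("g", 1:20),
                    group = rep(c("a", "b"), each = 10))
  res <- groupArchitectureTests(rec, grp, "ass")
  expect_equal(res$anova$f_value[res$anova$effect == "group"], 0)
  expect_true(all(res$tukey$p_adj > 0.9))
  # two groups 3 sd apart: highly significant
  set.seed(52)
  rec2 <- data.frame(gene_id = paste0("g", 1:100),
                     ass = c(rnorm(50, 0), rnorm(50, 3)))
  grp2 <- data.frame(gene_id = paste0("g", 1:100),
                     group = rep(c("lo", "hi"), each = 50))
  res2 <- groupArchitectureTests(rec2, grp2, "ass")
  expect_lt(res2$anova$p_value[res2$anova$effect == "group"], 0.001)
  expect_equal(res2$group_stats$n, c(50L, 50L))
  # three-group Tukey p-values equal the reference implementation
  set.seed(53)
  rec3 <- data.frame(gene_id = paste0("g", 1:15),
                     ass = rnorm(15, rep(c(0, 1, 3), each = 5)))
  grp3 <- data.frame(gene_id = paste0("g", 1:15),
                     group = rep(c("a", "b", "c"), each = 5))
  res3 <- groupArchitectureTests(rec3, grp3, "ass")
  d <- merge(grp3, rec3)
  ref <- TukeyHSD(aov(ass ~ group, data = d))$group
  expect_equal(res3$tukey$p_adj, unname(ref[, "p adj"]))
  # two-way layout uses tissue as second factor
  grp4 <- rbind(cbind(grp2, tissue = "root"),
                transform(cbind(grp2, tissue = "shoot"),
                          gene_id = paste0(gene_id, "s")))
  rec4 <- rbind(rec2, transform(rec2, gene_id = paste0(gene_id, "s"),
                                ass = ass + 0.5))
  res4 <- groupArchitectureTests(rec4, grp4, "ass")
  expect_true("tissue" %in% res4$anova$effect)
  # a group with < 2 observations is excluded with a warning
  grp5 <- rbind(grp2, data.frame(gene_id = "solo", group = "tiny"))
  rec5 <- rbind(rec2, data.frame(gene_id = "solo", ass = 9))
  expect_warning(groupArchitectureTests(rec5, grp5, "ass"), "tiny")
})

test_that("logistic coupling of mode propensity recovers coefficient signs", {
  set.seed(54)
  ds <- generateDataset(syntheticConfig(
    nGenes = 2000, seed = 54, timepoints = "6h",
    couplingBeta = c(0, 0.15, -0.3)))
  arch <- buildArchitecture(ds$models, ds$spliceScores, ds$promoters)
  injected <- unique(ds$truth$events$gene_id[ds$truth$events$type == "IR"])
  fit <- architectureModeRegression(arch, injected)
  expect_gt(fit$estimate[fit$term == "intron_count"], 0)
  expect_lt(fit$estimate[fit$term == "ass"], 0)
  expect_lt(fit$p_value[fit$term == "intron_count"], 0.05)
})
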