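ctTable <- function(dctTreated, dctControl, refCt = 20) {
  n <- length(dctTreated) + length(dctControl)
  samples <- paste0("s", seq_len(n))
  groups <- rep(c("treated", "control"),
                c(length(dctTreated), length(dctControl)))
  rbind(
    data.frame(sample = samples, group = groups, gene = "tgt",
               ct = refCt + c(dctTreated, dctControl)),
    data.frame(sample = samples, group = groups, gene = "ref", ct = refCt))
}

test_that("ddct implements the comparative-Ct arithmetic", {
  r <- ddct(ctTable(5, c(4, 4)), "tgt", "ref", controlGroup = "control")
  per <- r$perSample
  expect_equal(per$ddct[per$group == "treated"], 1)
  expect_equal(per$foldChange[per$group == "treated"], 0.5)

  same <- ddct(ctTable(c(4, 4), c(4, 4)), "tgt", "ref", "control")
  expect_equal(same$summary$meanFoldChange, c(1, 1))
  expect_equal(same$summary$knockdownPercent[1L], 0)

  # fold changes are scale-free in Ct
  base <- ctTable(c(4.7, 5.2, 4.9), c(4.0, 4.1, 3.9))
  shifted <- base
  shifted$ct <- shifted$ct + 3.3
  expect_equal(ddct(base, "tgt", "ref", "control")$perSample$foldChange,
               ddct(shifted, "tgt", "ref", "control")$perSample$foldChange)

  expect_error(ddct(ctTable(5, 4)[-4, ], "tgt", "ref", "control"),
               "reference gene")
  expect_error(ddct(ctTable(5, 4), "tgt", "ref", "mockery"), "control group")
})

test_that("the synthetic knockdown table recovers ~40% knockdown", {
  path <- system.file("extdata", "synthetic_ct_fig1d_like.tsv",
                      package = "siRNAscreen")
  r <- ddct(loadCtTable(path), "eGFP", "HKG4", controlGroup = "srGFP",
            alternative = "greater")
  kd <- r$summary$knockdownPercent[r$summary$group == "eGFP_dsRNA"]
  expect_equal(kd, 40, tolerance = 0.05)
  expect_lt(r$tests$p, 0.05)
})

test_that("band normalization cancels loading and exposure", {
  mk <- function(protein, gapdh, membrane = "m1") {
    data.frame(membrane = membrane,
               sample = rep(c("a", "b"), 2),
               group = rep(c("ctrl", "trt"), 2),
               protein = rep(c("AGO2", "GAPDH"), each = 2),
               intensity = c(protein, gapdh))
  }
  prop <- bandNorm(mk(c(2, 4), c(2, 4)), controlGroup = "ctrl")
  expect_equal(prop$folds$foldChange, c(1, 1))

  uneq <- bandNorm(mk(c(4, 2), c(4, 4)), controlGroup = "ctrl")
  expect_equal(sort(uneq$folds$ratio), c(0.5, 1))
  expect_equal(uneq$folds$foldChange[uneq$folds$group == "trt"], 0.5)

  # multiplying a membrane by a constant changes nothing downstream
  twoMem <- rbind(mk(c(4, 2), c(4, 4), "m1"), mk(c(8, 4), c(8, 8), "m2"))
  scaled <- twoMem
  scaled$intensity[scaled$membrane == "m2"] <-
    scaled$intensity[scaled$membrane == "m2"] * 7.5
  expect_equal(bandNorm(twoMem, "ctrl")$folds$foldChange,
               bandNorm(scaled, "ctrl")$folds$foldChange)

  noGapdh <- mk(c(4, 2), c(4, 4))[-3, ]
  expect_error(bandNorm(noGapdh, "ctrl"), "GAPDH")
  dark <- mk(c(0, 0), c(0, 0))
  expect_error(bandNorm(dark, "ctrl"), "no signal")
})

test_that("fluorescence summaries subtract background per embryo", {
  flat <- data.frame(replicate = rep(1:2, each = 4),
                     group = "a", embryo = 1:8,
                     mean_intensity = 10, background_intensity = 2)
  expect_warning(fs <- fluorSummary(flat), "20-30")
  expect_true(all(fs$replicates$net == 8))

  two <- rbind(flat, within(flat, group <- "b"))
  expect_warning(fs2 <- fluorSummary(two), "20-30")
  expect_equal(fs2$tests$p, 1)

  clamped <- flat
  clamped$background_intensity[1L] <- 99
  expect_warning(expect_warning(fluorSummary(clamped), "clamped"), "20-30")

  set.seed(17)
  sim <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(replicate = r,
               group = rep(c("hi", "lo"), each = 25),
               embryo = 1:50,
               mean_intensity = c(rnorm(25, 10), rnorm(25, 8)),
               background_intensity = 2)
  }))
  fs3 <- fluorSummary(sim)
  expect_lt(fs3$tests$p, 0.05)
  diff <- mean(fs3$replicates$net[fs3$replicates$group == "hi"]) -
    mean(fs3$replicates$net[fs3$replicates$group == "lo"])
  expect_equal(diff, 2, tolerance = 0.3)
})

test_that("miRNA guide filter keeps guides with >= 2 reads somewhere", {
  mirs <- as.character(bundleMirnas(tinyBundle))
  mkLib <- function(c1, c2) {
    reads <- c(rep(mirs[1L], c1), rep(mirs[2L], c2),
               craftReads(spike = c(2L, 2L, 2L, 2L), targetStarts = 160L))
    assignReads(reads, tinyBundle)
  }
  libs <- list(mkLib(1L, 2L), mkLib(1L, 0L), mkLib(1L, 0L))
  mt <- mirnaTotals(libs)
  expect_false(names(bundleMirnas(tinyBundle))[1L] %in% mt$kept)  # {1,1,1}
  expect_true(names(bundleMirnas(tinyBundle))[2L] %in% mt$kept)   # {2,0,0}
  expect_equal(unname(mt$totals), c(2, 0, 0))
  expect_equal(unname(mt$normalizedTotals), c(1, 0, 0))

  none <- mirnaTotals(list(mkLib(1L, 1L)))
  expect_identical(length(none$kept), 0L)
  expect_equal(unname(none$totals), 0)
})

test_that("the test battery matches independently coded references", {
  flat <- testBattery(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                      "anova_tukey")
  expect_equal(flat$omnibus$statistic, 0)
  expect_true(all(flat$pairwise$p > 0.99))

  values <- c(1, 2, 3, 1, 2, 3, 10, 11, 12)
  group <- rep(c("a", "b", "c"), each = 3)
  got <- testBattery(values, group, "anova_tukey")
  want <- oracleAnovaTukey(values, group)
  expect_equal(got$omnibus$statistic, want$F, tolerance = 1e-9)
  expect_equal(got$omnibus$p, want$p, tolerance = 1e-9)
  key <- paste(got$pairwise$group1, got$pairwise$group2)
  wkey <- paste(want$tukey$group1, want$tukey$group2)
  expect_equal(got$pairwise$p, want$tukey$p[match(key, wkey)],
               tolerance = 1e-9)
  flagged <- got$pairwise$p < 0.05
  expect_identical(sum(flagged), 2L)
  expect_true(all(grepl("c", paste(got$pairwise$group1,
                                   got$pairwise$group2)[flagged])))

  expect_error(testBattery(rep(5, 6), rep(c("a", "b"), each = 3),
                           "t_two_tailed"), "degenerate")
  expect_error(testBattery(values[1:6], group[1:6], "t_one_tailed"),
               "alternative")
  # rank tests proceed (no error) on degenerate data
  rank <- testBattery(rep(5, 6), rep(c("a", "b"), each = 3), "mann_whitney")
  expect_identical(nrow(rank$pairwise), 1L)
})

test_that("Wilcoxon/BH route matches enumeration and step-up oracles", {
  set.seed(23)
  for (i in 1:5) {
    x <- sample(seq(1, 200, by = 3), 4)
    y <- sample(seq(2, 200, by = 3), 4)
    z <- sample(seq(3, 198, by = 3), 4)
    got <- testBattery(c(x, y, z), rep(c("a", "b", "c"), each = 4),
                       "kruskal_wilcoxon_fdr")
    want <- list(oracleWilcoxExact(x, y), oracleWilcoxExact(x, z),
                 oracleWilcoxExact(y, z))
    expect_equal(got$pairwise$p, vapply(want, `[[`, 0, "p"),
                 tolerance = 1e-12)
    expect_equal(got$pairwise$p.adj, oracleBH(got$pairwise$p),
                 tolerance = 1e-12)
    # BH is monotone and never below the raw p-value
    o <- order(got$pairwise$p)
    expect_true(all(diff(got$pairwise$p.adj[o]) >= -1e-15))
    expect_true(all(got$pairwise$p.adj >= got$pairwise$p - 1e-15))
  }
})
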