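test_that("spike-in and RPM normalization follow the declared arithmetic", {
  reads <- craftReads(spike = c(8L, 10L, 12L, 10L), mirna = 5L,
                      targetStarts = rep(c(160L, 200L), c(30L, 20L)))
  asg <- assignReads(reads, tinyBundle)
  norm <- normalizeCounts(asg)
  expect_equal(norm$spikeinFactor, 10)
  expect_equal(norm$spikeinNormalized, 5)           # 50 / mean{8,10,12,10}
  expect_equal(norm$raw, 50)
  expect_equal(norm$rpm, 1e6)                       # denominator = genome+target
  expect_equal(norm$spikeinNormalized * norm$spikeinFactor, norm$raw)

  normF <- normalizeCounts(asg, denominator = "filtered_total")
  expect_equal(normF$rpm, 50 * 1e6 / sum(compartmentCounts(asg)))

  # uniform depth rescaling leaves the spike-in-normalized count unchanged
  col <- collapseReads(reads)
  col$count <- col$count * 3L
  asg3 <- assignReads(col, tinyBundle)
  expect_equal(normalizeCounts(asg3)$spikeinNormalized,
               norm$spikeinNormalized)

  # a missing spike-in breaks spike-in normalization but not RPM
  asg0 <- assignReads(craftReads(spike = c(0L, 10L, 12L, 10L),
                                 targetStarts = 160L), tinyBundle)
  expect_error(normalizeCounts(asg0), "zero reads")
  expect_equal(normalizeCounts(asg0, method = "rpm")$rpm, 1e6)
})

test_that("size distribution reports modes and conserves totals", {
  starts <- c(150L, 170L, 190L, 151L, 171L, 191L, 210L)
  lens <- c(20L, 20L, 20L, 21L, 21L, 21L, 19L)
  reads <- unlist(mapply(function(s, L) {
    substr(as.character(bundleTarget(tinyBundle)), s + 1L, s + L)
  }, starts, lens, SIMPLIFY = FALSE))
  asg <- assignReads(reads, tinyBundle)
  sd <- sizeDistribution(targetHits(asg))
  expect_setequal(sd$modes, c(20L, 21L))
  expect_identical(sd$total, 7)
  expect_identical(sum(sd$table$combined), 7)

  empty <- sizeDistribution(targetHits(asg)[0, ])
  expect_identical(empty$modes, integer(0))
  expect_identical(sum(empty$table$combined), 0)
})

test_that("coverage accumulates per-locus mass and respects bounds", {
  hits <- data.frame(sequence = "x", strand = "+", start = 5L, length = 20L,
                     count = 1L, nloci = 1L, ambiguous = FALSE)
  cov <- coverageProfile(hits, 100L)
  expect_identical(cov$sense[6:25], rep(1, 20))
  expect_identical(sum(cov$sense), 20)
  expect_identical(sum(cov$antisense), 0)

  cfg <- tinyConfig(biologySeed = 12, depth = 3000)
  lib <- sampleLibrary(applyProtocol(simulatePool(cfg), "standard"),
                       3000, samplingSeed = 2)
  asg <- assignReads(libraryReads(lib), tinyBundle)
  h <- targetHits(asg)
  cov2 <- coverageProfile(h, 300L)
  ps <- h[!h$ambiguous & !duplicated(h$sequence), ]
  expect_equal(cov2$mass, sum(ps$length * ps$count))

  bad <- hits
  bad$start <- 90L
  expect_error(coverageProfile(bad, 100L), "bounds")
})

test_that("replicates sharing biology show correlated coverage", {
  cfg <- tinyConfig(biologySeed = 14, depth = 5e4)
  pool <- applyProtocol(simulatePool(cfg), "standard")
  covs <- lapply(1:2, function(r) {
    coverageProfile(truthHits(sampleCounts(pool, 5e4, 600 + r)), 300L)
  })
  expect_gt(stats::cor(covs[[1L]]$sense, covs[[2L]]$sense), 0.8)
  expect_gt(stats::cor(covs[[1L]]$antisense, covs[[2L]]$antisense), 0.8)
})

test_that("phasing registers follow the 5' coordinate conventions", {
  mk <- function(strand, start, length = 20L) {
    data.frame(sequence = paste0("s", seq_along(start)), strand = strand,
               start = start, length = length, count = 1L, nloci = 1L,
               ambiguous = FALSE)
  }
  ph <- phasingProfile(mk("+", c(0L, 20L, 40L, 60L)), 20, 720L)
  expect_equal(ph$registers$sense_fraction[1L], 1)
  expect_equal(ph$maxRegisterFraction, 1)
  expect_identical(ph$verdict, "phased")

  flat <- phasingProfile(mk("+", 0:19), 20, 720L)
  expect_true(all(abs(flat$registers$sense_fraction - 0.05) < 1e-12))
  expect_equal(flat$chisq$sense$statistic, 0)
  expect_identical(flat$verdict, "unphased")

  # minus-strand 5' end sits at the right edge of the slice
  phm <- phasingProfile(mk("-", 80L), 20, 100L)   # 5' pos = 100 - 80 - 20 = 0
  expect_equal(phm$registers$antisense_fraction[1L], 1)

  none <- phasingProfile(mk("+", 0L)[0, ], 20, 720L)
  expect_identical(none$verdict, "undefined")
  expect_true(is.na(none$chisq$pooled$p.value))
})

test_that("composition matrices weight total vs unique reads differently", {
  mk <- function(seqs, counts) {
    data.frame(sequence = seqs, strand = "+", start = 0L,
               length = nchar(seqs), count = counts, nloci = 1L,
               ambiguous = FALSE)
  }
  two <- mk(c(strrep("A", 20), strrep("C", 20)), c(1L, 1L))
  cm <- compositionMatrix(two, 20L, "total")
  expect_true(all(abs(cm["A", ] - 0.5) < 1e-12))
  expect_true(all(abs(colSums(cm) - 1) < 1e-12))

  one <- compositionMatrix(mk("ACGTACGTACGTACGTACGT", 1L), 20L, "total")
  expect_identical(unname(one[, 1L]), c(1, 0, 0, 0))

  skew <- mk(c(strrep("A", 20), strrep("C", 20)), c(9L, 1L))
  expect_equal(unname(compositionMatrix(skew, 20L, "total")["A", 1L]), 0.9)
  expect_equal(unname(compositionMatrix(skew, 20L, "unique")["A", 1L]), 0.5)

  noneM <- compositionMatrix(two, 25L)
  expect_identical(attr(noneM, "nReads"), 0)
  expect_true(all(is.na(noneM)))
})

test_that("metric writers emit parseable files", {
  reads <- craftReads(spike = c(3L, 3L, 3L, 3L), mirna = 4L,
                      targetStarts = rep(c(155L, 230L), c(6L, 3L)))
  asg <- assignReads(reads, tinyBundle)
  m <- libraryMetrics(asg)
  dir <- withr::local_tempdir()
  writeMetrics(m, dir, sample = "s1", targetName = "target")
  js <- jsonlite::read_json(file.path(dir, "s1_metrics.json"))
  expect_equal(js$raw, m$normalized$raw)
  expect_true(file.exists(file.path(dir, "s1_size_distribution.tsv")))

  # bedGraph round trip reproduces the per-base profile
  gr <- rtracklayer::import(file.path(dir, "s1_sense.bedGraph"))
  back <- numeric(300)
  for (i in seq_along(gr)) {
    back[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      gr$score[i]
  }
  expect_equal(back, m$coverage$sense)
})
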