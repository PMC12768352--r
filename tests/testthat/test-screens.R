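# Screens are characterized on simulator ground truth: hit tables come from
# truthHits() on species-level draws, whose exact agreement with sequence
# assignment is established in test-assign.R / test-acceptance.R.

halfConfig <- function(...) {
  defaultSimConfig(tinyBundle, noiseDecoys = tinyDecoys,
                   injectedInterval = c(150L, 300L), ...)
}

test_that("upstreamTest flags only genuine upstream-mapping reads", {
  cfg0 <- halfConfig(biologySeed = 21, secondaryFraction = 0)
  pool0 <- applyProtocol(simulatePool(cfg0), "standard")
  hits0 <- lapply(1:3, function(r) truthHits(sampleCounts(pool0, 2e4,
                                                          700 + r)))
  res0 <- upstreamTest(hits0, c(150L, 300L))
  expect_identical(verdict(res0), "no_signal")
  expect_equal(unname(effectSize(res0)["upstream_fraction"]), 0)
  expect_true(all(vapply(hits0, function(h)
    all(h$start >= 150L), logical(1))))

  cfgA <- halfConfig(biologySeed = 21, secondaryFraction = 0.3,
                     pppFractionSecondary = 0)
  poolA <- applyProtocol(simulatePool(cfgA), "standard")
  hitsA <- lapply(1:3, function(r) truthHits(sampleCounts(poolA, 2e4,
                                                          800 + r)))
  resA <- upstreamTest(hitsA, c(150L, 300L))
  expect_identical(verdict(resA), "signal")
  expect_equal(unname(effectSize(resA)["upstream_fraction"]), 0.3,
               tolerance = 0.05)

  expect_identical(verdict(upstreamTest(hitsA[1L], c(150L, 300L))),
                   "underpowered")
  expect_error(upstreamTest(hitsA, c(0L, 300L)), "upstream")

  # the effect is monotone in the amplification fraction
  eff <- vapply(c(0, 0.15, 0.3), function(f) {
    cfg <- halfConfig(biologySeed = 21, secondaryFraction = f,
                      pppFractionSecondary = 0)
    p <- applyProtocol(simulatePool(cfg), "standard")
    h <- lapply(1:2, function(r) truthHits(sampleCounts(p, 1e4, 900 + r)))
    unname(effectSize(upstreamTest(h, c(150L, 300L)))["upstream_fraction"])
  }, numeric(1))
  expect_true(all(diff(eff) > 0))
})

normalizedTargetCount <- function(sc) {
  spike <- tapply(sc$count[sc$origin == "spikein"],
                  sc$sequence[sc$origin == "spikein"], sum)
  sum(sc$count[sc$origin %in% c("primary_siRNA", "secondary_siRNA")]) /
    mean(spike)
}

test_that("rpphContrast detects triphosphate species only when exposed", {
  cfg <- halfConfig(biologySeed = 23, secondaryFraction = 0.5,
                    pppFractionSecondary = 1)
  pool <- simulatePool(cfg)
  draw <- function(protocol, seed) {
    normalizedTargetCount(sampleCounts(applyProtocol(pool, protocol),
                                       2e4, seed))
  }
  counts <- do.call(rbind, lapply(1:3, function(r) rbind(
    data.frame(group = "treated", replicate = r, value = draw("rpph", r)),
    data.frame(group = "mock", replicate = r,
               value = draw("standard", 50 + r)))))
  res <- rpphContrast(counts, treated = "treated", mock = "mock")
  expect_identical(verdict(res), "signal")
  # capture arithmetic: removing the triphosphate half doubles the
  # treated/mock normalized ratio
  expect_equal(unname(effectSize(res)), 2, tolerance = 0.1)

  # with monophosphate secondary species both protocols see the same pool
  cfg0 <- halfConfig(biologySeed = 23, secondaryFraction = 0.5,
                     pppFractionSecondary = 0)
  pool0 <- simulatePool(cfg0)
  counts0 <- do.call(rbind, lapply(1:3, function(r) rbind(
    data.frame(group = "treated", replicate = r, value =
      normalizedTargetCount(sampleCounts(applyProtocol(pool0, "rpph"),
                                         2e4, 100 + r))),
    data.frame(group = "mock", replicate = r, value =
      normalizedTargetCount(sampleCounts(applyProtocol(pool0, "standard"),
                                         2e4, 150 + r))))))
  res0 <- rpphContrast(counts0, treated = "treated", mock = "mock")
  expect_identical(verdict(res0), "no_signal")
  expect_equal(unname(effectSize(res0)), 1, tolerance = 0.1)

  # paired variant agrees on the detection case
  resP <- rpphContrast(counts, treated = "treated", mock = "mock",
                       paired = TRUE)
  expect_identical(verdict(resP), "signal")

  # identical values across groups: F ~ 0, no signal
  flat <- data.frame(group = rep(c("treated", "mock"), each = 3),
                     replicate = rep(1:3, 2), value = rep(c(5, 6, 7), 2))
  resF <- rpphContrast(flat, treated = "treated", mock = "mock")
  expect_lt(resF@statistic, 1e-10)
  expect_identical(verdict(resF), "no_signal")

  expect_error(rpphContrast(flat[flat$group == "mock", ],
                            treated = "treated", mock = "mock"),
               "two groups")
  one <- flat[c(1, 4), ]
  expect_identical(verdict(rpphContrast(one, treated = "treated",
                                        mock = "mock")), "underpowered")
})

test_that("sizeShiftTest measures the 22-nt shift and JS divergence", {
  identicalDist <- list(c(`20` = 40, `21` = 40, `22` = 10),
                        c(`20` = 42, `21` = 38, `22` = 10))
  resI <- sizeShiftTest(identicalDist, identicalDist)
  expect_identical(verdict(resI), "no_signal")
  expect_equal(unname(effectSize(resI)["jsd"]), 0)

  disjointA <- list(c(`20` = 10, `21` = 0), c(`20` = 9, `21` = 0))
  disjointB <- list(c(`20` = 0, `21` = 10), c(`20` = 0, `21` = 11))
  resD <- sizeShiftTest(disjointA, disjointB)
  expect_equal(unname(effectSize(resD)["jsd"]), log(2), tolerance = 1e-12)

  cfgS <- halfConfig(biologySeed = 25, secondaryFraction = 0.4,
                     pppFractionSecondary = 0, secondaryUpstreamOnly = FALSE)
  poolS <- applyProtocol(simulatePool(cfgS), "standard")
  cfg0 <- halfConfig(biologySeed = 25, secondaryFraction = 0)
  pool0 <- applyProtocol(simulatePool(cfg0), "standard")
  distOf <- function(pool, seed) {
    sizeDistribution(truthHits(sampleCounts(pool, 2e4, seed)))
  }
  treated <- lapply(1:3, function(r) distOf(poolS, 300 + r))
  mock <- lapply(1:3, function(r) distOf(pool0, 350 + r))
  resS <- sizeShiftTest(treated, mock)
  expect_identical(verdict(resS), "signal")
  expect_gt(unname(effectSize(resS)["diff_fraction"]), 0.05)

  zero <- list(c(`20` = 0, `21` = 0))
  expect_identical(verdict(sizeShiftTest(zero, identicalDist)),
                   "underpowered")
})

test_that("loadingEnrichment compares target and miRNA RPM per replicate", {
  mkLib <- function(targetCount, mirnaCount) {
    assignReads(craftReads(spike = c(2L, 2L, 2L, 2L), mirna = mirnaCount,
                           targetStarts = rep(160L, targetCount)),
                tinyBundle)
  }
  equal <- lapply(c(10L, 12L, 11L), function(k) mkLib(k, k))
  resE <- loadingEnrichment(equal)
  expect_identical(verdict(resE), "no_signal")
  expect_equal(unname(effectSize(resE)["ratio"]), 1)

  five <- lapply(1:3, function(r) mkLib(48L + 2L * r, 10L))
  resF <- loadingEnrichment(five)
  expect_identical(verdict(resF), "signal")
  expect_equal(unname(effectSize(resF)["ratio"]), 5.2, tolerance = 0.05)

  expect_identical(verdict(loadingEnrichment(equal[1L])), "underpowered")
  noMir <- lapply(1:2, function(r) mkLib(10L, 0L))
  expect_identical(verdict(loadingEnrichment(noMir)), "underpowered")
})
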