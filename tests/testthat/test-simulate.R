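test_that("configuration invariants are enforced", {
  sp <- spikeFixture
  expect_error(simConfig("ACGT", spikeins = sp), "degenerate target")
  expect_error(simConfig(paste(rep("N", 100), collapse = ""), spikeins = sp),
               "alphabet")
  tgt <- syntheticTarget(100, seed = 1)
  expect_error(simConfig(tgt, spikeins = sp, targetFraction = 1.2),
               "targetFraction")
  expect_error(simConfig(tgt, spikeins = sp,
                         injectedInterval = c(50, 200)), "injectedInterval")
  badLd <- defaultLengthDistribution()
  badLd[1] <- badLd[1] + 0.1
  expect_error(simConfig(tgt, spikeins = sp, lengthDistribution = badLd),
               "sum to 1")
  expect_error(simConfig(tgt, spikeins = sp, targetFraction = 0.9,
                         noiseFraction = 0.2), "exceed 1")
})

test_that("secondary species obey the construction rules", {
  cfgNone <- tinyConfig(biologySeed = 3, secondaryFraction = 0)
  expect_identical(
    sum(poolSpecies(simulatePool(cfgNone))$origin == "secondary_siRNA"), 0L)

  cfg <- tinyConfig(biologySeed = 3, secondaryFraction = 0.3,
                    secondaryUpstreamOnly = TRUE, pppFractionSecondary = 0.5)
  sp <- poolSpecies(simulatePool(cfg))
  sec <- sp[sp$origin == "secondary_siRNA", ]
  expect_gt(nrow(sec), 0)
  expect_true(all(sec$strand == "antisense"))
  expect_true(all(sec$start + sec$length <= 150))
  expect_true(all(sec$start < 150))
  # five-prime mass split follows the triphosphate fraction exactly
  byFp <- tapply(sec$abundance, sec$five_prime, sum)
  expect_equal(unname(byFp["triphosphate"] / sum(byFp)), 0.5,
               tolerance = 1e-12)
  # primary species stay inside the injected interval
  prim <- sp[sp$origin == "primary_siRNA", ]
  expect_true(all(prim$start >= 150 & prim$start + prim$length <= 300))
})

test_that("biology seed fixes the species set; sampling seed only the draw", {
  cfgA <- tinyConfig(biologySeed = 5, samplingSeed = 1)
  cfgB <- tinyConfig(biologySeed = 5, samplingSeed = 999)
  expect_identical(poolSpecies(simulatePool(cfgA)),
                   poolSpecies(simulatePool(cfgB)))
  cfgC <- tinyConfig(biologySeed = 6)
  expect_false(identical(poolSpecies(simulatePool(cfgA))$abundance,
                         poolSpecies(simulatePool(cfgC))$abundance))

  pool <- simulatePool(cfgA)
  d1 <- sampleCounts(pool, 2000, samplingSeed = 42)
  d2 <- sampleCounts(pool, 2000, samplingSeed = 42)
  d3 <- sampleCounts(pool, 2000, samplingSeed = 43)
  expect_identical(d1$count, d2$count)
  expect_false(identical(d1$count, d3$count))
})

test_that("protocol capture masks follow the 5' chemistry", {
  cfg <- tinyConfig(biologySeed = 3, secondaryFraction = 0.4,
                    pppFractionSecondary = 1)
  pool <- simulatePool(cfg)
  std <- applyProtocol(pool, "standard")
  expect_identical(sum(poolSpecies(std)$five_prime == "triphosphate"), 0L)
  expect_identical(sum(poolSpecies(std)$origin == "secondary_siRNA"), 0L)

  rpph <- applyProtocol(pool, "rpph")
  expect_gt(sum(poolSpecies(rpph)$five_prime == "triphosphate"), 0L)
  expect_identical(nrow(poolSpecies(rpph)), nrow(poolSpecies(pool)))

  # modified species are only recovered by a PANDORA-class protocol
  modPool <- pool
  modPool@species$five_prime[1L] <- "modified"
  expect_false(modPool@species$species_id[1L] %in%
                 poolSpecies(applyProtocol(modPool, "rpph"))$species_id)
  expect_true(modPool@species$species_id[1L] %in%
                poolSpecies(applyProtocol(modPool, "pandora"))$species_id)

  # an all-monophosphate pool passes through every protocol unchanged
  monoPool <- applyProtocol(pool, "standard")
  for (p in c("standard", "rpph", "pandora")) {
    out <- applyProtocol(monoPool, p)
    expect_identical(poolSpecies(out)$species_id,
                     poolSpecies(monoPool)$species_id)
  }

  expect_error(libraryProtocol("enzymeless"))
})

test_that("sequencing draws conserve depth and are seed-deterministic", {
  pool1 <- singleSpeciesPool()
  lib1 <- sampleLibrary(pool1, 1, samplingSeed = 3)
  expect_identical(length(libraryReads(lib1)), 1L)
  expect_identical(as.character(libraryReads(lib1))[[1L]],
                   pool1@species$sequence)

  cfg <- tinyConfig(biologySeed = 5)
  pool <- applyProtocol(simulatePool(cfg), "standard")
  lib <- sampleLibrary(pool, 5000, samplingSeed = 11)
  expect_identical(length(libraryReads(lib)), 5000L)
  expect_identical(nrow(libraryTruth(lib)), 5000L)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeLibrary(sampleLibrary(pool, 1000, 7, sample = "x"), d1)
  writeLibrary(sampleLibrary(pool, 1000, 7, sample = "x"), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "x.fastq"))),
                   unname(tools::md5sum(file.path(d2, "x.fastq"))))

  emptyPool <- applyProtocol(
    simulatePool(tinyConfig(biologySeed = 2, targetFraction = 1,
                            spikeinAbundance = 0, noiseFraction = 0,
                            secondaryFraction = 1,
                            pppFractionSecondary = 1)), "standard")
  expect_error(sampleCounts(emptyPool, 100, 1), "standard")
})

test_that("read-length histogram converges to the configured distribution", {
  cfg <- tinyConfig(biologySeed = 9, targetFraction = 1,
                    spikeinAbundance = 0, noiseFraction = 0, depth = 1e5)
  sc <- sampleCounts(simulatePool(cfg), 1e5, samplingSeed = 21)
  emp <- tapply(sc$count, factor(sc$length, levels = 18:30), sum)
  emp[is.na(emp)] <- 0
  emp <- emp / sum(emp)
  tv <- 0.5 * sum(abs(emp - defaultLengthDistribution()))
  expect_lt(tv, 0.02)
})

test_that("multi-group designs produce labelled, paired libraries", {
  cfg <- tinyConfig(biologySeed = 4, depth = 800)
  design <- makeDesign(
    groups = list(dsRNA = list(config = cfg),
                  mock = list(config = mockConfig(cfg))),
    nReplicates = 3L)
  expect_identical(nrow(design$sampleSheet), 6L)
  expect_setequal(unique(design$sampleSheet$group), c("dsRNA", "mock"))
  mockTruth <- libraryTruth(design$libraries[["mock_rep1"]])
  expect_identical(sum(mockTruth$origin %in%
                         c("primary_siRNA", "secondary_siRNA")), 0L)

  expect_error(makeDesign(groups = list(a = list(config = cfg)),
                          nReplicates = 3L, samplingSeeds = 1:2),
               "length 2")

  # an RppH contrast shares the replicate pool: with no triphosphate species
  # the two protocols capture identical pools
  cfg0 <- tinyConfig(biologySeed = 4, secondaryFraction = 0.2,
                     pppFractionSecondary = 0)
  pool <- simulatePool(cfg0)
  expect_identical(poolSpecies(applyProtocol(pool, "rpph")),
                   poolSpecies(applyProtocol(pool, "standard")))

  outDir <- withr::local_tempdir()
  makeDesign(groups = list(g = list(config = tinyConfig(depth = 100))),
             nReplicates = 2L, outDir = outDir)
  expect_true(file.exists(file.path(outDir, "sample_sheet.tsv")))
  expect_true(file.exists(file.path(outDir, "g_rep1.fastq")))
  expect_true(file.exists(file.path(outDir, "g_rep2_truth.tsv")))
  expect_true(file.exists(file.path(outDir, "design_config.yaml")))
})
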