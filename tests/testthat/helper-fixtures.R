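# Shared fixtures, built once per test run. The small bundle keeps unit
# tests fast; acceptance tests build the full-size bundle themselves.

tinyBundle <- syntheticBundle(seed = 7L, targetLength = 300L, nGenome = 2L,
                              genomeLength = 600L, nMirnas = 8L)

spikeFixture <- stats::setNames(as.character(bundleSpikeins(tinyBundle)),
                                names(bundleSpikeins(tinyBundle)))

tinyDecoys <- decoyFragments(tinyBundle, n = 60L, seed = 11L)

tinyConfig <- function(...) {
  defaultSimConfig(tinyBundle, noiseDecoys = tinyDecoys,
                   injectedInterval = c(150L, 300L), depth = 5000,
                   ...)
}

# a hand-rolled single-species pool for degenerate-draw tests
singleSpeciesPool <- function(sequence = "ACGTACGTACGTACGTACGT") {
  new("TruePool",
      species = data.frame(species_id = "sp000001", sequence = sequence,
                           origin = "primary_siRNA", strand = "sense",
                           start = 0L, length = nchar(sequence),
                           five_prime = "monophosphate", abundance = 1),
      target = sequence, targetName = "target", protocol = "none")
}

# crafted reads for a library with known compartment counts:
# per spike-in counts, one miRNA at a given count, target reads at given
# 0-based starts/lengths on the tiny bundle target
craftReads <- function(spike = c(8L, 10L, 12L, 10L), mirna = 0L,
                       targetStarts = integer(0), targetLength = 20L,
                       bundle = tinyBundle) {
  tgt <- as.character(bundleTarget(bundle))
  reads <- character(0)
  sp <- as.character(bundleSpikeins(bundle))
  for (i in seq_along(sp)) reads <- c(reads, rep(sp[i], spike[i]))
  if (mirna > 0)
    reads <- c(reads, rep(as.character(bundleMirnas(bundle))[1L], mirna))
  for (s in targetStarts)
    reads <- c(reads, substr(tgt, s + 1L, s + targetLength))
  reads
}
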