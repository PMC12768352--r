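#' Library protocol constructor
#'
#' @param name `"standard"` (5'-monophosphate only), `"rpph"`
#'   (pyrophosphohydrolase pre-treatment: 5'-triphosphate also captured) or
#'   `"pandora"` (modification-removing protocol: everything captured).
#' @return a [LibraryProtocol-class].
#' @examples
#' libraryProtocol("rpph")
#' @export
libraryProtocol <- function(name = c("standard", "rpph", "pandora")) {
  if (is(name, "LibraryProtocol")) return(name)
  name <- match.arg(name)
  flags <- switch(name,
                  standard = c(FALSE, FALSE),
                  rpph = c(TRUE, FALSE),
                  pandora = c(TRUE, TRUE))
  new("LibraryProtocol", name = name, capturesTriphosphate = flags[1L],
      capturesModified = flags[2L])
}

#' Build a simulation configuration
#'
#' The generative model: per-position dicing initiation weights over the
#' injected interval are drawn once per `biologySeed` from a
#' Gamma(`hotspotConcentration`, rate = `hotspotConcentration`) distribution
#' (mean 1; small values give pronounced hotspots shared across replicates),
#' and per-position sense-strand probabilities from a symmetric
#' Beta(`strandBiasConcentration`, `strandBiasConcentration`). A primary
#' siRNA species is a (5' position, length, strand) triple fully contained in
#' the injected interval, with abundance proportional to
#' initiation weight x strand probability x length probability. In `phased`
#' mode, 5' ends are restricted to a processive register of period
#' `phaseStep` starting at each end of the injected interval (sense from the
#' interval start, antisense from the interval end). Secondary species are
#' antisense with their own length distribution and, when
#' `secondaryUpstreamOnly`, lie entirely upstream of the injected interval
#' with uniform 5' ends; a fraction `pppFractionSecondary` of their mass
#' carries a 5'-triphosphate. The remaining pool mass is split between
#' mature-miRNA background, four spike-ins at fixed relative input, and
#' decoy degradation noise.
#'
#' @param target named target sequence (sense strand).
#' @param injectedInterval 0-based half-open `[start, end)` of the injected
#'   dsRNA on the target; a full-length trigger is `c(0, nchar(target))`, a
#'   3'-half trigger `c(nchar(target)/2, nchar(target))`.
#' @param lengthDistribution named probability vector over read lengths
#'   (must sum to 1).
#' @param hotspotConcentration,strandBiasConcentration positive dispersion
#'   parameters of the hotspot and strand-selection draws.
#' @param targetFraction total relative abundance of target-derived
#'   molecules (0 for a mock library).
#' @param secondaryFraction proportion of target-derived mass that is
#'   secondary siRNA.
#' @param secondaryLengthDistribution length distribution of secondary
#'   species.
#' @param secondaryUpstreamOnly keep secondary species entirely upstream of
#'   the injected interval (antisense), as expected from RdRp acting on the
#'   target mRNA 5' of a 3'-half trigger.
#' @param pppFractionSecondary fraction of secondary mass carrying
#'   5'-triphosphate.
#' @param phased,phaseStep processive-dicing mode and its step.
#' @param mirnaBackground data.frame with columns `name`, `sequence`,
#'   `abundance` (relative weights).
#' @param spikeins four named spike-in sequences.
#' @param spikeinAbundance relative abundance of EACH spike-in (fixed molar
#'   input).
#' @param noiseDecoys decoy fragment sequences ([decoyFragments()]).
#' @param noiseFraction relative abundance of degradation noise.
#' @param depth default sequencing depth (reads per library).
#' @param biologySeed seed fixing the species set and abundances.
#' @param samplingSeed default seed of the multinomial sequencing draw.
#' @param targetName name used in coordinates and reports.
#' @return a validated [SimConfig-class].
#' @seealso [defaultSimConfig()] for a ready-made configuration wired to a
#'   [syntheticBundle()].
#' @export
simConfig <- function(target,
                      injectedInterval = c(0L, nchar(target)),
                      lengthDistribution = defaultLengthDistribution(),
                      hotspotConcentration = 0.5,
                      strandBiasConcentration = 0.5,
                      targetFraction = 0.55,
                      secondaryFraction = 0,
                      secondaryLengthDistribution =
                        c(`20` = 0.1, `21` = 0.2, `22` = 0.5, `23` = 0.2),
                      secondaryUpstreamOnly = TRUE,
                      pppFractionSecondary = 1,
                      phased = FALSE,
                      phaseStep = 21L,
                      mirnaBackground = data.frame(name = character(0),
                                                   sequence = character(0),
                                                   abundance = numeric(0)),
                      spikeins,
                      spikeinAbundance = 0.005,
                      noiseDecoys = character(0),
                      noiseFraction = 0,
                      depth = 2e5,
                      biologySeed = 1L,
                      samplingSeed = 1L,
                      targetName = NULL) {
  if (is.null(targetName))
    targetName <- if (!is.null(names(target))) names(target)[1L] else "target"
  target <- .normalizeSeq(target[[1L]], "target")
  spikeins <- stats::setNames(.normalizeSeq(spikeins, "spikeins"),
                              if (is.null(names(spikeins)))
                                .DEFAULT_SPIKEIN_NAMES else names(spikeins))
  cfg <- new("SimConfig",
             targetSequence = target,
             targetName = targetName,
             injectedInterval = as.integer(injectedInterval),
             lengthDistribution = lengthDistribution,
             hotspotConcentration = hotspotConcentration,
             strandBiasConcentration = strandBiasConcentration,
             targetFraction = targetFraction,
             secondaryFraction = secondaryFraction,
             secondaryLengthDistribution = secondaryLengthDistribution,
             secondaryUpstreamOnly = secondaryUpstreamOnly,
             pppFractionSecondary = pppFractionSecondary,
             phased = phased,
             phaseStep = as.integer(phaseStep),
             mirnaBackground = mirnaBackground,
             spikeins = spikeins,
             spikeinAbundance = spikeinAbundance,
             noiseDecoys = as.character(noiseDecoys),
             noiseFraction = noiseFraction,
             depth = depth,
             biologySeed = biologySeed,
             samplingSeed = samplingSeed)
  validObject(cfg)
  cfg
}

#' Default simulation configuration for a reference bundle
#'
#' Wires a [SimConfig-class] to a bundle: the bundle target, its spike-ins,
#' a Zipf-like miRNA background over the bundle's matures (abundance
#' proportional to rank^-1.1, a typical steep small-RNA abundance profile),
#' and decoy noise fragments derived from the bundle's genome proxy.
#'
#' @param bundle a [ReferenceBundle-class].
#' @param nDecoys number of decoy noise fragments.
#' @param decoySeed seed of the decoy generator.
#' @param ... further arguments passed to [simConfig()].
#' @return a [SimConfig-class].
#' @export
defaultSimConfig <- function(bundle, nDecoys = 300L, decoySeed = 101L, ...) {
  mirs <- as.character(bundle@mirnas)
  bg <- data.frame(name = names(bundle@mirnas),
                   sequence = mirs,
                   abundance = seq_along(mirs)^-1.1)
  args <- list(...)
  noiseFraction <- if ("noiseFraction" %in% names(args))
    args$noiseFraction else 0.05
  decoys <- if (noiseFraction > 0 && !"noiseDecoys" %in% names(args))
    decoyFragments(bundle, n = nDecoys, seed = decoySeed) else character(0)
  defaults <- list(target = stats::setNames(as.character(bundle@target),
                                            names(bundle@target)),
                   mirnaBackground = bg,
                   spikeins = stats::setNames(as.character(bundle@spikeins),
                                              names(bundle@spikeins)),
                   noiseDecoys = decoys,
                   noiseFraction = 0.05)
  do.call(simConfig, utils::modifyList(defaults, args))
}

#' Mock-injection counterpart of a configuration
#'
#' Mock libraries contain miRNA background, spike-ins and noise only: target
#' fraction and secondary fraction are set to zero, everything else is kept.
#'
#' @param config a [SimConfig-class].
#' @return a [SimConfig-class].
#' @export
mockConfig <- function(config) {
  config@targetFraction <- 0
  config@secondaryFraction <- 0
  validObject(config)
  config
}

# Species rows for target-derived molecules under one strand/mode.
.targetSpecies <- function(p5, length, strand, weight, target, origin,
                           five_prime) {
  start <- if (strand == "sense") p5 else p5 - length + 1L
  seqs <- substring(target, start + 1L, start + length)
  if (strand == "antisense") seqs <- .revComp(seqs)
  data.frame(sequence = seqs, origin = origin, strand = strand,
             start = as.integer(start), length = as.integer(length),
             five_prime = five_prime, abundance = weight)
}

#' Simulate the ground-truth molecule pool
#'
#' Draws the replicate-shared biology (hotspot weights, strand preferences)
#' once from `biologySeed` and builds the full species table with relative
#' abundances and truth labels. Deterministic given the configuration; the
#' sampling seed plays no role here, so replicates sharing a `biologySeed`
#' share the species set and differ only in the sequencing draw.
#'
#' @param config a [SimConfig-class].
#' @return a [TruePool-class].
#' @export
simulatePool <- function(config) {
  validObject(config)
  tl <- nchar(config@targetSequence)
  istart <- config@injectedInterval[1L]
  iend <- config@injectedInterval[2L]
  ilen <- iend - istart
  ld <- config@lengthDistribution
  lens <- as.integer(names(ld))

  bio <- .withSeed(config@biologySeed, {
    list(w = stats::rgamma(ilen, shape = config@hotspotConcentration,
                           rate = config@hotspotConcentration),
         s = stats::rbeta(ilen, config@strandBiasConcentration,
                          config@strandBiasConcentration))
  })

  rows <- list()

  # primary siRNAs: fully contained in the injected interval; 5' position
  # indexes the initiation weight (each strand measured on its own 5' end)
  primaryMass <- config@targetFraction * (1 - config@secondaryFraction)
  if (primaryMass > 0) {
    prim <- list()
    for (k in seq_along(lens)) {
      L <- lens[k]
      if (ld[k] <= 0 || ilen < L) next
      if (config@phased) {
        p5sense <- seq.int(istart, iend - 1L, by = config@phaseStep)
        p5sense <- p5sense[p5sense + L <= iend]
        p5anti <- seq.int(iend - 1L, istart, by = -config@phaseStep)
        p5anti <- p5anti[p5anti - L + 1L >= istart]
      } else {
        p5sense <- seq.int(istart, iend - L)
        p5anti <- seq.int(istart + L - 1L, iend - 1L)
      }
      if (length(p5sense)) {
        i <- p5sense - istart + 1L
        prim[[length(prim) + 1L]] <- .targetSpecies(
          p5sense, L, "sense", bio$w[i] * bio$s[i] * ld[k],
          config@targetSequence, "primary_siRNA", "monophosphate")
      }
      if (length(p5anti)) {
        i <- p5anti - istart + 1L
        prim[[length(prim) + 1L]] <- .targetSpecies(
          p5anti, L, "antisense", bio$w[i] * (1 - bio$s[i]) * ld[k],
          config@targetSequence, "primary_siRNA", "monophosphate")
      }
    }
    prim <- do.call(rbind, prim)
    prim$abundance <- prim$abundance / sum(prim$abundance) * primaryMass
    rows[[length(rows) + 1L]] <- prim
  }

  # secondary siRNAs: antisense, uniform 5' ends, own length distribution,
  # optionally restricted upstream of the injected interval
  secondaryMass <- config@targetFraction * config@secondaryFraction
  if (secondaryMass > 0) {
    sld <- config@secondaryLengthDistribution
    slens <- as.integer(names(sld))
    sec <- list()
    for (k in seq_along(slens)) {
      L <- slens[k]
      if (sld[k] <= 0) next
      lastStart <- if (config@secondaryUpstreamOnly) istart - L else tl - L
      if (lastStart < 0L) next
      starts <- seq.int(0L, lastStart)
      p5 <- starts + L - 1L   # antisense 5' end, sense coordinates
      sec[[length(sec) + 1L]] <- .targetSpecies(
        p5, L, "antisense", rep(sld[k] / length(starts), length(starts)),
        config@targetSequence, "secondary_siRNA", "monophosphate")
    }
    if (length(sec) == 0L)
      stop("no room for secondary species upstream of the injected interval")
    sec <- do.call(rbind, sec)
    sec$abundance <- sec$abundance / sum(sec$abundance) * secondaryMass
    ppp <- config@pppFractionSecondary
    parts <- list()
    if (ppp > 0) {
      p <- sec
      p$five_prime <- "triphosphate"
      p$abundance <- p$abundance * ppp
      parts[[length(parts) + 1L]] <- p
    }
    if (ppp < 1) {
      q <- sec
      q$abundance <- q$abundance * (1 - ppp)
      parts[[length(parts) + 1L]] <- q
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, parts)
  }

  mirnaMass <- max(0, 1 - config@targetFraction - config@noiseFraction -
                     4 * config@spikeinAbundance)
  if (mirnaMass > 0 && nrow(config@mirnaBackground) > 0) {
    bg <- config@mirnaBackground
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = .normalizeSeq(bg$sequence, "mirnaBackground"),
      origin = "miRNA", strand = NA_character_, start = NA_integer_,
      length = nchar(bg$sequence), five_prime = "monophosphate",
      abundance = bg$abundance / sum(bg$abundance) * mirnaMass)
  }

  if (config@spikeinAbundance > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = unname(config@spikeins), origin = "spikein",
      strand = NA_character_, start = NA_integer_,
      length = nchar(config@spikeins), five_prime = "monophosphate",
      abundance = rep(config@spikeinAbundance, length(config@spikeins)))
  }

  if (config@noiseFraction > 0) {
    nd <- config@noiseDecoys
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = nd, origin = "noise", strand = NA_character_,
      start = NA_integer_, length = nchar(nd),
      five_prime = "monophosphate",
      abundance = rep(config@noiseFraction / length(nd), length(nd)))
  }

  species <- do.call(rbind, rows)
  species <- species[species$abundance > 0, , drop = FALSE]
  species$species_id <- sprintf("sp%06d", seq_len(nrow(species)))
  rownames(species) <- NULL
  species <- species[, c("species_id", "sequence", "origin", "strand",
                         "start", "length", "five_prime", "abundance")]
  new("TruePool", species = species, target = config@targetSequence,
      targetName = config@targetName, protocol = "none")
}

#' Apply a library protocol's capture mask to a pool
#'
#' 5'-monophosphate species are always captured; 5'-triphosphate species
#' only when the protocol exposes them (RppH, PANDORA); otherwise-modified
#' species only under a PANDORA-class protocol. Abundances of captured
#' species are unchanged (renormalization happens implicitly in the
#' sequencing draw).
#'
#' @param pool a [TruePool-class].
#' @param protocol a [LibraryProtocol-class] or protocol name.
#' @return a capture-filtered [TruePool-class].
#' @export
applyProtocol <- function(pool, protocol) {
  stopifnot(is(pool, "TruePool"))
  if (nrow(pool@species) == 0L) stop("pool is empty")
  protocol <- libraryProtocol(protocol)
  fp <- pool@species$five_prime
  keep <- fp == "monophosphate" |
    (fp == "triphosphate" & protocol@capturesTriphosphate) |
    (fp == "modified" & protocol@capturesModified)
  out <- pool
  out@species <- pool@species[keep, , drop = FALSE]
  rownames(out@species) <- NULL
  out@protocol <- protocol@name
  out
}

#' Multinomial sequencing draw at the species level
#'
#' @param pool a [TruePool-class] (after [applyProtocol()], or raw).
#' @param depth number of reads to draw.
#' @param samplingSeed seed of the draw (the only randomness here).
#' @return the pool's species data.frame with an integer `count` column;
#'   counts sum to `depth` exactly.
#' @export
sampleCounts <- function(pool, depth, samplingSeed) {
  stopifnot(is(pool, "TruePool"))
  if (depth <= 0) stop("depth must be positive")
  sp <- pool@species
  if (nrow(sp) == 0L || sum(sp$abundance) <= 0)
    stop(sprintf("pool is empty after protocol '%s'", pool@protocol))
  sp$count <- .withSeed(samplingSeed,
                        as.integer(stats::rmultinom(1L, size = depth,
                                                    prob = sp$abundance)))
  sp
}

#' Sample a sequencing library from a pool
#'
#' Expands the species-level draw of [sampleCounts()] into named reads with
#' one ground-truth record per read. Deterministic given `samplingSeed`.
#'
#' @inheritParams sampleCounts
#' @param sample sample name (prefixes read ids).
#' @return a [SimulatedLibrary-class].
#' @export
sampleLibrary <- function(pool, depth, samplingSeed, sample = "library") {
  sp <- sampleCounts(pool, depth, samplingSeed)
  idx <- rep(seq_len(nrow(sp)), sp$count)
  ids <- sprintf("%s_r%07d", sample, seq_along(idx))
  reads <- stats::setNames(Biostrings::DNAStringSet(sp$sequence[idx]), ids)
  truth <- data.frame(read_id = ids,
                      origin = sp$origin[idx],
                      strand = sp$strand[idx],
                      start = sp$start[idx],
                      length = sp$length[idx],
                      five_prime = sp$five_prime[idx])
  new("SimulatedLibrary", sample = sample, reads = reads, truth = truth,
      protocol = pool@protocol, depth = as.numeric(depth),
      samplingSeed = as.numeric(samplingSeed))
}

#' Write a simulated library to disk
#'
#' Emits `<sample>.fastq` (constant Q40 qualities) and `<sample>_truth.tsv`.
#'
#' @param library a [SimulatedLibrary-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
writeLibrary <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, paste0(library@sample, ".fastq"))
  writeSequences(library@reads, fq, format = "fastq")
  tsv <- file.path(dir, paste0(library@sample, "_truth.tsv"))
  utils::write.table(library@truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq = fq, truth = tsv))
}

# Config echo for YAML/JSON provenance.
configAsList <- function(config) {
  list(targetName = config@targetName,
       targetLength = nchar(config@targetSequence),
       injectedInterval = as.integer(config@injectedInterval),
       lengthDistribution = as.list(config@lengthDistribution),
       hotspotConcentration = config@hotspotConcentration,
       strandBiasConcentration = config@strandBiasConcentration,
       targetFraction = config@targetFraction,
       secondaryFraction = config@secondaryFraction,
       secondaryLengthDistribution =
         as.list(config@secondaryLengthDistribution),
       secondaryUpstreamOnly = config@secondaryUpstreamOnly,
       pppFractionSecondary = config@pppFractionSecondary,
       phased = config@phased,
       phaseStep = config@phaseStep,
       nMirnaBackground = nrow(config@mirnaBackground),
       spikeinAbundance = config@spikeinAbundance,
       nNoiseDecoys = length(config@noiseDecoys),
       noiseFraction = config@noiseFraction,
       depth = config@depth,
       biologySeed = config@biologySeed,
       samplingSeed = config@samplingSeed)
}

#' Simulate a multi-group replicated design
#'
#' One library per (group, replicate). Replicates of a group share the
#' group's pool (the biology seed fixes hotspot and strand structure) and
#' differ only in their sequencing draws. Groups that share a configuration
#' but differ in protocol (an RppH contrast) are therefore built from the
#' same RNA pool per replicate, mirroring a paired enzyme/mock treatment of
#' one extraction.
#'
#' @param groups named list; each element is a list with elements `config`
#'   (a [SimConfig-class]) and optionally `protocol` (default standard).
#' @param nReplicates replicates per group.
#' @param samplingSeeds integer vector of length
#'   `length(groups) * nReplicates` (group-major order); by default derived
#'   from each config's `samplingSeed` plus the replicate index. A vector of
#'   any other length is an error.
#' @param outDir when given, libraries (FASTQ + truth), the sample sheet and
#'   a YAML config echo are written there.
#' @return list with `sampleSheet` (data.frame: sample, group, replicate,
#'   protocol, biology_seed, sampling_seed) and `libraries` (named list of
#'   [SimulatedLibrary-class]).
#' @export
makeDesign <- function(groups, nReplicates = 3L, samplingSeeds = NULL,
                       outDir = NULL) {
  if (length(groups) < 1L || is.null(names(groups)))
    stop("groups must be a non-empty named list")
  nlib <- length(groups) * nReplicates
  if (!is.null(samplingSeeds) && length(samplingSeeds) != nlib)
    stop(sprintf("samplingSeeds has length %d but %d libraries are requested",
                 length(samplingSeeds), nlib))
  libs <- list()
  sheet <- list()
  k <- 0L
  for (g in names(groups)) {
    spec <- groups[[g]]
    config <- spec$config
    stopifnot(is(config, "SimConfig"))
    protocol <- libraryProtocol(if (is.null(spec$protocol)) "standard"
                                else spec$protocol)
    pool <- applyProtocol(simulatePool(config), protocol)
    for (r in seq_len(nReplicates)) {
      k <- k + 1L
      seed <- if (is.null(samplingSeeds))
        config@samplingSeed + (k - 1L) else samplingSeeds[k]
      sampleName <- sprintf("%s_rep%d", g, r)
      libs[[sampleName]] <- sampleLibrary(pool, config@depth, seed,
                                          sample = sampleName)
      sheet[[k]] <- data.frame(sample = sampleName, group = g,
                               replicate = r, protocol = protocol@name,
                               biology_seed = config@biologySeed,
                               sampling_seed = seed)
    }
  }
  sheet <- do.call(rbind, sheet)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (lib in libs) writeLibrary(lib, outDir)
    utils::write.table(sheet, file.path(outDir, "sample_sheet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(lapply(groups, function(s) configAsList(s$config)),
                     file.path(outDir, "design_config.yaml"))
  }
  list(sampleSheet = sheet, libraries = libs)
}
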