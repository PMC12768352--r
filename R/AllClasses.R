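#' @import methods
NULL

#' Library capture chemistry
#'
#' Describes which 5' chemistries a small-RNA library protocol can ligate and
#' therefore sequence. The standard 5'-ligation protocol only captures
#' 5'-monophosphate species; pyrophosphohydrolase (RppH) pre-treatment
#' converts 5'-triphosphate ends (the hallmark of RNA-dependent RNA
#' polymerase products) to monophosphate so they become ligatable; a
#' PANDORA-style protocol additionally recovers species carrying other
#' ligation-blocking modifications.
#'
#' @slot name protocol label, one of `"standard"`, `"rpph"`, `"pandora"`.
#' @slot capturesTriphosphate logical, are 5'-triphosphate species sequenced.
#' @slot capturesModified logical, are otherwise-modified species sequenced.
#' @seealso [libraryProtocol()], [applyProtocol()]
#' @export
setClass("LibraryProtocol",
  representation(name = "character",
                 capturesTriphosphate = "logical",
                 capturesModified = "logical"))

setValidity("LibraryProtocol", function(object) {
  known <- list(standard = c(FALSE, FALSE),
                rpph     = c(TRUE,  FALSE),
                pandora  = c(TRUE,  TRUE))
  if (length(object@name) != 1L || !object@name %in% names(known))
    return("unknown protocol name (use standard, rpph or pandora)")
  want <- known[[object@name]]
  if (object@capturesTriphosphate != want[1L] ||
      object@capturesModified != want[2L])
    return(sprintf("capture flags inconsistent with protocol '%s'",
                   object@name))
  TRUE
})

#' Simulation configuration for the dicing simulator
#'
#' Parametric model of siRNA biogenesis from an injected dsRNA trigger:
#' per-position initiation weights (hotspots) drawn from a gamma
#' distribution, per-position strand selection from a beta distribution,
#' a read-length distribution, optional phased (processive) dicing, optional
#' secondary species synthesized upstream of the trigger with their own
#' length distribution and 5'-triphosphate fraction, plus mature-miRNA
#' background, four spike-ins at fixed input, and decoy degradation noise.
#' Built with [simConfig()]; see that constructor for field semantics.
#'
#' @export
setClass("SimConfig",
  representation(targetSequence = "character",
                 targetName = "character",
                 injectedInterval = "integer",
                 lengthDistribution = "numeric",
                 hotspotConcentration = "numeric",
                 strandBiasConcentration = "numeric",
                 targetFraction = "numeric",
                 secondaryFraction = "numeric",
                 secondaryLengthDistribution = "numeric",
                 secondaryUpstreamOnly = "logical",
                 pppFractionSecondary = "numeric",
                 phased = "logical",
                 phaseStep = "integer",
                 mirnaBackground = "data.frame",
                 spikeins = "character",
                 spikeinAbundance = "numeric",
                 noiseDecoys = "character",
                 noiseFraction = "numeric",
                 depth = "numeric",
                 biologySeed = "numeric",
                 samplingSeed = "numeric"))

.checkLengthDist <- function(d, label) {
  if (length(d) == 0L || is.null(names(d)))
    return(sprintf("%s must be a named numeric vector (names = lengths)", label))
  lens <- suppressWarnings(as.integer(names(d)))
  if (any(is.na(lens)) || any(lens < 1L))
    return(sprintf("%s names must be positive integer lengths", label))
  if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
    return(sprintf("%s must be non-negative and sum to 1", label))
  TRUE
}

setValidity("SimConfig", function(object) {
  msg <- character(0)
  tl <- nchar(object@targetSequence)
  if (length(object@targetSequence) != 1L || tl == 0L)
    msg <- c(msg, "targetSequence must be a single non-empty string")
  if (grepl("[^ACGT]", object@targetSequence))
    msg <- c(msg, "targetSequence: invalid nucleotide alphabet (ACGT only)")
  iv <- object@injectedInterval
  if (length(iv) != 2L || iv[1L] < 0L || iv[2L] > tl || iv[1L] >= iv[2L])
    msg <- c(msg, "injectedInterval must be 0-based half-open within the target")
  ok <- .checkLengthDist(object@lengthDistribution, "lengthDistribution")
  if (!isTRUE(ok)) msg <- c(msg, ok)
  ok <- .checkLengthDist(object@secondaryLengthDistribution,
                         "secondaryLengthDistribution")
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (isTRUE(ok) && isTRUE(.checkLengthDist(object@lengthDistribution, "x"))) {
    maxL <- max(as.integer(names(object@lengthDistribution))[
      object@lengthDistribution > 0])
    if (tl < maxL)
      msg <- c(msg, "degenerate target: shorter than the longest read length")
  }
  for (f in c("targetFraction", "secondaryFraction", "pppFractionSecondary",
              "noiseFraction", "spikeinAbundance")) {
    v <- slot(object, f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste(f, "must be a single value in [0, 1]"))
  }
  if (object@hotspotConcentration <= 0 || object@strandBiasConcentration <= 0)
    msg <- c(msg, "concentration parameters must be positive")
  if (length(object@spikeins) != 4L || is.null(names(object@spikeins)))
    msg <- c(msg, "exactly 4 named spike-in sequences are required")
  mirnaMass <- 1 - object@targetFraction - object@noiseFraction -
    4 * object@spikeinAbundance
  if (mirnaMass < -1e-9)
    msg <- c(msg, "target, noise and spike-in fractions exceed 1")
  if (mirnaMass > 1e-9 && nrow(object@mirnaBackground) == 0L)
    msg <- c(msg, "mirnaBackground is empty but miRNA mass is positive")
  if (object@noiseFraction > 0 && length(object@noiseDecoys) == 0L)
    msg <- c(msg, "noiseFraction > 0 requires noiseDecoys")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@phaseStep < 2L) msg <- c(msg, "phaseStep must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Ground-truth molecule pool
#'
#' The species-level output of [simulatePool()]: one row per distinct
#' molecular species with its origin label (primary_siRNA, secondary_siRNA,
#' miRNA, spikein, noise), strand and 0-based start on the target (NA for
#' non-target origins), length, 5' chemistry and relative abundance.
#'
#' @slot species data.frame of species with truth labels and abundances.
#' @slot target target (sense) sequence the coordinates refer to.
#' @slot targetName name used for the target in coordinates and output.
#' @slot protocol name of the capture protocol applied (`"none"` before
#'   [applyProtocol()]).
#' @export
setClass("TruePool",
  representation(species = "data.frame",
                 target = "character",
                 targetName = "character",
                 protocol = "character"))

setValidity("TruePool", function(object) {
  need <- c("species_id", "sequence", "origin", "strand", "start", "length",
            "five_prime", "abundance")
  if (!all(need %in% names(object@species)))
    return("species table is missing required columns")
  if (any(object@species$abundance < 0))
    return("species abundances must be non-negative")
  TRUE
})

#' A sequenced synthetic library with per-read ground truth
#'
#' @slot sample sample name.
#' @slot reads named DNAStringSet of sequenced reads.
#' @slot truth data.frame with one row per read: read_id, origin, strand,
#'   start (0-based on the target), length, five_prime.
#' @slot protocol capture protocol the pool was filtered with.
#' @slot depth number of reads drawn.
#' @slot samplingSeed seed of the multinomial draw.
#' @export
setClass("SimulatedLibrary",
  representation(sample = "character",
                 reads = "DNAStringSet",
                 truth = "data.frame",
                 protocol = "character",
                 depth = "numeric",
                 samplingSeed = "numeric"))

setValidity("SimulatedLibrary", function(object) {
  if (length(object@reads) != nrow(object@truth))
    return("every read must have exactly one truth record")
  TRUE
})

#' Reference bundle for read assignment
#'
#' Holds the four reference compartments used by [assignReads()]: the target
#' transgene, a genome proxy (multi-FASTA), mature miRNA sequences, and
#' exactly four spike-in sequences.
#'
#' @slot target DNAStringSet of length 1 (named).
#' @slot genomeProxy DNAStringSet of genome-proxy sequences.
#' @slot mirnas DNAStringSet of mature miRNA sequences (18-24 nt).
#' @slot spikeins DNAStringSet of exactly 4 named spike-in sequences.
#' @seealso [referenceBundle()], [syntheticBundle()]
#' @export
setClass("ReferenceBundle",
  representation(target = "DNAStringSet",
                 genomeProxy = "DNAStringSet",
                 mirnas = "DNAStringSet",
                 spikeins = "DNAStringSet"))

setValidity("ReferenceBundle", function(object) {
  if (length(object@target) != 1L)
    return("exactly one target sequence is required")
  if (length(object@spikeins) != 4L)
    return("exactly four spike-in sequences are required")
  nms <- c(names(object@target), names(object@genomeProxy),
           names(object@mirnas), names(object@spikeins))
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    return("all reference sequences must carry unique names")
  w <- Biostrings::width(object@mirnas)
  if (length(w) && (any(w < 18L) || any(w > 24L)))
    return("mature miRNA sequences must be 18-24 nt")
  for (s in c("target", "genomeProxy", "mirnas", "spikeins")) {
    af <- Biostrings::alphabetFrequency(slot(object, s))
    if (length(slot(object, s)) &&
        any(rowSums(af[, c("A", "C", "G", "T"), drop = FALSE]) !=
            Biostrings::width(slot(object, s))))
      return(sprintf("%s contains non-ACGT characters", s))
  }
  TRUE
})

#' Compartment-assigned library
#'
#' Result of [assignReads()]: every length-filtered collapsed read is placed
#' in exactly one compartment (spike-in, miRNA, genome proxy, target, or
#' unassigned) following the genome-subtractive precedence, and target
#' matches are recorded per locus with strand and 0-based start.
#'
#' @slot compartments named list of data.frames (sequence, count) per
#'   compartment.
#' @slot spikeinCounts named numeric, reads per spike-in (zeros kept).
#' @slot mirnaCounts named numeric, reads per mature miRNA guide.
#' @slot hits data.frame of target hits, one row per locus: sequence, strand
#'   (+/-), start (0-based), length, count (read multiplicity), nloci
#'   (loci for that sequence), ambiguous (reverse-complement palindrome).
#' @slot totals list: parsed, filtered, perCompartment (named numeric).
#' @slot precedence compartment test order used.
#' @slot targetName,targetLength coordinates the hits refer to.
#' @export
setClass("AssignedLibrary",
  representation(compartments = "list",
                 spikeinCounts = "numeric",
                 mirnaCounts = "numeric",
                 hits = "data.frame",
                 totals = "list",
                 precedence = "character",
                 targetName = "character",
                 targetLength = "integer"))

setValidity("AssignedLibrary", function(object) {
  per <- object@totals$perCompartment
  if (is.null(per)) return("totals$perCompartment missing")
  if (abs(sum(per) - object@totals$filtered) > 1e-8)
    return("compartment totals do not add up to the length-filtered total")
  TRUE
})

#' Result of a secondary-siRNA screen
#'
#' @slot screen one of `"upstream"`, `"rpph"`, `"size_shift"`, `"loading"`.
#' @slot effect named numeric effect size(s); screen-specific, see the
#'   corresponding screen function.
#' @slot statistic test statistic (NA when not computable).
#' @slot pValue p-value in `[0, 1]` (NA when not computable).
#' @slot verdict `"signal"`, `"no_signal"` or `"underpowered"`.
#' @slot details list of screen-specific tables (per-replicate effects,
#'   post-hoc contrasts, thresholds used).
#' @export
setClass("ScreenResult",
  representation(screen = "character",
                 effect = "numeric",
                 statistic = "numeric",
                 pValue = "numeric",
                 verdict = "character",
                 details = "list"))

setValidity("ScreenResult", function(object) {
  if (!object@screen %in% c("upstream", "rpph", "size_shift", "loading"))
    return("unknown screen name")
  if (!object@verdict %in% c("signal", "no_signal", "underpowered"))
    return("verdict must be signal, no_signal or underpowered")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value outside [0, 1]")
  TRUE
})
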