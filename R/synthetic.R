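# Synthetic reference material. All sequences produced here are random
# stand-ins (the experiments this package models used a 720-nt transgene,
# a sequenced genome and annotated miRNAs, none of which are bundled);
# generation is deterministic given the seed and screened so that the
# compartments cannot collide by exact matching.

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Deterministic synthetic target transgene
#'
#' A random 720-nt sequence standing in for a GFP-class transgene coding
#' sequence. Deterministic given `seed`.
#'
#' @param length target length in nt.
#' @param seed RNG seed.
#' @param name sequence name.
#' @return named character vector of length 1.
#' @export
syntheticTarget <- function(length = 720L, seed = 7L, name = "target") {
  stats::setNames(.withSeed(seed, .randSeq(length)), name)
}

#' Synthetic reference bundle
#'
#' Generates a deterministic reference bundle: a 720-nt target, a multi-FASTA
#' genome proxy, mature miRNA sequences (21-22 nt) and four spike-ins
#' carrying the conventional spike-in names. Genome-proxy sequences, miRNAs
#' and spike-ins are screened to share no 15-mer with the target (either
#' strand), so no read from a non-target compartment can exactly match the
#' target and compartment assignment has a unique correct answer.
#'
#' @param seed RNG seed (whole bundle is deterministic given it).
#' @param targetLength target length in nt.
#' @param nGenome,genomeLength number and length of genome-proxy sequences.
#' @param nMirnas number of mature miRNAs.
#' @return a [ReferenceBundle-class].
#' @export
syntheticBundle <- function(seed = 42L, targetLength = 720L, nGenome = 6L,
                            genomeLength = 2000L, nMirnas = 50L) {
  .withSeed(seed, {
    target <- .randSeq(targetLength)
    tk <- unique(c(.kmers(target, 15L), .kmers(.revComp(target), 15L)))
    clashFree <- function(s) {
      !any(.kmers(s, 15L) %in% tk) && !any(.kmers(.revComp(s), 15L) %in% tk)
    }
    draw <- function(n, taken = character(0)) {
      repeat {
        s <- .randSeq(n)
        if (clashFree(s) && !s %in% taken) return(s)
      }
    }
    genome <- character(nGenome)
    for (i in seq_len(nGenome)) genome[i] <- draw(genomeLength)
    mirnas <- character(nMirnas)
    for (i in seq_len(nMirnas))
      mirnas[i] <- draw(sample(21:22, 1L), taken = mirnas)
    spikes <- character(4L)
    for (i in 1:4) spikes[i] <- draw(22L, taken = c(mirnas, spikes))
    referenceBundle(
      target = stats::setNames(target, "target"),
      genomeProxy = stats::setNames(genome,
                                    sprintf("scaffold%02d", seq_len(nGenome))),
      mirnas = stats::setNames(mirnas, sprintf("mir-%03d", seq_len(nMirnas))),
      spikeins = stats::setNames(spikes, .DEFAULT_SPIKEIN_NAMES))
  })
}

#' Decoy degradation fragments
#'
#' Generates noise fragments from a first-order Markov model fitted to the
#' genome-proxy dinucleotide composition (a dinucleotide-shuffle surrogate),
#' then screens out any fragment that would be assigned to a compartment
#' (spike-in equality, miRNA window, exact genome or target match on either
#' strand). The surviving decoys mimic RNA degradation background while
#' guaranteeing that noise reads stay unassigned, which isolates the
#' pipeline's specificity.
#'
#' @param bundle a [ReferenceBundle-class].
#' @param n number of decoy fragments.
#' @param lengths candidate fragment lengths (default straddles the 18-30 nt
#'   analysis window so some decoys exercise the length filter).
#' @param seed RNG seed.
#' @return character vector of `n` decoy sequences.
#' @export
decoyFragments <- function(bundle, n = 300L, lengths = 16:32, seed = 101L) {
  gseq <- paste(as.character(bundle@genomeProxy), collapse = "")
  if (nchar(gseq) < 2L)
    stop("genome proxy is required to fit the decoy model")
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(gseq, "")[[1L]]
  trans <- table(factor(chars[-length(chars)], nt),
                 factor(chars[-1L], nt)) + 1
  trans <- sweep(unclass(trans), 1L, rowSums(trans), "/")
  p0 <- table(factor(chars, nt)) / length(chars)

  mirnaChr <- stats::setNames(as.character(bundle@mirnas),
                              names(bundle@mirnas))
  mirTab <- if (length(mirnaChr)) .mirnaTables(mirnaChr, minLen = 16L)
            else NULL
  spikes <- as.character(bundle@spikeins)

  genCandidates <- function(k) {
    vapply(seq_len(k), function(i) {
      L <- sample(lengths, 1L)
      s <- character(L)
      s[1L] <- sample(nt, 1L, prob = p0)
      for (j in seq_len(L - 1L))
        s[j + 1L] <- sample(nt, 1L, prob = trans[s[j], ])
      paste(s, collapse = "")
    }, character(1))
  }

  .withSeed(seed, {
    decoys <- character(0)
    while (length(decoys) < n) {
      cand <- genCandidates(n - length(decoys))
      bad <- cand %in% spikes
      if (!is.null(mirTab))
        bad <- bad | !is.na(.mirnaLookup(cand, mirTab))
      bad <- bad | .matchesAnywhere(cand, bundle@genomeProxy)
      bad <- bad | .matchesAnywhere(cand, bundle@target)
      decoys <- c(decoys, cand[!bad])
    }
    decoys[seq_len(n)]
  })
}

#' Default siRNA read-length distribution
#'
#' Probability mass over 18-30 nt with the mode shared between 20 and 21 nt,
#' the size class observed for dsRNA-derived siRNAs in this system.
#'
#' @return named numeric vector summing to 1.
#' @export
defaultLengthDistribution <- function() {
  c(`18` = 0.05, `19` = 0.10, `20` = 0.27, `21` = 0.27, `22` = 0.12,
    `23` = 0.07, `24` = 0.04, `25` = 0.03, `26` = 0.02, `27` = 0.01,
    `28` = 0.01, `29` = 0.005, `30` = 0.005)
}

#' @rdname defaultLengthDistribution
#' @details `secondaryLengthDistribution()` is the default length profile of
#'   secondary species, with its mode shifted to 22 nt as reported for
#'   RdRp-derived secondary siRNAs in nematodes.
#' @export
secondaryLengthDistribution <- function() {
  c(`20` = 0.1, `21` = 0.2, `22` = 0.5, `23` = 0.2)
}
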