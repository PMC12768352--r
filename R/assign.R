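#' Length-filter collapsed reads
#'
#' Reads shorter than `minLen` or longer than `maxLen` are removed;
#' multiplicities are untouched. The defaults follow the usual small-RNA
#' window: reads shorter than 18 nt are discarded and 18-30 nt reads are
#' analyzed.
#'
#' @param reads collapsed-read data.frame (`sequence`, `count`) or a
#'   character vector of sequences.
#' @param minLen,maxLen inclusive length bounds, `1 <= minLen <= maxLen`.
#' @return object of the same shape as `reads`, filtered.
#' @export
lengthFilter <- function(reads, minLen = 18L, maxLen = 30L) {
  if (!(minLen >= 1L && minLen <= maxLen))
    stop("length bounds must satisfy 1 <= minLen <= maxLen")
  if (is.data.frame(reads)) {
    keep <- nchar(reads$sequence) >= minLen & nchar(reads$sequence) <= maxLen
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  reads[nchar(reads) >= minLen & nchar(reads) <= maxLen]
}

#' Find all exact occurrences of a read on both strands of a reference
#'
#' A `+` hit means the read equals the reference slice
#' `[start, start + length)`; a `-` hit means the read equals the reverse
#' complement of that slice. Coordinates are 0-based on the reference sense
#' strand; `start` is always the leftmost base of the slice. A read that is
#' its own reverse complement reports each locus on both strands.
#'
#' @param read a single read sequence.
#' @param reference a single (optionally named) reference sequence.
#' @return data.frame with columns `strand`, `start`, `length`, ordered by
#'   ascending start with `+` before `-`.
#' @examples
#' matchExact("ACGTA", c(ref = "ACGTACGTAC"))
#' @export
matchExact <- function(read, reference) {
  read <- .normalizeSeq(read, "read")
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  refseq <- .normalizeSeq(reference[[1L]], "reference")
  if (nchar(read) > nchar(refseq))
    stop("read is longer than the reference")
  subject <- Biostrings::DNAString(refseq)
  plus <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(read), subject)) - 1L
  minus <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(.revComp(read)),
                             subject)) - 1L
  out <- data.frame(
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    start = c(plus, minus),
    length = rep(nchar(read), length(plus) + length(minus)))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- internal bulk matchers -------------------------------------------------

# Hash maps for the miRNA matching window: a read is assigned to a mature
# miRNA when it aligns exactly within the mature sequence, allowing up to
# `maxOverhang` unconstrained nucleotides beyond the mature 3' end (a
# stand-in for quantifier-style precursor-window matching when only mature
# sequences are available).
.mirnaTables <- function(mirnas, minLen = 18L, maxOverhang = 2L) {
  subMap <- new.env(hash = TRUE, parent = emptyenv())
  sufMap <- new.env(hash = TRUE, parent = emptyenv())
  put <- function(env, key, val) {
    if (is.null(env[[key]])) env[[key]] <- val
  }
  for (i in seq_along(mirnas)) {
    s <- mirnas[[i]]
    nm <- names(mirnas)[i]
    n <- nchar(s)
    for (k in seq(from = min(minLen, n), to = n)) {
      for (sub in .kmers(s, k)) put(subMap, sub, nm)
    }
    for (k in seq(from = max(1L, minLen - maxOverhang), to = n)) {
      put(sufMap, substr(s, n - k + 1L, n), nm)
    }
  }
  list(sub = subMap, suf = sufMap, maxOverhang = maxOverhang)
}

.mirnaLookup <- function(seqs, tables) {
  vapply(seqs, function(r) {
    hit <- tables$sub[[r]]
    if (!is.null(hit)) return(hit)
    L <- nchar(r)
    for (o in seq_len(tables$maxOverhang)) {
      if (L - o < 1L) break
      hit <- tables$suf[[substr(r, 1L, L - o)]]
      if (!is.null(hit)) return(hit)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Does each sequence occur exactly (either strand) anywhere in `refs`?
.matchesAnywhere <- function(seqs, refs) {
  if (length(seqs) == 0L || length(refs) == 0L)
    return(logical(length(seqs)))
  hit <- logical(length(seqs))
  both <- c(refs, Biostrings::reverseComplement(refs))
  for (w in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    cnt <- Biostrings::vcountPDict(pd, both)
    hit[idx] <- rowSums(cnt) > 0
  }
  hit
}

# All exact target loci (both strands) for a set of distinct sequences, as
# one flat data.frame (seqIdx into `seqs`, strand, start, length). Minus
# hits come from matching against the reverse complement of the target; a
# 1-based match start s there is leftmost sense coordinate tl - s - w + 1
# (0-based).
.targetLoci <- function(seqs, target) {
  parts <- list()
  if (length(seqs)) {
    tl <- nchar(as.character(target))
    targetD <- Biostrings::DNAString(as.character(target))
    rcTargetD <- Biostrings::reverseComplement(targetD)
    for (w in unique(nchar(seqs))) {
      idx <- which(nchar(seqs) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
      for (strand in c("+", "-")) {
        si <- Biostrings::startIndex(
          Biostrings::matchPDict(pd, if (strand == "+") targetD
                                     else rcTargetD))
        nhit <- lengths(si)
        if (sum(nhit) == 0L) next
        s <- unlist(si, use.names = FALSE)
        start0 <- if (strand == "+") s - 1L else tl - s - w + 1L
        parts[[length(parts) + 1L]] <- data.frame(
          seqIdx = rep(idx, nhit), strand = strand,
          start = as.integer(start0), length = w)
      }
    }
  }
  if (length(parts) == 0L)
    return(data.frame(seqIdx = integer(0), strand = character(0),
                      start = integer(0), length = integer(0)))
  do.call(rbind, parts)
}

#' Assign collapsed reads to compartments by exact matching
#'
#' Each length-filtered read is tested against the compartments in
#' `precedence` order (default: spike-in, then mature miRNA, then genome
#' proxy, then target) and lands in the first compartment it matches;
#' anything left is unassigned. This reproduces genome-subtractive target
#' mapping: a read matching the genome proxy is never counted for the
#' target. Matching is exact on both strands; the miRNA compartment allows
#' the read to extend up to 2 nt past the mature 3' end (see
#' [ReferenceBundle-class]). Reads that are their own reverse complement are
#' counted once and flagged `ambiguous`; they are excluded from
#' strand-resolved outputs downstream.
#'
#' @param reads collapsed-read data.frame, or a character vector /
#'   DNAStringSet of raw reads (collapsed internally).
#' @param bundle a [ReferenceBundle-class].
#' @param minLen,maxLen length filter applied before assignment.
#' @param precedence permutation of
#'   `c("spikein", "mirna", "genome", "target")`.
#' @return an [AssignedLibrary-class].
#' @export
assignReads <- function(reads, bundle, minLen = 18L, maxLen = 30L,
                        precedence = c("spikein", "mirna", "genome",
                                       "target")) {
  stopifnot(is(bundle, "ReferenceBundle"))
  if (!setequal(precedence, c("spikein", "mirna", "genome", "target")))
    stop("precedence must be a permutation of spikein, mirna, genome, target")
  if (length(bundle@target) != 1L)
    stop("reference bundle lacks a target sequence")
  if (!is.data.frame(reads)) reads <- collapseReads(reads)
  parsed <- sum(reads$count)
  reads <- lengthFilter(reads, minLen, maxLen)
  filtered <- sum(reads$count)
  seqs <- reads$sequence
  counts <- reads$count
  n <- length(seqs)

  compartment <- rep(NA_character_, n)
  refName <- rep(NA_character_, n)
  loci <- NULL

  spikeSeqs <- as.character(bundle@spikeins)
  mirnaChr <- stats::setNames(as.character(bundle@mirnas),
                              names(bundle@mirnas))
  mirTab <- if (length(mirnaChr)) .mirnaTables(mirnaChr, minLen = minLen)
            else NULL

  for (comp in precedence) {
    open <- which(is.na(compartment))
    if (length(open) == 0L) break
    if (comp == "spikein") {
      m <- match(seqs[open], spikeSeqs)
      hitIdx <- open[!is.na(m)]
      compartment[hitIdx] <- "spikein"
      refName[hitIdx] <- names(bundle@spikeins)[m[!is.na(m)]]
    } else if (comp == "mirna") {
      if (!is.null(mirTab)) {
        hits <- .mirnaLookup(seqs[open], mirTab)
        hitIdx <- open[!is.na(hits)]
        compartment[hitIdx] <- "mirna"
        refName[hitIdx] <- hits[!is.na(hits)]
      }
    } else if (comp == "genome") {
      hit <- .matchesAnywhere(seqs[open], bundle@genomeProxy)
      compartment[open[hit]] <- "genome"
    } else {
      flat <- .targetLoci(seqs[open], bundle@target)
      flat$seqIdx <- open[flat$seqIdx]
      compartment[unique(flat$seqIdx)] <- "target"
      loci <- flat
    }
  }
  compartment[is.na(compartment)] <- "unassigned"

  # Per-locus hit table; reverse-complement palindromes report the same loci
  # on both strands, so keep the + rows once and flag them ambiguous.
  hits <- data.frame(sequence = character(0), strand = character(0),
                     start = integer(0), length = integer(0),
                     count = integer(0), nloci = integer(0),
                     ambiguous = logical(0))
  if (!is.null(loci) && nrow(loci)) {
    tIdx <- unique(loci$seqIdx)
    pal <- stats::setNames(seqs[tIdx] == .revComp(seqs[tIdx]), tIdx)
    isPal <- pal[as.character(loci$seqIdx)]
    loci <- loci[!(isPal & loci$strand == "-"), , drop = FALSE]
    nloci <- table(loci$seqIdx)
    hits <- data.frame(sequence = seqs[loci$seqIdx],
                       strand = loci$strand,
                       start = loci$start,
                       length = loci$length,
                       count = counts[loci$seqIdx],
                       nloci = as.integer(nloci[as.character(loci$seqIdx)]),
                       ambiguous = unname(pal[as.character(loci$seqIdx)]))
    rownames(hits) <- NULL
  }

  compNames <- c("spikein", "mirna", "genome", "target", "unassigned")
  compartments <- lapply(stats::setNames(compNames, compNames), function(k) {
    keep <- compartment == k
    data.frame(sequence = seqs[keep], count = counts[keep],
               row.names = NULL)
  })
  perCompartment <- vapply(compartments, function(d) sum(d$count), numeric(1))

  tallyBy <- function(allNames, which) {
    out <- stats::setNames(numeric(length(allNames)), allNames)
    keep <- compartment == which & !is.na(refName)
    if (any(keep)) {
      t <- tapply(counts[keep], refName[keep], sum)
      out[names(t)] <- t
    }
    out
  }

  new("AssignedLibrary",
      compartments = compartments,
      spikeinCounts = tallyBy(names(bundle@spikeins), "spikein"),
      mirnaCounts = tallyBy(names(bundle@mirnas), "mirna"),
      hits = hits,
      totals = list(parsed = parsed, filtered = filtered,
                    perCompartment = perCompartment),
      precedence = precedence,
      targetName = names(bundle@target),
      targetLength = Biostrings::width(bundle@target)[1L])
}

#' Restrict target hits to unique, single-locus reads
#'
#' Phasing analysis is performed on unique, perfectly matching reads of the
#' siRNA size class: one record per distinct sequence (multiplicity collapsed
#' to 1), restricted to sequences matching the target at exactly one locus,
#' with length in `[minLen, maxLen]` (default 20-22 nt).
#'
#' @param hits hit data.frame from [targetHits()] (or [truthHits()]).
#' @param minLen,maxLen inclusive length bounds.
#' @return hit data.frame with `count` set to 1 for every retained record.
#' @export
uniqueHits <- function(hits, minLen = 20L, maxLen = 22L) {
  keep <- hits$nloci == 1L & !hits$ambiguous &
    hits$length >= minLen & hits$length <= maxLen
  out <- hits[keep, , drop = FALSE]
  out$count <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Target hits from simulator ground truth
#'
#' Builds the same per-locus hit table as [assignReads()] directly from a
#' simulated library's truth records (or from a species table carrying a
#' `count` column, as returned by [sampleCounts()]), bypassing sequence
#' matching. Useful as an independent tally when validating assignment and
#' for fast Monte-Carlo characterization of the screens.
#'
#' @param x a [SimulatedLibrary-class] or a species data.frame with `count`.
#' @param target optional target sequence used to reconstruct read sequences
#'   (needed for composition analysis; hits from a species table already
#'   carry sequences).
#' @return hit data.frame with the [assignReads()] hit columns.
#' @export
truthHits <- function(x, target = NULL) {
  targetOrigins <- c("primary_siRNA", "secondary_siRNA")
  if (is(x, "SimulatedLibrary")) {
    tr <- x@truth
    tr <- tr[tr$origin %in% targetOrigins, , drop = FALSE]
    if (nrow(tr) == 0L)
      return(data.frame(sequence = character(0), strand = character(0),
                        start = integer(0), length = integer(0),
                        count = integer(0), nloci = integer(0),
                        ambiguous = logical(0)))
    key <- paste(tr$strand, tr$start, tr$length)
    agg <- tr[!duplicated(key), c("strand", "start", "length")]
    agg$count <- as.integer(table(key)[paste(agg$strand, agg$start,
                                             agg$length)])
    df <- agg
  } else {
    stopifnot(is.data.frame(x), "count" %in% names(x))
    df <- x[x$origin %in% targetOrigins & x$count > 0, , drop = FALSE]
    df <- df[, c("sequence", "strand", "start", "length", "count")]
  }
  df$strand <- ifelse(df$strand == "sense", "+", "-")
  if (!"sequence" %in% names(df)) {
    if (is.null(target)) {
      df$sequence <- NA_character_
    } else {
      s <- substring(target, df$start + 1L, df$start + df$length)
      df$sequence <- ifelse(df$strand == "+", s, .revComp(s))
    }
  }
  df$nloci <- 1L
  df$ambiguous <- FALSE
  rownames(df) <- NULL
  df[, c("sequence", "strand", "start", "length", "count", "nloci",
         "ambiguous")]
}
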