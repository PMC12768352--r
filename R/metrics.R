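# One record per distinct sequence, with a strand class: reads hitting loci
# on both strands (reverse-complement palindromes or true two-strand
# multi-locus reads) are "ambiguous" and excluded from strand-resolved
# outputs but kept in combined tallies.
.perSequence <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(sequence = character(0), length = integer(0),
                      count = integer(0), nloci = integer(0),
                      strand = character(0)))
  strands <- tapply(hits$strand, hits$sequence,
                    function(s) if (length(unique(s)) > 1L) "ambiguous"
                                else s[1L])
  df <- hits[!duplicated(hits$sequence),
             c("sequence", "length", "count", "nloci", "ambiguous"),
             drop = FALSE]
  df$strand <- unname(strands[df$sequence])
  df$strand[df$ambiguous] <- "ambiguous"
  df$ambiguous <- NULL
  rownames(df) <- NULL
  df
}

#' Spike-in and RPM normalization of target-mapped counts
#'
#' The spike-in factor is the mean of the four per-spike-in read counts
#' (each spike-in entered the library at the same fixed molar input); the
#' normalized count is `raw / factor` and is invariant to uniform depth
#' rescaling. RPM uses 10^6 x raw / denominator, where the denominator is
#' either all reads assigned to genome + target (`"mapped_total"`, default)
#' or all length-filtered reads (`"filtered_total"`); the choice is echoed
#' in the result because it is a convention, not a given.
#'
#' @param assigned an [AssignedLibrary-class].
#' @param denominator RPM denominator definition.
#' @param method `"both"` (default), `"spikein"` or `"rpm"`. A spike-in with
#'   zero reads is an error whenever spike-in normalization is requested;
#'   RPM alone still works.
#' @return list with elements `raw`, `spikeinCounts`, `spikeinFactor`,
#'   `spikeinNormalized`, `rpm`, `denominator`, `denominatorDef`.
#' @export
normalizeCounts <- function(assigned,
                            denominator = c("mapped_total", "filtered_total"),
                            method = c("both", "spikein", "rpm")) {
  stopifnot(is(assigned, "AssignedLibrary"))
  denominator <- match.arg(denominator)
  method <- match.arg(method)
  per <- assigned@totals$perCompartment
  raw <- unname(per["target"])
  out <- list(raw = raw, spikeinCounts = NULL, spikeinFactor = NA_real_,
              spikeinNormalized = NA_real_, rpm = NA_real_,
              denominator = NA_real_, denominatorDef = denominator)
  if (method %in% c("both", "spikein")) {
    sc <- assigned@spikeinCounts
    if (any(sc == 0))
      stop("spike-in '", names(sc)[sc == 0][1L],
           "' has zero reads; spike-in normalization is undefined")
    out$spikeinCounts <- sc
    out$spikeinFactor <- mean(sc)
    out$spikeinNormalized <- raw / out$spikeinFactor
  }
  if (method %in% c("both", "rpm")) {
    den <- switch(denominator,
                  mapped_total = unname(per["genome"] + per["target"]),
                  filtered_total = assigned@totals$filtered)
    if (den == 0) stop("RPM denominator is zero")
    out$denominator <- den
    out$rpm <- raw * 1e6 / den
  }
  out
}

#' Mean, standard deviation and standard error across replicates
#'
#' @param x numeric vector of per-replicate values (NA dropped).
#' @return list with `mean`, `sd`, `se`, `n`.
#' @export
averageReplicates <- function(x) .meanSdSe(x)

#' Size distribution of target-mapped reads
#'
#' Multiplicity-weighted counts per read length and strand. Each distinct
#' sequence is counted once (multi-locus reads are not double-counted);
#' ambiguous-strand reads enter the combined column only.
#'
#' @param hits hit data.frame ([targetHits()]).
#' @param lengths lengths to tabulate (default 18-30 nt).
#' @return list with `table` (data.frame: length, sense, antisense,
#'   combined), `modes` (lengths sharing the maximal combined count; empty
#'   when there are no reads) and `total`.
#' @export
sizeDistribution <- function(hits, lengths = 18:30) {
  ps <- .perSequence(hits)
  tab <- data.frame(length = as.integer(lengths))
  sumBy <- function(keep) {
    vapply(lengths, function(L) sum(ps$count[keep & ps$length == L]),
           numeric(1))
  }
  tab$sense <- sumBy(ps$strand == "+")
  tab$antisense <- sumBy(ps$strand == "-")
  tab$combined <- sumBy(rep(TRUE, nrow(ps)))
  modes <- if (sum(tab$combined) > 0)
    tab$length[tab$combined == max(tab$combined)] else integer(0)
  list(table = tab, modes = modes, total = sum(tab$combined))
}

#' Strand-resolved per-base coverage of the target
#'
#' Every locus of a multi-locus read contributes `count / nloci`, so total
#' coverage mass equals the sum of length x count over (non-ambiguous)
#' reads. Ambiguous-strand reads are excluded.
#'
#' @param hits hit data.frame ([targetHits()]).
#' @param targetLength length of the target sequence.
#' @return list with numeric vectors `sense` and `antisense` (per-base
#'   depth, position 1 = target base 0), `targetLength` and `mass`.
#' @export
coverageProfile <- function(hits, targetLength) {
  h <- hits[!hits$ambiguous, , drop = FALSE]
  if (nrow(h) && (any(h$start < 0) ||
                  any(h$start + h$length > targetLength)))
    stop("hit outside the target bounds")
  addCov <- function(rows) {
    d <- numeric(targetLength + 1L)
    if (nrow(rows)) {
      w <- rows$count / rows$nloci
      for (j in seq_len(nrow(rows))) {
        a <- rows$start[j] + 1L
        b <- rows$start[j] + rows$length[j] + 1L
        d[a] <- d[a] + w[j]
        d[b] <- d[b] - w[j]
      }
    }
    cumsum(d)[seq_len(targetLength)]
  }
  sense <- addCov(h[h$strand == "+", , drop = FALSE])
  antisense <- addCov(h[h$strand == "-", , drop = FALSE])
  list(sense = sense, antisense = antisense, targetLength = targetLength,
       mass = sum(sense) + sum(antisense))
}

#' Write a coverage track as bedGraph
#'
#' @param coverage result of [coverageProfile()].
#' @param path output file.
#' @param strand which track to write.
#' @param targetName sequence name used in the track.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(coverage, path, strand = c("sense", "antisense"),
                          targetName = "target") {
  strand <- match.arg(strand)
  v <- coverage[[strand]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  gr <- GenomicRanges::GRanges(
    targetName,
    IRanges::IRanges(start = ends - r$lengths + 1L, end = ends),
    score = r$values)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Dicer phasing registers modulo m
#'
#' 5' positions of unique 20-22 nt single-locus reads are reduced modulo
#' `m` (20 or 21), each strand measured along its own 5'->3' axis: `+` reads
#' use `start`, `-` reads use `targetLength - start - length`. Register
#' fractions are reported per strand and pooled (per-strand counts summed by
#' register index), with a chi-square goodness-of-fit test against
#' uniformity over the m registers. Processive end-initiated dicing
#' concentrates each strand in one register; internal initiation spreads 5'
#' ends across registers. The categorical call requires both a small pooled
#' chi-square p-value and a dominant register (`maxRegisterFraction` above
#' `fracThreshold`, default `2/m`): hotspot structure alone inflates the
#' chi-square, so the dominance guard keeps "phased" reserved for true
#' periodicity.
#'
#' @param hits unique-hit data.frame ([uniqueHits()]).
#' @param m phasing modulus (>= 2).
#' @param targetLength length of the target sequence.
#' @param pThreshold,fracThreshold verdict thresholds (defaults 1e-3 and
#'   `2/m`).
#' @return list with `m`, `registers` (data.frame of per-register counts and
#'   fractions, per strand and pooled), `n` (reads used per strand and
#'   pooled), `maxRegisterFraction` (max over per-strand fractions),
#'   `chisq` (statistic and p per strand and pooled) and `verdict`
#'   (`"phased"`, `"unphased"` or `"undefined"` when no reads are left).
#' @export
phasingProfile <- function(hits, m = 21L, targetLength,
                           pThreshold = 1e-3, fracThreshold = NULL) {
  if (m < 2L) stop("modulus m must be >= 2")
  if (is.null(fracThreshold)) fracThreshold <- 2 / m
  p5 <- ifelse(hits$strand == "+", hits$start,
               targetLength - hits$start - hits$length)
  reg <- p5 %% m
  countReg <- function(keep) {
    vapply(0:(m - 1L), function(r) sum(hits$count[keep & reg == r]),
           numeric(1))
  }
  senseC <- countReg(hits$strand == "+")
  antiC <- countReg(hits$strand == "-")
  pooledC <- senseC + antiC
  frac <- function(x) if (sum(x) > 0) x / sum(x) else rep(NA_real_, m)
  registers <- data.frame(register = 0:(m - 1L),
                          sense_count = senseC,
                          sense_fraction = frac(senseC),
                          antisense_count = antiC,
                          antisense_fraction = frac(antiC),
                          pooled_count = pooledC,
                          pooled_fraction = frac(pooledC))
  chisq <- list(sense = .chisqUniform(senseC),
                antisense = .chisqUniform(antiC),
                pooled = .chisqUniform(pooledC))
  perStrandMax <- suppressWarnings(
    max(c(registers$sense_fraction, registers$antisense_fraction),
        na.rm = TRUE))
  if (!is.finite(perStrandMax)) perStrandMax <- NA_real_
  n <- c(sense = sum(senseC), antisense = sum(antiC), pooled = sum(pooledC))
  verdict <- if (n["pooled"] == 0) {
    "undefined"
  } else if (!is.na(chisq$pooled$p.value) &&
             chisq$pooled$p.value < pThreshold &&
             !is.na(perStrandMax) && perStrandMax > fracThreshold) {
    "phased"
  } else {
    "unphased"
  }
  list(m = as.integer(m), registers = registers, n = n,
       maxRegisterFraction = perStrandMax, chisq = chisq, verdict = verdict,
       thresholds = c(p = pThreshold, fraction = fracThreshold))
}

#' Positional nucleotide composition of target-mapped reads
#'
#' Frequency of A/C/G/T per position over reads of exactly length `L`.
#' `"total"` mode weights each read by its multiplicity; `"unique"` mode
#' weights each distinct sequence once — the two differ whenever counts are
#' skewed, which is what a composition bias check is after.
#'
#' @param hits hit data.frame ([targetHits()]).
#' @param L read length to profile.
#' @param mode `"total"` or `"unique"`.
#' @return 4 x L matrix (rows A, C, G, T; columns sum to 1) with attribute
#'   `nReads`; all-NA with `nReads = 0` when no read has length `L`.
#' @export
compositionMatrix <- function(hits, L, mode = c("total", "unique")) {
  mode <- match.arg(mode)
  ps <- .perSequence(hits)
  ps <- ps[ps$length == L, , drop = FALSE]
  nt <- c("A", "C", "G", "T")
  if (nrow(ps) == 0L) {
    mat <- matrix(NA_real_, 4L, L, dimnames = list(nt, NULL))
    attr(mat, "nReads") <- 0
    return(mat)
  }
  w <- if (mode == "total") ps$count else rep(1L, nrow(ps))
  mat <- vapply(seq_len(L), function(j) {
    ch <- substring(ps$sequence, j, j)
    vapply(nt, function(b) sum(w[ch == b]), numeric(1)) / sum(w)
  }, numeric(4))
  rownames(mat) <- nt
  attr(mat, "nReads") <- sum(w)
  mat
}

#' Full per-library siRNA characterization
#'
#' Convenience wrapper bundling normalization, size distribution, coverage,
#' phasing (both moduli) and composition for one assigned library.
#'
#' @param assigned an [AssignedLibrary-class].
#' @param denominator RPM denominator (see [normalizeCounts()]).
#' @param phaseModuli phasing moduli to evaluate.
#' @param compositionLengths lengths to profile (total and unique modes).
#' @return named list of the individual metric results.
#' @export
libraryMetrics <- function(assigned, denominator = "mapped_total",
                           phaseModuli = c(20L, 21L),
                           compositionLengths = c(20L, 21L)) {
  hits <- targetHits(assigned)
  uh <- uniqueHits(hits)
  tl <- assigned@targetLength
  list(
    normalized = normalizeCounts(assigned, denominator = denominator),
    sizeDistribution = sizeDistribution(hits),
    coverage = coverageProfile(hits, tl),
    phasing = stats::setNames(
      lapply(phaseModuli, function(m) phasingProfile(uh, m, tl)),
      paste0("mod", phaseModuli)),
    composition = stats::setNames(lapply(compositionLengths, function(L) {
      list(total = compositionMatrix(hits, L, "total"),
           unique = compositionMatrix(hits, L, "unique"))
    }), paste0("len", compositionLengths)))
}

#' Write per-library metrics to a directory
#'
#' Emits a JSON summary, size-distribution and phasing TSVs, composition
#' TSVs, and one bedGraph per strand.
#'
#' @param metrics result of [libraryMetrics()].
#' @param dir output directory.
#' @param sample sample name used as file prefix.
#' @param targetName sequence name for the bedGraph tracks.
#' @return `dir`, invisibly.
#' @export
writeMetrics <- function(metrics, dir, sample = "library",
                         targetName = "target") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, sample)
  norm <- metrics$normalized
  summary <- list(
    raw = norm$raw, spikeinFactor = norm$spikeinFactor,
    spikeinNormalized = norm$spikeinNormalized, rpm = norm$rpm,
    rpmDenominator = norm$denominatorDef,
    sizeModes = metrics$sizeDistribution$modes,
    phasing = lapply(metrics$phasing, function(p)
      list(m = p$m, maxRegisterFraction = p$maxRegisterFraction,
           pooledP = p$chisq$pooled$p.value, verdict = p$verdict)))
  jsonlite::write_json(summary, paste0(pre, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(metrics$sizeDistribution$table,
                     paste0(pre, "_size_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(metrics$phasing))
    utils::write.table(metrics$phasing[[nm]]$registers,
                       paste0(pre, "_phasing_", nm, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(metrics$composition)) {
    comp <- metrics$composition[[nm]]
    for (mode in names(comp))
      utils::write.table(comp[[mode]],
                         paste0(pre, "_composition_", nm, "_", mode, ".tsv"),
                         sep = "\t", quote = FALSE, col.names = FALSE)
  }
  writeBedGraph(metrics$coverage, paste0(pre, "_sense.bedGraph"),
                "sense", targetName)
  writeBedGraph(metrics$coverage, paste0(pre, "_antisense.bedGraph"),
                "antisense", targetName)
  invisible(dir)
}
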