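.DEFAULT_SPIKEIN_NAMES <- c("lin-4-5p", "miR-125a-5p", "miR-148a-3p",
                            "miR-659-5p")

#' Build a reference bundle
#'
#' @param target single named sequence of the target transgene (character or
#'   DNAStringSet of length 1).
#' @param genomeProxy named sequences standing in for the genome (character
#'   vector or DNAStringSet; may be empty).
#' @param mirnas named mature miRNA sequences, 18-24 nt.
#' @param spikeins exactly four spike-in sequences; when unnamed, the
#'   conventional spike-in names (lin-4-5p, miR-125a-5p, miR-148a-3p,
#'   miR-659-5p) are applied in order.
#' @return a [ReferenceBundle-class] object.
#' @export
referenceBundle <- function(target, genomeProxy = character(0),
                            mirnas = character(0), spikeins) {
  asSet <- function(x, what, defaultNames = NULL) {
    if (is(x, "DNAStringSet")) x <- as.character(x) |> stats::setNames(names(x))
    if (length(x) == 0L) return(Biostrings::DNAStringSet())
    seqs <- .normalizeSeq(x, what = what)
    nms <- names(x)
    if (is.null(nms) || any(nms == "")) {
      if (!is.null(defaultNames) && length(x) == length(defaultNames))
        nms <- defaultNames
      else if (is.null(nms))
        nms <- paste0(what, seq_along(x))
    }
    stats::setNames(Biostrings::DNAStringSet(seqs), nms)
  }
  if (is.character(target) && is.null(names(target)))
    names(target) <- "target"
  new("ReferenceBundle",
      target = asSet(target, "target"),
      genomeProxy = asSet(genomeProxy, "genome"),
      mirnas = asSet(mirnas, "mirna"),
      spikeins = asSet(spikeins, "spikein",
                       defaultNames = .DEFAULT_SPIKEIN_NAMES))
}

#' Read or write a reference bundle as FASTA files
#'
#' A bundle directory holds `target.fasta`, `genome.fasta`, `mirnas.fasta`
#' and `spikeins.fasta`.
#'
#' @param dir directory containing (or to receive) the FASTA files.
#' @return for `readReferenceBundle`, a [ReferenceBundle-class]; for
#'   `writeReferenceBundle`, `dir` invisibly.
#' @export
readReferenceBundle <- function(dir) {
  rd <- function(f, required = TRUE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing reference file: ", p, call. = FALSE)
      return(character(0))
    }
    readSequences(p, format = "fasta")
  }
  referenceBundle(target = rd("target.fasta"),
                  genomeProxy = rd("genome.fasta", required = FALSE),
                  mirnas = rd("mirnas.fasta", required = FALSE),
                  spikeins = rd("spikeins.fasta"))
}

#' @rdname readReferenceBundle
#' @param bundle a [ReferenceBundle-class] object.
#' @export
writeReferenceBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(set, f) {
    if (length(set))
      Biostrings::writeXStringSet(set, file.path(dir, f), format = "fasta")
  }
  wr(bundle@target, "target.fasta")
  wr(bundle@genomeProxy, "genome.fasta")
  wr(bundle@mirnas, "mirnas.fasta")
  wr(bundle@spikeins, "spikeins.fasta")
  invisible(dir)
}
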