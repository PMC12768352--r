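#' Read small-RNA sequences from FASTA or FASTQ
#'
#' Sequences are uppercased and U is coerced to T; records containing any
#' other non-ACGT character are rejected, because downstream assignment is
#' exact matching. Names are truncated at the first whitespace.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return named character vector of sequences.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgu"), tf)
#' readSequences(tf)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("no ", format, " records parsed from '", path,
         "' (empty or mixed-format file?)", call. = FALSE)
  seqs <- .normalizeSeq(as.character(set), what = basename(path))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTQ records get a constant Q40 quality string; qualities are never used
#' downstream.
#'
#' @param seqs named character vector (or DNAStringSet) of sequences.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"` (default from extension).
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%06d", seq_along(seqs))
  if (format == "fastq") {
    Biostrings::writeXStringSet(
      seqs, path, format = "fastq",
      qualities = Biostrings::PhredQuality(strrep("I", Biostrings::width(seqs))))
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}

#' Collapse reads into unique sequences with multiplicities
#'
#' @param reads character vector (or DNAStringSet) of read sequences.
#' @return data.frame with columns `sequence` and `count`, ordered by
#'   decreasing count then sequence. Counts conserve the input total.
#' @seealso [expandReads()] for the inverse (up to read order).
#' @export
collapseReads <- function(reads) {
  reads <- as.character(reads)
  if (length(reads) == 0L)
    return(data.frame(sequence = character(0), count = integer(0)))
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out[order(-out$count, out$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' @rdname collapseReads
#' @param collapsed a collapsed-read data.frame.
#' @export
expandReads <- function(collapsed) {
  rep(collapsed$sequence, collapsed$count)
}

# Shared TSV loader with the error contract all table loaders follow.
.loadTsv <- function(path, required, numericCols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L)
    stop("'", path, "' contains no data rows", call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in numericCols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric value in column '", col, "' of '", path,
           "' at row ", bad, call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

.checkAgainstSheet <- function(df, sampleSheet, path) {
  if (is.null(sampleSheet)) return(invisible(NULL))
  bad <- setdiff(unique(df$sample), sampleSheet$sample)
  if (length(bad))
    stop("'", path, "' references samples absent from the sample sheet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(NULL)
}

#' Load the experiment design (sample sheet)
#'
#' @param path TSV with columns `sample`, `group`, `replicate`.
#' @return data.frame of the design.
#' @export
loadSampleSheet <- function(path) {
  .loadTsv(path, required = c("sample", "group", "replicate"))
}

#' Load a qPCR Ct table
#'
#' One row per (sample, gene); technical replicates are expected to be
#' averaged beforehand. Duplicated (sample, gene) pairs are an error.
#'
#' @param path TSV with columns `sample`, `group`, `gene`, `ct`.
#' @param sampleSheet optional design data.frame to validate sample keys.
#' @return data.frame of Ct measurements.
#' @export
loadCtTable <- function(path, sampleSheet = NULL) {
  df <- .loadTsv(path, required = c("sample", "group", "gene", "ct"),
                 numericCols = "ct")
  key <- paste(df$sample, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, gene) row in '", path, "': ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  .checkAgainstSheet(df, sampleSheet, path)
  df
}

#' Load a western-blot band-intensity table
#'
#' @param path TSV with columns `membrane`, `sample`, `group`, `protein`,
#'   `intensity`.
#' @param sampleSheet optional design data.frame to validate sample keys.
#' @return data.frame of band intensities.
#' @export
loadBandTable <- function(path, sampleSheet = NULL) {
  df <- .loadTsv(path,
                 required = c("membrane", "sample", "group", "protein",
                              "intensity"),
                 numericCols = "intensity")
  if (any(df$intensity < 0))
    stop("negative band intensity in '", path, "'", call. = FALSE)
  .checkAgainstSheet(df, sampleSheet, path)
  df
}

#' Load a per-embryo fluorescence table
#'
#' @param path TSV with columns `replicate`, `group`, `embryo`,
#'   `mean_intensity`, `background_intensity`.
#' @param sampleSheet optional design data.frame (unused keys are tolerated;
#'   fluorescence replicates are images, not libraries).
#' @return data.frame of fluorescence measurements.
#' @export
loadFluorTable <- function(path, sampleSheet = NULL) {
  df <- .loadTsv(path,
                 required = c("replicate", "group", "embryo",
                              "mean_intensity", "background_intensity"),
                 numericCols = c("mean_intensity", "background_intensity"))
  if (any(df$mean_intensity < 0) || any(df$background_intensity < 0))
    stop("negative intensity in '", path, "'", call. = FALSE)
  df
}
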