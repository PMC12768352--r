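# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps biology/sampling seed separation
# honest: no simulator call leaks randomness into another.
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Uppercase, coerce U->T, and reject anything outside ACGT. Ambiguity codes
# are rejected on purpose: downstream assignment is exact matching, for which
# IUPAC wildcards have no defined semantics.
.normalizeSeq <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  if (any(nchar(x) == 0L))
    stop(what, " contains an empty record", call. = FALSE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("invalid nucleotide alphabet in ", what, " (record ",
         which(bad)[1L], "); only A/C/G/T/U are accepted", call. = FALSE)
  x
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All substrings of length k (for reference k-mer screens).
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), k:n)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  invisible(x)
}

# Chi-square goodness of fit against the uniform distribution over m cells,
# computed directly so zero-count registers never trigger warnings.
.chisqUniform <- function(counts) {
  n <- sum(counts)
  m <- length(counts)
  if (n == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0))
  expected <- n / m
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = m - 1, lower.tail = FALSE),
       n = n)
}

.meanSdSe <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- if (n > 1) stats::sd(x) else NA_real_
  list(mean = mean(x), sd = s, se = if (n > 1) s / sqrt(n) else NA_real_,
       n = n)
}
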