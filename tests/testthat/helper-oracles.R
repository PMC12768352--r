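# Independent brute-force oracles. These deliberately avoid the package's
# own helpers (reverse complement, matching, test wrappers) so that
# agreement is evidence, not tautology.

oracleRevComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# scan every substring of the reference and compare to the read / its
# reverse complement
oracleMatch <- function(read, ref) {
  L <- nchar(read)
  n <- nchar(ref)
  subs <- substring(ref, 1:(n - L + 1L), L:n)
  plus <- which(subs == read) - 1L
  minus <- which(subs == oracleRevComp(read)) - 1L
  out <- data.frame(
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    start = as.integer(c(plus, minus)),
    length = rep(L, length(plus) + length(minus)))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randSeqSeeded <- function(n, seed) {
  set.seed(seed)
  randSeq(n)
}

# one-way ANOVA + Tukey-Kramer from first principles
oracleAnovaTukey <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ns <- tapply(values, group, length)
  means <- tapply(values, group, mean)
  grand <- mean(values)
  sse <- sum((values - means[group])^2)
  dfe <- length(values) - k
  mse <- sse / dfe
  ssb <- sum(ns * (means - grand)^2)
  Fstat <- (ssb / (k - 1)) / mse
  pF <- stats::pf(Fstat, k - 1, dfe, lower.tail = FALSE)
  pairs <- utils::combn(levels(group), 2L, simplify = FALSE)
  tukey <- do.call(rbind, lapply(pairs, function(pr) {
    d <- means[pr[2L]] - means[pr[1L]]
    se <- sqrt(mse / 2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
    q <- abs(d) / se
    data.frame(group1 = pr[2L], group2 = pr[1L], diff = unname(d),
               p = stats::ptukey(q, k, dfe, lower.tail = FALSE))
  }))
  rownames(tukey) <- NULL
  list(F = Fstat, p = pF, tukey = tukey)
}

# Welch two-sample t from first principles
oracleWelchT <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# pooled-variance two-sample t (for the F = t^2 identity)
oraclePooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# exact two-sided Mann-Whitney p by full enumeration (no ties)
oracleWilcoxExact <- function(x, y) {
  u <- sum(outer(x, y, ">"))
  all <- c(x, y)
  n <- length(x)
  splits <- utils::combn(length(all), n, simplify = FALSE)
  us <- vapply(splits, function(ix) {
    sum(outer(all[ix], all[-ix], ">"))
  }, numeric(1))
  pLess <- mean(us <= u)
  pGreater <- mean(us >= u)
  list(U = u, p = min(1, 2 * min(pLess, pGreater)))
}

# Benjamini-Hochberg from the step-up definition
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}
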