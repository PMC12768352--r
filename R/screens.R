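.screenResult <- function(screen, effect, statistic, pValue, verdict,
                          details = list()) {
  new("ScreenResult", screen = screen, effect = effect,
      statistic = as.numeric(statistic), pValue = as.numeric(pValue),
      verdict = verdict, details = details)
}

# two-sample t p-value that survives constant data
.safeT <- function(x, y = NULL, ...) {
  tryCatch(stats::t.test(x, y, ...),
           error = function(e) {
             d <- if (is.null(y)) mean(x) - list(...)$mu
                  else mean(x) - mean(y)
             list(statistic = NA_real_,
                  p.value = if (abs(d) < 1e-12) 1 else 0)
           })
}

#' Screen for secondary siRNAs mapping upstream of the injected interval
#'
#' When only the 3' half of the target is injected, reads mapping entirely
#' upstream of the injected interval cannot be direct dicing products of the
#' trigger; their presence indicates amplification templated on the target
#' mRNA. The effect is the per-replicate fraction of target-mapped reads
#' (per-locus weighted) lying entirely within `[0, interval start)`; the
#' normalization factor cancels in this within-library ratio. The verdict is
#' `"signal"` when the mean fraction exceeds `tau` and a one-sample t-test
#' against `tau` (alternative: greater) rejects at `alpha`.
#'
#' @param hitsList list of per-replicate hit data.frames ([targetHits()] or
#'   [truthHits()]).
#' @param injectedInterval 0-based half-open interval of the trigger on the
#'   target; the interval start must be positive (otherwise there is no
#'   upstream region to screen).
#' @param tau upstream-fraction tolerance (absorbs chance multi-locus
#'   artifacts).
#' @param alpha test level.
#' @return a [ScreenResult-class]; `"underpowered"` with fewer than 2
#'   replicates.
#' @export
upstreamTest <- function(hitsList, injectedInterval, tau = 0.01,
                         alpha = 0.05) {
  istart <- injectedInterval[1L]
  if (istart <= 0)
    stop("injected interval starts at 0: no upstream region to screen")
  fractions <- vapply(hitsList, function(h) {
    w <- h$count / h$nloci
    tot <- sum(w)
    if (tot == 0) return(NA_real_)
    sum(w[h$start + h$length <= istart]) / tot
  }, numeric(1))
  fractions <- fractions[!is.na(fractions)]
  eff <- c(upstream_fraction = mean(fractions))
  details <- list(perReplicate = fractions, tau = tau,
                  n = length(fractions))
  if (length(fractions) < 2L)
    return(.screenResult("upstream", eff, NA_real_, NA_real_,
                         "underpowered", details))
  if (stats::sd(fractions) == 0) {
    p <- if (mean(fractions) > tau) 0 else 1
    stat <- NA_real_
  } else {
    tt <- stats::t.test(fractions, mu = tau, alternative = "greater")
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  verdict <- if (!is.na(p) && mean(fractions) > tau && p < alpha)
    "signal" else "no_signal"
  .screenResult("upstream", eff, stat, p, verdict, details)
}

#' RppH-contrast screen for 5'-triphosphate secondary siRNAs
#'
#' Compares spike-in-normalized target-mapped counts between enzyme-treated
#' and mock-treated libraries prepared from the same RNA. A one-way ANOVA is
#' fitted across all groups with Tukey HSD pairwise contrasts (Tukey-Kramer
#' for unbalanced designs); the effect per contrast is the ratio of treated
#' to mock group means. Triphosphate secondary species are invisible to the
#' standard protocol, so amplification shows up as treated > mock.
#'
#' @param counts data.frame with columns `group`, `replicate`, `value`
#'   (spike-in-normalized target counts).
#' @param treated,mock equal-length character vectors naming the contrast
#'   pairs (treated vs its mock).
#' @param paired use a paired t-test per contrast (replicate-matched)
#'   instead of the ANOVA/Tukey route.
#' @param alpha test level.
#' @return a [ScreenResult-class]: `"signal"` if any contrast has
#'   treated > mock with adjusted p < `alpha`; `"underpowered"` when any
#'   group has fewer than 2 replicates.
#' @export
rpphContrast <- function(counts, treated, mock, paired = FALSE,
                         alpha = 0.05) {
  stopifnot(all(c("group", "replicate", "value") %in% names(counts)),
            length(treated) == length(mock))
  groups <- unique(counts$group)
  if (length(groups) < 2L) stop("at least two groups are required")
  if (!all(c(treated, mock) %in% groups))
    stop("contrast groups absent from the counts table")
  gmeans <- tapply(counts$value, counts$group, mean)
  ratios <- stats::setNames(as.numeric(gmeans[treated] / gmeans[mock]),
                            paste0(treated, "/", mock))
  nPer <- table(counts$group)
  if (any(nPer < 2L))
    return(.screenResult("rpph", ratios, NA_real_, NA_real_, "underpowered",
                         list(groupMeans = gmeans, nPerGroup = nPer)))

  if (paired) {
    contrastP <- vapply(seq_along(treated), function(i) {
      t_ <- counts[counts$group == treated[i], ]
      m_ <- counts[counts$group == mock[i], ]
      m_ <- m_[match(t_$replicate, m_$replicate), ]
      .safeT(t_$value, m_$value, paired = TRUE)$p.value
    }, numeric(1))
    stat <- NA_real_
    omnibusP <- NA_real_
    details <- list(method = "paired t", contrastP = contrastP,
                    groupMeans = gmeans)
  } else {
    counts$group <- factor(counts$group)
    fit <- stats::aov(value ~ group, data = counts)
    an <- summary(fit)[[1L]]
    stat <- an[["F value"]][1L]
    omnibusP <- an[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$group
    contrastP <- vapply(seq_along(treated), function(i) {
      nm1 <- paste0(treated[i], "-", mock[i])
      nm2 <- paste0(mock[i], "-", treated[i])
      row <- rownames(tk) %in% c(nm1, nm2)
      if (!any(row)) return(NA_real_)
      tk[row, "p adj"][1L]
    }, numeric(1))
    details <- list(method = "anova_tukey", anovaF = stat,
                    anovaP = omnibusP, tukey = tk, contrastP = contrastP,
                    groupMeans = gmeans)
  }
  sig <- !is.na(contrastP) & contrastP < alpha & ratios > 1
  verdict <- if (any(sig)) "signal" else "no_signal"
  p <- if (all(is.na(contrastP))) NA_real_ else min(contrastP, na.rm = TRUE)
  .screenResult("rpph", ratios, stat, p, verdict, details)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Natural-log convention: the divergence of distributions with disjoint
#' support is log(2).
#'
#' @param p,q non-negative numeric vectors of equal length (normalized
#'   internally).
#' @return a single non-negative number.
#' @export
jsDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

.asLengthCounts <- function(x) {
  if (is.list(x) && !is.null(x$table))
    return(stats::setNames(x$table$combined, x$table$length))
  x
}

#' Size-shift screen for a secondary siRNA size class
#'
#' Secondary siRNAs in nematodes are 22-nt RdRp products, so amplification
#' shifts the read-length distribution toward 22 nt. The effect combines the
#' difference in per-replicate 22-nt fractions (treated - mock) with the
#' Jensen-Shannon divergence between the pooled length distributions; the
#' verdict requires a positive fraction difference, a two-sample t-test at
#' `alpha` and divergence above `jsThreshold`.
#'
#' @param treated,mock lists of per-replicate length distributions: either
#'   [sizeDistribution()] results or named count vectors (names = lengths).
#' @param shiftLength diagnostic length (default 22).
#' @param jsThreshold minimal pooled divergence.
#' @param alpha test level.
#' @return a [ScreenResult-class]; `"underpowered"` when a replicate has a
#'   zero-total distribution or an arm has fewer than 2 replicates.
#' @export
sizeShiftTest <- function(treated, mock, shiftLength = 22L,
                          jsThreshold = 0.01, alpha = 0.05) {
  tr <- lapply(treated, .asLengthCounts)
  mo <- lapply(mock, .asLengthCounts)
  allLens <- sort(unique(as.integer(c(unlist(lapply(tr, names)),
                                      unlist(lapply(mo, names))))))
  align <- function(v) {
    out <- stats::setNames(numeric(length(allLens)), allLens)
    out[names(v)] <- v
    out
  }
  tr <- lapply(tr, align)
  mo <- lapply(mo, align)
  totals <- c(vapply(tr, sum, numeric(1)), vapply(mo, sum, numeric(1)))
  key <- as.character(shiftLength)
  frac22 <- function(v) if (key %in% names(v)) v[[key]] / sum(v) else 0
  if (any(totals == 0))
    return(.screenResult("size_shift",
                         c(diff_fraction = NA_real_, jsd = NA_real_),
                         NA_real_, NA_real_, "underpowered",
                         list(reason = "zero-total size distribution")))
  fT <- vapply(tr, frac22, numeric(1))
  fM <- vapply(mo, frac22, numeric(1))
  pT <- Reduce(`+`, lapply(tr, function(v) v / sum(v))) / length(tr)
  pM <- Reduce(`+`, lapply(mo, function(v) v / sum(v))) / length(mo)
  jsd <- jsDivergence(pT, pM)
  eff <- c(diff_fraction = mean(fT) - mean(fM), jsd = jsd)
  details <- list(treatedFractions = fT, mockFractions = fM,
                  shiftLength = shiftLength, jsThreshold = jsThreshold)
  if (length(fT) < 2L || length(fM) < 2L)
    return(.screenResult("size_shift", eff, NA_real_, NA_real_,
                         "underpowered", details))
  tt <- .safeT(fT, fM)
  verdict <- if (!is.na(tt$p.value) && tt$p.value < alpha &&
                 eff["diff_fraction"] > 0 && jsd > jsThreshold)
    "signal" else "no_signal"
  .screenResult("size_shift", eff, unname(tt$statistic), tt$p.value,
                verdict, details)
}

#' Argonaute-loading enrichment of target siRNAs over miRNAs
#'
#' For RISC-isolated (IP) libraries: compares the RPM of target-mapped reads
#' with the RPM of the miRNA compartment (after the >= 2-read guide filter,
#' see [mirnaTotals()]) across replicates; efficient loading of siRNAs shows
#' up as a ratio above 1.
#'
#' @param assignedList list of [AssignedLibrary-class], one per replicate.
#' @param minReads miRNA guide filter threshold.
#' @param alpha test level.
#' @return a [ScreenResult-class]: effect is the ratio of mean target RPM to
#'   mean miRNA RPM, tested by a paired two-tailed t-test across replicates;
#'   `"underpowered"` with < 2 replicates or a zero miRNA count anywhere.
#' @export
loadingEnrichment <- function(assignedList, minReads = 2L, alpha = 0.05) {
  mt <- mirnaTotals(assignedList, minReads = minReads)
  per <- vapply(assignedList, function(a) {
    p <- compartmentCounts(a)
    c(target = unname(p["target"]),
      denom = unname(p["genome"] + p["target"]))
  }, numeric(2))
  mirna <- mt$totals
  n <- length(assignedList)
  if (any(per["denom", ] == 0))
    return(.screenResult("loading", c(ratio = NA_real_), NA_real_, NA_real_,
                         "underpowered",
                         list(reason = "zero mapped reads in a replicate")))
  targetRPM <- per["target", ] * 1e6 / per["denom", ]
  mirnaRPM <- mirna * 1e6 / per["denom", ]
  eff <- c(ratio = mean(targetRPM) / mean(mirnaRPM))
  details <- list(targetRPM = targetRPM, mirnaRPM = mirnaRPM,
                  guidesKept = mt$kept)
  if (n < 2L || any(mirna == 0))
    return(.screenResult("loading", eff, NA_real_, NA_real_, "underpowered",
                         details))
  tt <- .safeT(targetRPM, mirnaRPM, paired = TRUE)
  verdict <- if (!is.na(tt$p.value) && eff["ratio"] > 1 &&
                 tt$p.value < alpha) "signal" else "no_signal"
  .screenResult("loading", eff, unname(tt$statistic), tt$p.value, verdict,
                details)
}
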