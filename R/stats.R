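#' Comparative-Ct (2^-ddCt) fold changes
#'
#' For each sample, dCt = Ct(target gene) - Ct(reference gene); ddCt is
#' taken relative to the mean dCt of the control group, and the fold change
#' is 2^-ddCt. Group tests compare dCt values between each treated group and
#' the control with a Student t-test whose tail must be declared by the
#' caller (knockdown corresponds to treated dCt greater than control, i.e.
#' `alternative = "greater"`). Fold changes are scale-free: adding a
#' constant to every Ct leaves them unchanged.
#'
#' @param ct Ct data.frame ([loadCtTable()]): sample, group, gene, ct.
#' @param targetGene,referenceGene gene labels in the table.
#' @param controlGroup group used as the ddCt baseline.
#' @param alternative t-test tail for dCt(treated) vs dCt(control).
#' @return list with `perSample` (sample, group, dct, ddct, foldChange),
#'   `summary` (per group: mean/sd fold change, knockdown percent) and
#'   `tests` (one row per treated group: statistic, p).
#' @export
ddct <- function(ct, targetGene, referenceGene, controlGroup,
                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  tgt <- ct[ct$gene == targetGene, ]
  ref <- ct[ct$gene == referenceGene, ]
  if (nrow(tgt) == 0L) stop("target gene '", targetGene, "' not in table")
  i <- match(tgt$sample, ref$sample)
  if (anyNA(i))
    stop("missing reference gene '", referenceGene, "' for sample(s): ",
         paste(tgt$sample[is.na(i)], collapse = ", "))
  per <- data.frame(sample = tgt$sample, group = tgt$group,
                    dct = tgt$ct - ref$ct[i])
  if (!controlGroup %in% per$group)
    stop("control group '", controlGroup, "' has no samples")
  controlMean <- mean(per$dct[per$group == controlGroup])
  per$ddct <- per$dct - controlMean
  per$foldChange <- 2^(-per$ddct)
  groups <- unique(per$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    fc <- per$foldChange[per$group == g]
    data.frame(group = g, n = length(fc), meanFoldChange = mean(fc),
               sdFoldChange = if (length(fc) > 1) stats::sd(fc) else NA_real_,
               knockdownPercent = (1 - mean(fc)) * 100)
  }))
  treatedGroups <- setdiff(groups, controlGroup)
  tests <- do.call(rbind, lapply(treatedGroups, function(g) {
    x <- per$dct[per$group == g]
    y <- per$dct[per$group == controlGroup]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(group = g, statistic = NA_real_, p = NA_real_))
    tt <- .safeT(x, y, alternative = alternative)
    data.frame(group = g, statistic = unname(tt$statistic), p = tt$p.value)
  }))
  list(perSample = per, summary = summary, tests = tests,
       alternative = alternative, controlGroup = controlGroup)
}

#' Western-band double normalization and fold changes
#'
#' Within each membrane, intensities are first divided by the darkest
#' (maximal) band of that membrane — removing per-membrane exposure — and
#' each investigated protein is then divided by the loading control of the
#' same lane. Fold changes are relative to the control-group mean. The group
#' test is a two-tailed Student t-test, or a Mann-Whitney test when a
#' Shapiro-Wilk check (alpha = 0.05, either group) flags non-normality; the
#' gate's choice is returned.
#'
#' @param bands band table ([loadBandTable()]).
#' @param controlGroup baseline group.
#' @param loadingControl loading-control protein (default GAPDH).
#' @param test `"auto"` (Shapiro-gated), `"t"` or `"mann_whitney"`.
#' @return list with `ratios` (per lane and protein), `folds` (fold change
#'   vs control mean) and `tests` (per protein and group: method, statistic,
#'   p).
#' @export
bandNorm <- function(bands, controlGroup, loadingControl = "GAPDH",
                     test = c("auto", "t", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(all(c("membrane", "sample", "group", "protein", "intensity")
                %in% names(bands)))
  ratios <- list()
  for (mb in unique(bands$membrane)) {
    sub <- bands[bands$membrane == mb, ]
    darkest <- max(sub$intensity)
    if (darkest <= 0) stop("membrane '", mb, "' has no signal")
    sub$norm <- sub$intensity / darkest
    lc <- sub[sub$protein == loadingControl, ]
    other <- sub[sub$protein != loadingControl, ]
    j <- match(other$sample, lc$sample)
    if (anyNA(j))
      stop("membrane '", mb, "' lacks a ", loadingControl,
           " band for sample(s): ",
           paste(unique(other$sample[is.na(j)]), collapse = ", "))
    if (any(lc$norm[j] == 0))
      stop("zero ", loadingControl, " intensity on membrane '", mb, "'")
    other$ratio <- other$norm / lc$norm[j]
    ratios[[length(ratios) + 1L]] <-
      other[, c("membrane", "sample", "group", "protein", "ratio")]
  }
  ratios <- do.call(rbind, ratios)
  rownames(ratios) <- NULL
  if (!controlGroup %in% ratios$group)
    stop("control group '", controlGroup, "' has no lanes")

  folds <- list()
  tests <- list()
  for (pr in unique(ratios$protein)) {
    rp <- ratios[ratios$protein == pr, ]
    ctrlMean <- mean(rp$ratio[rp$group == controlGroup])
    rp$foldChange <- rp$ratio / ctrlMean
    folds[[pr]] <- rp
    for (g in setdiff(unique(rp$group), controlGroup)) {
      x <- rp$ratio[rp$group == g]
      y <- rp$ratio[rp$group == controlGroup]
      method <- test
      if (test == "auto") {
        normal <- function(v) {
          if (length(v) < 3L || stats::sd(v) == 0) return(TRUE)
          stats::shapiro.test(v)$p.value >= 0.05
        }
        method <- if (normal(x) && normal(y)) "t" else "mann_whitney"
      }
      res <- if (method == "t") {
        tt <- .safeT(x, y)
        c(unname(tt$statistic), tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x, y))
        c(unname(wt$statistic), wt$p.value)
      }
      tests[[length(tests) + 1L]] <-
        data.frame(protein = pr, group = g, method = method,
                   statistic = res[1L], p = res[2L])
    }
  }
  list(ratios = ratios, folds = do.call(rbind, folds),
       tests = do.call(rbind, tests))
}

#' Per-replicate fluorescence summaries and group comparison
#'
#' Background is subtracted per embryo (clamped at zero with a warning when
#' background exceeds signal); replicate values are the mean over the 20-30
#' embryos of an image (a count outside that range draws a warning), and
#' groups are compared by a two-tailed t-test on replicate means.
#'
#' @param fluor fluorescence table ([loadFluorTable()]).
#' @return list with `embryos` (net intensities), `replicates` (per-image
#'   means) and `tests` (pairwise group comparisons on replicate means).
#' @export
fluorSummary <- function(fluor) {
  net <- fluor$mean_intensity - fluor$background_intensity
  if (any(net < 0)) {
    warning(sum(net < 0),
            " embryo(s) with background above signal; clamped to 0")
    net <- pmax(net, 0)
  }
  fluor$net <- net
  key <- interaction(fluor$group, fluor$replicate, drop = TRUE)
  sizes <- table(key)
  if (any(sizes < 20L | sizes > 30L))
    warning("image(s) with embryo count outside 20-30: ",
            paste(names(sizes)[sizes < 20L | sizes > 30L], collapse = ", "))
  reps <- stats::aggregate(net ~ group + replicate, data = fluor, FUN = mean)
  groups <- unique(reps$group)
  tests <- list()
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    for (pr in pairs) {
      x <- reps$net[reps$group == pr[1L]]
      y <- reps$net[reps$group == pr[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        tests[[length(tests) + 1L]] <-
          data.frame(group1 = pr[1L], group2 = pr[2L],
                     statistic = NA_real_, p = NA_real_,
                     note = "fewer than 2 replicates")
        next
      }
      tt <- .safeT(x, y)
      tests[[length(tests) + 1L]] <-
        data.frame(group1 = pr[1L], group2 = pr[2L],
                   statistic = unname(tt$statistic), p = tt$p.value,
                   note = "")
    }
  }
  list(embryos = fluor, replicates = reps,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' miRNA guide filter and per-replicate totals
#'
#' A guide is retained when it has at least `minReads` reads in at least one
#' replicate; totals per replicate sum the retained guides. A
#' spike-in-normalized variant (totals divided by each library's spike-in
#' factor) is also returned for cross-treatment comparisons of the miRNA
#' pool.
#'
#' @param assignedList list of [AssignedLibrary-class], one per replicate.
#' @param minReads retention threshold (default 2).
#' @return list with `guides` (filtered guide x replicate count matrix),
#'   `totals`, `normalizedTotals` (NA when a library lacks a spike-in),
#'   `kept` and `dropped` guide names.
#' @export
mirnaTotals <- function(assignedList, minReads = 2L) {
  stopifnot(length(assignedList) >= 1L)
  counts <- vapply(assignedList, mirnaCounts,
                   numeric(length(mirnaCounts(assignedList[[1L]]))))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(names(mirnaCounts(assignedList[[1L]])),
                                     NULL))
  if (is.null(colnames(counts)))
    colnames(counts) <- if (!is.null(names(assignedList)))
      names(assignedList) else paste0("rep", seq_len(ncol(counts)))
  keep <- apply(counts, 1L, max) >= minReads
  guides <- counts[keep, , drop = FALSE]
  totals <- colSums(guides)
  factors <- vapply(assignedList, function(a) {
    sc <- spikeinCounts(a)
    if (any(sc == 0)) NA_real_ else mean(sc)
  }, numeric(1))
  if (anyNA(factors))
    warning("zero spike-in counts in some libraries; ",
            "normalized totals set to NA there")
  list(guides = guides, totals = totals,
       normalizedTotals = totals / factors,
       kept = rownames(guides), dropped = rownames(counts)[!keep])
}

#' The statistical test battery used across the quantitative analyses
#'
#' Dispatches the tests used for group comparisons: one- or two-tailed
#' Student t (two groups), one-way ANOVA with Tukey HSD post-hoc contrasts,
#' Kruskal-Wallis with pairwise Wilcoxon rank-sum tests under
#' Benjamini-Hochberg FDR correction, or a plain Mann-Whitney test. A
#' one-tailed direction is never inferred from the data: the caller must
#' declare `alternative`.
#'
#' @param values numeric measurements.
#' @param group group label per value.
#' @param test which battery entry to run.
#' @param alternative tail for the one-tailed t-test (`"greater"` tests
#'   group1 > group2 in the order of factor levels).
#' @return list with `omnibus` (data.frame: method, statistic, p; NULL for
#'   plain two-group tests) and `pairwise` (data.frame: group1, group2,
#'   statistic, p, p.adj where applicable).
#' @export
testBattery <- function(values, group,
                        test = c("t_two_tailed", "t_one_tailed",
                                 "anova_tukey", "kruskal_wilcoxon_fdr",
                                 "mann_whitney"),
                        alternative = NULL) {
  test <- match.arg(test)
  group <- factor(group)
  lv <- levels(group)
  sizes <- table(group)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  parametric <- test %in% c("t_two_tailed", "t_one_tailed", "anova_tukey")
  if (parametric &&
      all(tapply(values, group, stats::var) == 0))
    stop("degenerate variance: all groups are constant; ",
         "use a rank-based test")

  if (test %in% c("t_two_tailed", "t_one_tailed", "mann_whitney")) {
    if (length(lv) != 2L) stop(test, " requires exactly two groups")
    x <- values[group == lv[1L]]
    y <- values[group == lv[2L]]
    if (test == "t_one_tailed") {
      if (is.null(alternative) ||
          !alternative %in% c("greater", "less"))
        stop("one-tailed t-test requires alternative = 'greater' or 'less'")
      tt <- stats::t.test(x, y, alternative = alternative)
    } else if (test == "t_two_tailed") {
      tt <- stats::t.test(x, y)
    } else {
      tt <- suppressWarnings(stats::wilcox.test(x, y))
    }
    pw <- data.frame(group1 = lv[1L], group2 = lv[2L],
                     statistic = unname(tt$statistic), p = tt$p.value)
    return(list(omnibus = NULL, pairwise = pw, method = test))
  }

  if (length(lv) < 3L)
    stop(test, " requires at least three groups")
  df <- data.frame(values = values, group = group)
  if (test == "anova_tukey") {
    fit <- stats::aov(values ~ group, data = df)
    an <- summary(fit)[[1L]]
    omnibus <- data.frame(method = "anova",
                          statistic = an[["F value"]][1L],
                          p = an[["Pr(>F)"]][1L])
    tk <- stats::TukeyHSD(fit)$group
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group1 = vapply(cmp, `[`, "", 1L),
                     group2 = vapply(cmp, `[`, "", 2L),
                     statistic = tk[, "diff"], p = tk[, "p adj"])
    rownames(pw) <- NULL
    return(list(omnibus = omnibus, pairwise = pw, method = test))
  }
  # kruskal_wilcoxon_fdr
  kw <- stats::kruskal.test(values ~ group, data = df)
  omnibus <- data.frame(method = "kruskal_wallis",
                        statistic = unname(kw$statistic), p = kw$p.value)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- suppressWarnings(
      stats::wilcox.test(values[group == pr[1L]], values[group == pr[2L]]))
    data.frame(group1 = pr[1L], group2 = pr[2L],
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
  pw$p.adj <- stats::p.adjust(pw$p, method = "BH")
  list(omnibus = omnibus, pairwise = pw, method = test)
}
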