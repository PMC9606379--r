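# Degree-of-Apicality statistics for smFISH m.f.i. measurements and the
# associated significance-test battery.

#' Degree of Apicality
#'
#' Background-subtracted ratio of apical over basal mean fluorescence
#' intensity: `(apical - background) / (basal - background)`. Values above 1
#' indicate an apical localization bias, 1 means symmetric signal.
#'
#' @param apical,basal,background m.f.i. values (vectorized); both signals
#'   must strictly exceed the background.
#' @return positive numeric DoA values.
#' @examples
#' degreeOfApicality(8, 4, 2)   # 3
#' degreeOfApicality(4, 8, 2)   # 1/3
#' @export
degreeOfApicality <- function(apical, basal, background = 0) {
  if (any(basal <= background))
    stop("invalid measurement: basal m.f.i. must exceed background")
  if (any(apical <= background))
    stop("invalid measurement: apical m.f.i. must exceed background")
  (apical - background) / (basal - background)
}

#' Compute DoA per measurement group, excluding invalid measurements
#'
#' Applies [degreeOfApicality()] row-wise to a measurement table.
#' Measurements whose apical or basal m.f.i. does not exceed the background
#' are excluded (not clamped); their count is messaged and attached as the
#' `"n_excluded"` attribute.
#'
#' @param measurements data.frame with columns `group_id`, `cell_type`,
#'   `apical_mfi`, `basal_mfi`, `bg_mfi` (plus optional `rna_id`,
#'   `condition`).
#' @return data.frame of valid rows with a `doa` column appended.
#' @export
doaTable <- function(measurements) {
  need <- c("group_id", "cell_type", "apical_mfi", "basal_mfi", "bg_mfi")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ok <- measurements$apical_mfi > measurements$bg_mfi &
    measurements$basal_mfi > measurements$bg_mfi
  if (any(!ok))
    message("excluding ", sum(!ok),
            " measurement(s) with signal not above background")
  out <- measurements[ok, , drop = FALSE]
  out$doa <- degreeOfApicality(out$apical_mfi, out$basal_mfi, out$bg_mfi)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Knockdown-over-wild-type DoA ratio
#'
#' The DoA measured in knockdown cells divided by the DoA of neighboring
#' wild-type cells of the same image stack; 1 means no localization change.
#'
#' @param doaKd,doaWt positive DoA values.
#' @return positive ratio (vectorized).
#' @examples
#' kdWtDoA(5, 2)  # 2.5
#' @export
kdWtDoA <- function(doaKd, doaWt) {
  if (any(doaKd <= 0) || any(doaWt <= 0))
    stop("DoA values must be > 0")
  doaKd / doaWt
}

#' Mutant DoA over the mean wild-type DoA
#'
#' For conditions without mosaic tissue (no within-stack wild-type
#' neighbors), a single mutant egg chamber's DoA is divided by the average
#' DoA of n wild-type egg chambers.
#'
#' @param doaMut positive mutant DoA.
#' @param wtDoas non-empty vector of positive wild-type DoAs.
#' @return positive ratio.
#' @examples
#' nullVsWtDoA(3, c(1, 2))  # 2
#' @export
nullVsWtDoA <- function(doaMut, wtDoas) {
  if (length(wtDoas) == 0L) stop("'wtDoas' must be non-empty")
  if (any(doaMut <= 0) || any(wtDoas <= 0))
    stop("DoA values must be > 0")
  doaMut / mean(wtDoas)
}

#' Pair knockdown and wild-type DoAs by image stack
#'
#' Joins the `wt` and `kd` rows of a DoA table on `group_id` (the image
#' stack) and computes the per-stack KD/wt DoA ratio. Stacks lacking either
#' cell type are dropped with a message.
#'
#' @param doaTbl output of [doaTable()].
#' @return data.frame with `group_id` and `kd_wt_doa`.
#' @export
pairedKdWtDoA <- function(doaTbl) {
  wt <- doaTbl[doaTbl$cell_type == "wt", c("group_id", "doa")]
  kd <- doaTbl[doaTbl$cell_type == "kd", c("group_id", "doa")]
  mg <- merge(kd, wt, by = "group_id", suffixes = c("_kd", "_wt"))
  nDrop <- length(unique(doaTbl$group_id)) - nrow(mg)
  if (nDrop > 0)
    message("dropping ", nDrop, " stack(s) without a wt/kd pair")
  data.frame(group_id = mg$group_id,
             kd_wt_doa = kdWtDoA(mg$doa_kd, mg$doa_wt),
             stringsAsFactors = FALSE)
}

#' One-sample t-test against a reference of 1
#'
#' Tests whether the mean of `values` (typically KD/wt DoA ratios or A/B
#' intensity ratios) differs from 1, the no-change reference. Zero-variance
#' samples do not error: p is 1 when the mean equals 1 and 0 otherwise
#' (with the matching one-sided convention), and the result carries a
#' `degenerate` flag.
#'
#' @param values numeric vector, n >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param mu reference value (1 unless stated otherwise).
#' @return a [TestResult-class].
#' @examples
#' oneSampleTVsOne(c(2.0, 2.2, 1.8))
#' @export
oneSampleTVsOne <- function(values,
                            alternative = c("two.sided", "less", "greater"),
                            mu = 1) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required")
  m <- mean(values)
  if (sd(values) == 0) {
    p <- switch(alternative,
                two.sided = as.numeric(m == mu),
                less = as.numeric(m >= mu),
                greater = as.numeric(m <= mu))
    return(TestResult("One-sample t-test vs mu (degenerate variance)",
                      statistic = if (m == mu) 0 else sign(m - mu) * Inf,
                      df = n - 1, p.value = p, alternative = alternative,
                      estimate = m, n = n, degenerate = TRUE))
  }
  tt <- t.test(values, mu = mu, alternative = alternative)
  TestResult("One-sample t-test vs mu", tt$statistic, tt$parameter,
             tt$p.value, alternative, m, n)
}

#' KD-over-wild-type total signal ratio
#'
#' Ratio of background-subtracted total (apical + basal) smFISH intensity
#' in knockdown versus wild-type cells; values below 1 indicate RNA
#' degradation in the knockdown. Typically tested against 1 with
#' `oneSampleTVsOne(alternative = "less")`.
#'
#' @param mKd,mWt single measurements (lists or one-row data.frames with
#'   `apical_mfi`, `basal_mfi`, `bg_mfi`).
#' @return positive ratio.
#' @export
totalSignalRatio <- function(mKd, mWt) {
  tot <- function(m)
    (m$apical_mfi - m$bg_mfi) + (m$basal_mfi - m$bg_mfi)
  den <- tot(mWt)
  if (any(den <= 0) || any(tot(mKd) <= 0))
    stop("background-corrected total signal must be positive")
  tot(mKd) / den
}

#' Two-sample t-test (Student or Welch)
#'
#' Two-sided comparison of two group means, either with the pooled-variance
#' Student statistic or the Welch-Satterthwaite unpooled variant.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param pooled `TRUE` for the pooled (Student) test, `FALSE` (default)
#'   for Welch.
#' @return a [TestResult-class] with `estimate` the difference of means.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6), pooled = TRUE)
#' @export
twoSampleT <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(TestResult(
      "Two-sample t-test (degenerate variance)",
      statistic = if (d == 0) 0 else sign(d) * Inf,
      df = length(a) + length(b) - 2L,
      p.value = as.numeric(d == 0), alternative = "two.sided",
      estimate = d, n = c(length(a), length(b)), degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = pooled)
  TestResult(if (pooled) "Two-sample Student t-test"
             else "Welch two-sample t-test",
             tt$statistic, tt$parameter, tt$p.value, "two.sided",
             mean(a) - mean(b), c(length(a), length(b)))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Compares k group means by one-way ANOVA, followed by all pairwise Tukey
#' honest-significant-difference tests on the studentized range
#' distribution (Tukey-Kramer correction for unequal group sizes). When all
#' groups are identical constants the decomposition is degenerate; F is
#' reported as 0 with p = 1 and all pairwise p-values 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `anova` (a [TestResult-class], `df = c(k - 1, N - k)`)
#'   and `tukey`, a data.frame of pairwise comparisons (`comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @examples
#' anovaTukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
#' @export
anovaTukey <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  k <- length(groups); N <- length(y)
  pairs <- combn(names(groups), 2L)
  pairNames <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  if (var(y) == 0) {
    tukey <- data.frame(comparison = pairNames, diff = 0, lwr = 0,
                        upr = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(anova = TestResult("One-way ANOVA (degenerate variance)",
                                   0, c(k - 1L, N - k), 1, "two.sided",
                                   mean(y), vapply(groups, length, 1L),
                                   degenerate = TRUE),
                tukey = tukey))
  }
  fit <- aov(y ~ g)
  tab <- anova(fit)
  th <- TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                      lwr = th[, "lwr"], upr = th[, "upr"],
                      p_adj = th[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  list(anova = TestResult("One-way ANOVA", tab$`F value`[1],
                          c(tab$Df[1], tab$Df[2]), tab$`Pr(>F)`[1],
                          "two.sided", mean(y),
                          vapply(groups, length, 1L)),
       tukey = tukey)
}

#' Paired A/B intensity ratio against an even-distribution null
#'
#' Computes the per-pair apical/basal ratio and tests its mean against 1
#' with the two-sided one-sample t-test, the procedure used for uniformly
#' distributed fluorescence signal (e.g. cytoplasmic GFP fusions).
#'
#' @param aValues,bValues paired numeric vectors of equal length >= 2;
#'   `bValues` must be strictly positive.
#' @return a [TestResult-class].
#' @export
abRatioVsOne <- function(aValues, bValues) {
  if (length(aValues) != length(bValues) || length(aValues) < 2L)
    stop("'aValues' and 'bValues' must be paired, length >= 2")
  if (any(bValues <= 0)) stop("'bValues' must be > 0")
  oneSampleTVsOne(aValues / bValues, alternative = "two.sided")
}

#' Significance stars for figure-style annotation
#'
#' @param p numeric p-values.
#' @return character vector: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#'   `ns` otherwise.
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Per-RNA KD/wt DoA summary
#'
#' Aggregates paired KD/wt DoA ratios per RNA and condition: mean, SD, n,
#' and the one-sample two-sided t-test against 1 with significance stars.
#'
#' @param doaTbl output of [doaTable()] including `rna_id` and `condition`.
#' @return data.frame with one row per RNA x condition.
#' @export
summarizeKdWtDoA <- function(doaTbl) {
  keys <- unique(doaTbl[, c("rna_id", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- doaTbl[doaTbl$rna_id == keys$rna_id[i] &
                    doaTbl$condition == keys$condition[i], , drop = FALSE]
    ratios <- pairedKdWtDoA(sub)$kd_wt_doa
    tt <- oneSampleTVsOne(ratios)
    data.frame(rna_id = keys$rna_id[i], condition = keys$condition[i],
               mean_kd_wt_doa = mean(ratios), sd = sd(ratios),
               n = length(ratios), t = tt@statistic, df = tt@df,
               p_value = tt@p.value,
               significance = significanceStars(tt@p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
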