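# Enrichment calling: median-of-ratios normalization, per-gene Welch test on
# log2 normalized counts, BH correction, and fold-change-based contaminant
# triage. This is a fully specified stand-in for a DESeq2 analysis: no
# dispersion or fold-change shrinkage, so results on raw counts are close to
# but not identical with an NB Wald test. Classification of an externally
# produced differential table (via readEnrichmentTable) is exact.

.sizeFactorsMatrix <- function(m) {
  if (nrow(m) == 0L) stop("count table has no genes")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("size factors are undefined: no gene has nonzero counts in ",
         "every sample")
  # median taken on the log-ratio scale: with an even number of reference
  # genes the two central ratios average geometrically, matching the
  # reference median-of-ratios implementation
  logGeo <- rowMeans(log(m[ref, , drop = FALSE]))
  apply(m[ref, , drop = FALSE], 2L,
        function(cnts) exp(median(log(cnts) - logGeo)))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors by the median-of-ratios rule: for each
#' sample, the median over reference genes of that gene's count divided by
#' its geometric mean across samples. Reference genes are those with a
#' nonzero count in every sample; if none exists the factors are undefined
#' and an error is raised. The median is taken on the log-ratio scale, so
#' an even number of reference genes averages the two central ratios
#' geometrically.
#'
#' @param object an [LCMCountSet-class] or a non-negative count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(A1 = c(10, 20), A2 = c(10, 20), B1 = c(20, 40), B2 = c(20, 40))
#' sizeFactorsMedianRatio(m)
#' @rdname sizeFactorsMedianRatio
#' @export
setMethod("sizeFactorsMedianRatio", "matrix",
          function(object) .sizeFactorsMatrix(object))

#' @rdname sizeFactorsMedianRatio
#' @export
setMethod("sizeFactorsMedianRatio", "LCMCountSet",
          function(object) .sizeFactorsMatrix(counts(object)))

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up false-discovery-rate adjustment: order the m p-values
#' increasingly, multiply the i-th by m/i, enforce monotonicity from the
#' largest down, clip at 1, and return in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1L)))
  adj[order(o)]
}

# Welch two-sided t on rows of a matrix split by a two-level factor;
# returns p = 1 for genes with zero variance in both groups.
.rowWelchP <- function(logm, isA) {
  a <- logm[, isA, drop = FALSE]
  b <- logm[, !isA, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- 1
  list(p = p, statistic = t, df = df, degenerate = degen)
}

#' Per-gene apical-versus-basal enrichment test
#'
#' Normalizes counts by the supplied (or freshly computed median-of-ratios)
#' size factors, then per gene computes the log2 fold change of mean apical
#' over mean basal normalized counts (with `pseudocount` added to each mean)
#' and a two-sided Welch t-test on `log2(normalized + pseudocount)` between
#' the domains. P-values are Benjamini-Hochberg adjusted. Genes with zero
#' counts in every sample are dropped before testing (their number is
#' messaged and recorded in `metadata()$dropped_all_zero`). Genes with zero
#' variance in both domains get p = 1 (no evidence) and are flagged in
#' `metadata()$degenerate_genes`.
#'
#' @param object an [LCMCountSet-class] with >= 2 replicates per domain.
#' @param sizeFactors optional named positive per-sample factors; computed
#'   by [sizeFactorsMedianRatio()] when `NULL`.
#' @param pseudocount positive value added after normalization, used in both
#'   the fold change and the test transform.
#' @return an [EnrichmentResults-class] with `loc_class` unset; see
#'   [classifyGenes()].
#' @examples
#' sim <- simulateLcmCounts(nGenes = 200, seed = 1)
#' res <- testEnrichment(sim$counts)
#' head(res)
#' @rdname testEnrichment
#' @export
setMethod("testEnrichment", "LCMCountSet",
          function(object, sizeFactors = NULL, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  m <- counts(object)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(object)
  if (length(sizeFactors) != ncol(m) || any(sizeFactors <= 0))
    stop("'sizeFactors' must be positive, one per sample")
  isA <- as.character(object$domain) == "apical"
  if (sum(isA) < 2L || sum(!isA) < 2L)
    stop("each domain needs at least 2 replicates")

  allZero <- rowSums(m) == 0
  if (any(allZero))
    message("dropping ", sum(allZero), " gene(s) with all-zero counts")
  m <- m[!allZero, , drop = FALSE]
  norm <- sweep(m, 2L, sizeFactors, `/`)
  log2fc <- log2((rowMeans(norm[, isA, drop = FALSE]) + pseudocount) /
                   (rowMeans(norm[, !isA, drop = FALSE]) + pseudocount))
  wt <- .rowWelchP(log2(norm + pseudocount), isA)
  EnrichmentResults(rownames(m), log2fc, wt$p, benjaminiHochberg(wt$p),
                    metadata = list(pseudocount = pseudocount,
                                    size_factors = sizeFactors,
                                    dropped_all_zero = sum(allZero),
                                    degenerate_genes =
                                      rownames(m)[wt$degenerate]))
})

#' Classify tested genes into localization classes
#'
#' Applies the significance gate and the absolute fold-change contaminant
#' triage. Genes with `fdr >= fdrThreshold` are `not_significant`.
#' Significant genes are split by `log2fc` at the contaminant boundary
#' `fcThreshold` (default 3): `log2fc > fcThreshold` is an
#' `oocyte_contaminant`, `0 < log2fc <= fcThreshold` a `bona_fide_apical`
#' transcript, `-fcThreshold <= log2fc < 0` a `bona_fide_basal` transcript,
#' and `log2fc < -fcThreshold` a `muscle_contaminant`. A significant gene
#' with `log2fc` exactly 0 has no direction and is classed
#' `not_significant`. The five classes partition the records.
#'
#' @param records an [EnrichmentResults-class] (or data.frame with `log2fc`
#'   and `fdr` columns).
#' @param fdrThreshold strict FDR gate (significant means `fdr < threshold`).
#' @param fcThreshold positive contaminant fold-change boundary.
#' @return the records with `loc_class` filled in; thresholds are stored in
#'   `metadata()` for `EnrichmentResults` input.
#' @examples
#' sim <- simulateLcmCounts(nGenes = 500, seed = 1)
#' res <- classifyGenes(testEnrichment(sim$counts))
#' table(res$loc_class)
#' @export
classifyGenes <- function(records, fdrThreshold = 0.1, fcThreshold = 3) {
  if (fdrThreshold <= 0 || fcThreshold <= 0)
    stop("thresholds must be positive")
  lfc <- records$log2fc
  fdr <- records$fdr
  if (is.null(lfc) || is.null(fdr))
    stop("'records' must carry 'log2fc' and 'fdr'")
  cls <- rep("not_significant", length(lfc))
  sig <- fdr < fdrThreshold
  cls[sig & lfc > fcThreshold] <- "oocyte_contaminant"
  cls[sig & lfc > 0 & lfc <= fcThreshold] <- "bona_fide_apical"
  cls[sig & lfc < 0 & lfc >= -fcThreshold] <- "bona_fide_basal"
  cls[sig & lfc < -fcThreshold] <- "muscle_contaminant"
  records$loc_class <- cls
  if (is(records, "EnrichmentResults"))
    metadata(records)[c("fdr_threshold", "fc_threshold")] <-
      list(fdrThreshold, fcThreshold)
  records
}

#' Count genes per localization class
#'
#' @param records classified records (see [classifyGenes()]).
#' @return named integer vector over the five classes, plus `apical_total`
#'   and `basal_total` (significant genes with positive / negative fold
#'   change, i.e. bona fide plus the same-side contaminants).
#' @export
classCounts <- function(records) {
  cls <- factor(records$loc_class, levels = .locClasses)
  out <- table(cls)
  n <- setNames(as.integer(out), names(out))
  c(n,
    apical_total = n[["bona_fide_apical"]] + n[["oocyte_contaminant"]],
    basal_total = n[["bona_fide_basal"]] + n[["muscle_contaminant"]])
}

#' Through-origin validation regression
#'
#' Fits `y = coefficient * x` without an intercept, the model used to
#' validate RNA-seq fold changes against independent smFISH fold changes
#' (n points give n - 1 degrees of freedom).
#'
#' @param x,y equal-length numeric vectors (n >= 2); `x` must not be all
#'   zero.
#' @return list with `coefficient`, `coefficient_se`, `degrees_of_freedom`,
#'   `adj_r_squared` and `f_pvalue`.
#' @examples
#' fitValidationRegression(c(1, 2, 3), c(2.1, 3.9, 6.2))
#' @export
fitValidationRegression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must have equal length >= 2")
  if (all(x == 0)) stop("'x' must not be all zero")
  fit <- lm(y ~ x - 1)
  s <- summary(fit)
  list(coefficient = unname(coef(fit)[1]),
       coefficient_se = unname(s$coefficients[1, 2]),
       degrees_of_freedom = fit$df.residual,
       adj_r_squared = s$adj.r.squared,
       f_pvalue = unname(pf(s$fstatistic[1], s$fstatistic[2],
                            s$fstatistic[3], lower.tail = FALSE)))
}
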