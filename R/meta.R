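# Group-wise meta-analyses: EJC enrichment and translation efficiency of
# apical versus basal transcript sets.

#' Translation efficiency
#'
#' Ribosome-footprint TPM divided by RNA-seq TPM. Genes with non-positive
#' RNA TPM have no defined efficiency and return `NA` (their count is
#' messaged); they are excluded from group comparisons rather than raising
#' an error over a whole table.
#'
#' @param rfpTpm ribosome-footprint TPM (>= 0, vectorized).
#' @param rnaTpm RNA-seq TPM.
#' @return numeric efficiencies, `NA` where `rnaTpm <= 0`.
#' @examples
#' translationEfficiency(c(10, 5), c(10, 10))  # 1, 0.5
#' @export
translationEfficiency <- function(rfpTpm, rnaTpm) {
  if (length(rfpTpm) != length(rnaTpm))
    stop("'rfpTpm' and 'rnaTpm' must have equal length")
  if (any(rfpTpm < 0, na.rm = TRUE)) stop("'rfpTpm' must be >= 0")
  bad <- !(rnaTpm > 0)
  if (any(bad))
    message("excluding ", sum(bad), " gene(s) with non-positive RNA TPM")
  out <- rfpTpm / rnaTpm
  out[bad] <- NA_real_
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two groups with midranks for ties. The p-value is
#' exact (by enumeration of rank assignments) when the combined sample size
#' is at most 12 and the data are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact override the branch rule (`NULL` = rule above); mainly for
#'   comparing the two branches.
#' @return a [TestResult-class] (statistic is the Mann-Whitney W of group
#'   `a`; `estimate` is the difference of group medians).
#' @examples
#' pValue(wilcoxonRankSum(c(1, 2), c(3, 4)))  # 1/3
#' @export
wilcoxonRankSum <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  hasTies <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact))
    exact <- (length(a) + length(b) <= 12L) && !hasTies
  if (exact && hasTies)
    stop("exact enumeration requires tie-free data")
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- wt$p.value
  degenerate <- is.nan(p)  # complete ties: zero rank variance, no evidence
  if (degenerate) p <- 1
  TestResult(if (exact) "Wilcoxon rank-sum test (exact)"
             else "Wilcoxon rank-sum test (normal approximation)",
             wt$statistic, NA_real_, p, "two.sided",
             median(a) - median(b), c(length(a), length(b)),
             degenerate = degenerate)
}

#' Compare apical and basal gene sets on a per-gene metric
#'
#' Restricts an annotation table to bona fide apical and basal genes
#' (contaminant classes and unclassified rows are excluded by
#' construction), computes the requested per-gene metric, and compares the
#' two sets with the two-sided Wilcoxon rank-sum test.
#'
#' @param table data.frame with columns `gene_id`, `loc_class` and, as the
#'   metric requires, `ejc_lfc` or `rfp_tpm` + `rna_tpm`.
#' @param metric `"ejc_lfc"` (external EJC-IP log2 fold change) or
#'   `"translation_efficiency"` (RFP TPM / RNA TPM, computed here; genes
#'   with non-positive RNA TPM are dropped and counted).
#' @return list with `medians` (named: apical, basal), `n` (usable genes
#'   per class), `n_dropped` and `test` (a [TestResult-class]).
#' @examples
#' tab <- simulateTpmTables(nGenesPerGroup = 30, shift = 2, seed = 1)
#' compareGroups(tab, metric = "translation_efficiency")$medians
#' @export
compareGroups <- function(table,
                          metric = c("ejc_lfc", "translation_efficiency")) {
  metric <- match.arg(metric)
  keep <- table$loc_class %in% c("bona_fide_apical", "bona_fide_basal")
  tab <- table[keep, , drop = FALSE]
  vals <- if (metric == "ejc_lfc") {
    if (is.null(tab$ejc_lfc)) stop("column 'ejc_lfc' is required")
    tab$ejc_lfc
  } else {
    if (is.null(tab$rfp_tpm) || is.null(tab$rna_tpm))
      stop("columns 'rfp_tpm' and 'rna_tpm' are required")
    translationEfficiency(tab$rfp_tpm, tab$rna_tpm)
  }
  usable <- !is.na(vals)
  apical <- vals[usable & tab$loc_class == "bona_fide_apical"]
  basal <- vals[usable & tab$loc_class == "bona_fide_basal"]
  if (!length(apical))
    stop("no usable bona_fide_apical genes for metric ", sQuote(metric))
  if (!length(basal))
    stop("no usable bona_fide_basal genes for metric ", sQuote(metric))
  list(medians = c(apical = median(apical), basal = median(basal)),
       n = c(apical = length(apical), basal = length(basal)),
       n_dropped = sum(!usable),
       test = wilcoxonRankSum(apical, basal))
}
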