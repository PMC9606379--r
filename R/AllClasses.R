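#' Two-domain LCM count set
#'
#' An `LCMCountSet` holds a gene-by-sample matrix of non-negative integer
#' read counts from laser-capture microdissected apical and basal tissue
#' fragments, as a thin extension of
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' The `domain` column of `colData` labels every sample as `"apical"` or
#' `"basal"`; at least two replicates per domain are required.
#'
#' @slot .Data inherited `SummarizedExperiment` representation with a single
#'   `"counts"` assay.
#'
#' @seealso [LCMCountSet()] for construction, [sizeFactorsMedianRatio()],
#'   [testEnrichment()].
#' @aliases LCMCountSet-class
#' @exportClass LCMCountSet
setClass("LCMCountSet", contains = "SummarizedExperiment")

.validLCMCountSet <- function(object) {
  msg <- NULL
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m))
      msg <- c(msg, "counts must be numeric")
    else if (length(m) && (any(!is.finite(m)) || any(m < 0) ||
                           any(abs(m - round(m)) > 1e-8)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  if (!("domain" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain a 'domain' column")
  else {
    dom <- as.character(object$domain)
    if (!all(dom %in% c("apical", "basal")))
      msg <- c(msg, "domain labels must be 'apical' or 'basal'")
    else if (ncol(object) && (sum(dom == "apical") < 2L ||
                              sum(dom == "basal") < 2L))
      msg <- c(msg, "at least 2 samples per domain are required")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("LCMCountSet", .validLCMCountSet)

#' Construct an LCMCountSet
#'
#' @param counts integer-valued matrix of non-negative read counts, genes in
#'   rows (unique rownames), samples in columns.
#' @param domain character or factor of `"apical"`/`"basal"` labels, one per
#'   column of `counts`; at least 2 replicates per domain.
#' @param replicateIds sample identifiers; defaults to `colnames(counts)`.
#'
#' @return an [LCMCountSet-class] object.
#' @examples
#' m <- matrix(rpois(40, 50), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), c(paste0("A", 1:2), paste0("B", 1:2))))
#' cset <- LCMCountSet(m, domain = c("apical", "apical", "basal", "basal"))
#' domains(cset)
#' @export
LCMCountSet <- function(counts, domain,
                        replicateIds = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.numeric(counts) && length(counts) &&
      all(is.finite(counts)) && all(abs(counts - round(counts)) < 1e-8) &&
      max(counts) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  if (is.null(replicateIds))
    replicateIds <- paste0("S", seq_len(ncol(counts)))
  colnames(counts) <- replicateIds
  if (length(domain) != ncol(counts))
    stop("'domain' must have one label per sample")
  cd <- DataFrame(domain = factor(as.character(domain),
                                  levels = c("apical", "basal")),
                  replicate_id = replicateIds,
                  row.names = replicateIds)
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd)
  new("LCMCountSet", se)
}

#' Per-gene enrichment results
#'
#' Extends [DataFrame][S4Vectors::DataFrame-class] with one row per tested
#' gene and columns `log2fc` (apical over basal), `p_value`, `fdr`
#' (Benjamini-Hochberg adjusted) and `loc_class`. `loc_class` is `NA` until
#' [classifyGenes()] assigns one of `oocyte_contaminant`, `bona_fide_apical`,
#' `bona_fide_basal`, `muscle_contaminant`, `not_significant`. Analysis
#' parameters (pseudocount, thresholds, dropped genes) live in `metadata()`.
#'
#' @aliases EnrichmentResults-class
#' @exportClass EnrichmentResults
setClass("EnrichmentResults", contains = "DFrame")

# range checks only on the columns present: column-wise replacement in
# S4Vectors temporarily builds single-column objects of this class, so
# presence of all four columns is enforced by the constructor instead.
.validEnrichmentResults <- function(object) {
  msg <- NULL
  ok01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if ("p_value" %in% colnames(object) && !ok01(object$p_value))
    msg <- c(msg, "p_value must lie in [0, 1]")
  if ("fdr" %in% colnames(object) && !ok01(object$fdr))
    msg <- c(msg, "fdr must lie in [0, 1]")
  if ("loc_class" %in% colnames(object)) {
    cls <- object$loc_class
    known <- c("oocyte_contaminant", "bona_fide_apical", "bona_fide_basal",
               "muscle_contaminant", "not_significant")
    if (!all(is.na(cls) | cls %in% known))
      msg <- c(msg, "unknown loc_class label")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("EnrichmentResults", .validEnrichmentResults)

EnrichmentResults <- function(geneIds, log2fc, pValue, fdr,
                              locClass = rep(NA_character_, length(geneIds)),
                              metadata = list()) {
  stopifnot(length(log2fc) == length(geneIds),
            length(pValue) == length(geneIds),
            length(fdr) == length(geneIds))
  df <- DataFrame(log2fc = as.numeric(log2fc),
                  p_value = as.numeric(pValue),
                  fdr = as.numeric(fdr),
                  loc_class = as.character(locClass),
                  row.names = geneIds)
  out <- new("EnrichmentResults", df)
  metadata(out) <- metadata
  out
}

#' Apical-basal axis intensity profile
#'
#' One channel's fluorescence intensity sampled along a line ROI spanning the
#' apical-basal axis of a group of follicle cells. Position 0 is the apical
#' end. Profiles are constructed raw and carry a `normalized` flag once
#' [normalizeProfile()] has mapped positions to `[0, 1]` and values to the
#' 0-1 range; `constant` marks degenerate flat profiles whose values were
#' mapped to all zeros.
#'
#' @slot profileId character scalar identifier.
#' @slot channel character scalar channel label.
#' @slot positions strictly increasing numeric positions, apical end first.
#' @slot values non-negative intensities, same length as `positions`.
#' @slot normalized logical flag set by [normalizeProfile()].
#' @slot constant logical flag for degenerate constant profiles.
#'
#' @aliases AxisProfile-class
#' @exportClass AxisProfile
setClass("AxisProfile",
         representation(profileId = "character", channel = "character",
                        positions = "numeric", values = "numeric",
                        normalized = "logical", constant = "logical"),
         prototype(profileId = "profile", channel = "ch1",
                   normalized = FALSE, constant = FALSE))

.validAxisProfile <- function(object) {
  msg <- NULL
  if (length(object@positions) < 3L)
    msg <- c(msg, "a profile needs at least 3 positions")
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("AxisProfile", .validAxisProfile)

#' Construct an AxisProfile
#'
#' @param positions strictly increasing numeric vector (0 = apical end),
#'   length >= 3.
#' @param values non-negative intensities, same length.
#' @param profileId,channel identifiers.
#' @param normalized,constant state flags; normally left at their defaults
#'   and set by [normalizeProfile()].
#' @return an [AxisProfile-class] object.
#' @examples
#' p <- AxisProfile(seq(0, 1, length.out = 11), rep(1, 11))
#' auc50Position(p)
#' @export
AxisProfile <- function(positions, values, profileId = "profile",
                        channel = "ch1", normalized = FALSE,
                        constant = FALSE) {
  new("AxisProfile", profileId = as.character(profileId),
      channel = as.character(channel), positions = as.numeric(positions),
      values = as.numeric(values), normalized = normalized,
      constant = constant)
}

#' Hypothesis-test result
#'
#' Uniform container for the package's test battery (one-sample t against 1,
#' Student/Welch two-sample t, one-way ANOVA, Wilcoxon rank sum). The
#' `degenerate` flag marks zero-variance inputs whose p-value was set by
#' convention (1 when the estimate sits on the null, 0 otherwise) instead of
#' raising an error.
#'
#' @slot method descriptive test name.
#' @slot statistic test statistic (t, F or W).
#' @slot df degrees of freedom; length 2 for ANOVA, `NA` for rank tests.
#' @slot p.value p-value in \[0, 1\].
#' @slot alternative `"two.sided"`, `"less"` or `"greater"`.
#' @slot estimate sample estimate (mean, difference of means, ...).
#' @slot n per-group sample sizes.
#' @slot degenerate logical zero-variance flag.
#'
#' @aliases TestResult-class
#' @exportClass TestResult
setClass("TestResult",
         representation(method = "character", statistic = "numeric",
                        df = "numeric", p.value = "numeric",
                        alternative = "character", estimate = "numeric",
                        n = "integer", degenerate = "logical"))

.validTestResult <- function(object) {
  if (!is.na(object@p.value) &&
      (object@p.value < 0 || object@p.value > 1))
    return("p.value must lie in [0, 1]")
  TRUE
}
setValidity("TestResult", .validTestResult)

TestResult <- function(method, statistic, df, p.value, alternative,
                       estimate, n, degenerate = FALSE) {
  new("TestResult", method = method, statistic = as.numeric(statistic),
      df = as.numeric(df), p.value = as.numeric(p.value),
      alternative = alternative, estimate = as.numeric(estimate),
      n = as.integer(n), degenerate = degenerate)
}
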