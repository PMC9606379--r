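#' @rdname LCMCountSet
#' @param x an object with domain labels.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname sizeFactorsMedianRatio
#' @export
setGeneric("sizeFactorsMedianRatio",
           function(object) standardGeneric("sizeFactorsMedianRatio"))

#' @rdname testEnrichment
#' @export
setGeneric("testEnrichment",
           function(object, sizeFactors = NULL, pseudocount = 0.5)
             standardGeneric("testEnrichment"))

#' @rdname normalizeProfile
#' @export
setGeneric("normalizeProfile", function(p) standardGeneric("normalizeProfile"))

#' @rdname auc50Position
#' @export
setGeneric("auc50Position", function(p) standardGeneric("auc50Position"))

#' @rdname TestResult-class
#' @param x a [TestResult-class].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TestResult-class
#' @export
setMethod("pValue", "TestResult", function(x) x@p.value)

#' @rdname LCMCountSet
#' @export
setMethod("domains", "LCMCountSet",
          function(x) setNames(as.character(x$domain), colnames(x)))

#' @importFrom BiocGenerics counts
#' @rdname LCMCountSet
#' @param object an `LCMCountSet`.
#' @export
setMethod("counts", "LCMCountSet",
          function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "LCMCountSet", function(object) {
  dom <- table(as.character(object$domain))
  cat("LCMCountSet with", nrow(object), "genes and", ncol(object),
      "samples\n")
  cat("  apical replicates:", dom[["apical"]],
      " basal replicates:", dom[["basal"]], "\n")
  callNextMethod()
})

setMethod("show", "TestResult", function(object) {
  cat(object@method, "\n")
  cat("  statistic =", format(object@statistic, digits = 5),
      " df =", paste(format(object@df, digits = 4), collapse = ", "),
      " p =", format(object@p.value, digits = 4), "\n")
  cat("  alternative:", object@alternative,
      " estimate =", format(object@estimate, digits = 5),
      " n =", paste(object@n, collapse = ", "), "\n")
  if (object@degenerate)
    cat("  note: zero-variance sample; p set by convention\n")
})

setMethod("show", "AxisProfile", function(object) {
  cat("AxisProfile", sQuote(object@profileId),
      "channel", sQuote(object@channel), "with",
      length(object@positions), "positions\n")
  cat("  span [", min(object@positions), ",", max(object@positions), "]",
      if (object@normalized) " (normalized)" else "",
      if (object@constant) " (constant)" else "", "\n", sep = "")
})

#' @rdname AxisProfile
#' @param p an `AxisProfile`.
#' @export
profilePositions <- function(p) p@positions

#' @rdname AxisProfile
#' @export
profileValues <- function(p) p@values

#' @rdname AxisProfile
#' @export
profileChannel <- function(p) p@channel

#' @rdname AxisProfile
#' @export
profileId <- function(p) p@profileId

#' @rdname AxisProfile
#' @export
isNormalized <- function(p) p@normalized
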