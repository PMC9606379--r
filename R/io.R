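# Plain-text readers and writers. TSV/CSV with '.' decimal separator, UTF-8,
# Unix newlines throughout (Fiji exports from European locales must be
# converted before ingestion).

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write / read a two-domain count table as TSV
#'
#' The dialect is `gene<TAB>A1..An<TAB>B1..Bn`: first column `gene`, then
#' one column per sample. Domains are taken from a two-column sample sheet
#' (`sample_id, domain`) when given, otherwise inferred from the leading
#' `A`/`B` of the sample names.
#'
#' @param x an [LCMCountSet-class].
#' @param path file path.
#' @return `readCountTable` returns an [LCMCountSet-class];
#'   `writeCountTable` the path, invisibly.
#' @export
writeCountTable <- function(x, path) {
  m <- counts(x)
  .writeTsv(data.frame(gene = rownames(m), m, check.names = FALSE), path)
}

#' @rdname writeCountTable
#' @param sampleSheet optional data.frame with `sample_id` and `domain`
#'   columns (see [readSampleSheet()]).
#' @export
readCountTable <- function(path, sampleSheet = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("expected first column 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  domain <- if (!is.null(sampleSheet)) {
    i <- match(colnames(m), sampleSheet$sample_id)
    if (anyNA(i)) stop("sample sheet is missing sample(s): ",
                       paste(colnames(m)[is.na(i)], collapse = ", "))
    sampleSheet$domain[i]
  } else {
    lead <- substr(colnames(m), 1L, 1L)
    if (!all(lead %in% c("A", "B")))
      stop("cannot infer domains from sample names; provide a sample sheet")
    ifelse(lead == "A", "apical", "basal")
  }
  LCMCountSet(m, domain = domain)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id` and `domain`
#'   (apical/basal).
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "domain") %in% names(df)))
    stop("sample sheet needs columns 'sample_id' and 'domain'")
  df
}

#' Write / read a ground-truth table as TSV
#'
#' @param truth data.frame from a generator (`id`, `true_class`,
#'   `true_lfc` or `true_auc50`).
#' @param path file path.
#' @export
writeTruthTable <- function(truth, path) .writeTsv(truth, path)

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path)
  read.delim(path, stringsAsFactors = FALSE)

#' Write / read axis profiles as long-format CSV
#'
#' Columns `profile_id, channel, position, value`; one row per sampled
#' position.
#'
#' @param profiles list of [AxisProfile-class] objects.
#' @param path file path.
#' @export
writeProfiles <- function(profiles, path) {
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(profile_id = p@profileId, channel = p@channel,
               position = p@positions, value = p@values,
               stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("profile_id", "channel", "position", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  keys <- unique(df[, c("profile_id", "channel")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$profile_id == keys$profile_id[i] &
                df$channel == keys$channel[i], , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    AxisProfile(sub$position, sub$value, profileId = keys$profile_id[i],
                channel = keys$channel[i])
  })
}

#' Write / read polarity measurement tables as CSV
#'
#' Columns `group_id, rna_id, condition, cell_type, apical_mfi, basal_mfi,
#' bg_mfi`.
#'
#' @param measurements data.frame of measurements.
#' @param path file path.
#' @export
writePolarityMeasurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writePolarityMeasurements
#' @export
readPolarityMeasurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "cell_type", "apical_mfi", "basal_mfi", "bg_mfi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write an enrichment-results table as TSV
#'
#' Columns `gene_id, log2fc, p_value, fdr, loc_class`.
#'
#' @param records an [EnrichmentResults-class].
#' @param path file path.
#' @export
writeEnrichmentTable <- function(records, path) {
  .writeTsv(data.frame(gene_id = rownames(records),
                       log2fc = records$log2fc,
                       p_value = records$p_value, fdr = records$fdr,
                       loc_class = records$loc_class,
                       stringsAsFactors = FALSE), path)
}

#' Read an enrichment (differential-expression) table with a column map
#'
#' Ingests either this package's own output or an externally produced
#' differential-enrichment table (e.g. a published processed supplementary
#' table) through a column map naming which input columns hold the gene
#' identifier, the log2 fold change that should feed [classifyGenes()],
#' and the FDR. `p_value` and `loc_class` entries are optional. Rows with
#' unparseable or out-of-range numeric values are rejected with their line
#' numbers messaged.
#'
#' @param path TSV/CSV path (separator sniffed from the header line).
#' @param columnMap named character vector mapping record fields
#'   (`gene_id`, `log2fc`, `fdr`, optionally `p_value`, `loc_class`) to
#'   input column names.
#' @return an [EnrichmentResults-class].
#' @export
readEnrichmentTable <- function(path,
                                columnMap = c(gene_id = "gene_id",
                                              log2fc = "log2fc",
                                              p_value = "p_value",
                                              fdr = "fdr",
                                              loc_class = "loc_class")) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) {
    warning("empty enrichment table: ", path)
    return(EnrichmentResults(character(0), numeric(0), numeric(0),
                             numeric(0)))
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  mapped <- function(field)
    if (field %in% names(columnMap)) columnMap[[field]] else NULL
  for (field in c("gene_id", "log2fc", "fdr")) {
    col <- mapped(field)
    if (is.null(col) || !(col %in% names(df)))
      stop("mapped column for ", sQuote(field), " (",
           if (is.null(col)) "unmapped" else sQuote(col),
           ") not found in ", path)
  }
  getNum <- function(field) {
    col <- mapped(field)
    if (is.null(col) || !(col %in% names(df)))
      return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  lfc <- getNum("log2fc"); fdr <- getNum("fdr"); p <- getNum("p_value")
  cls <- if (!is.null(mapped("loc_class")) &&
             mapped("loc_class") %in% names(df))
    as.character(df[[mapped("loc_class")]])
  else rep(NA_character_, nrow(df))
  bad01 <- function(x) !is.na(x) & (x < 0 | x > 1)
  bad <- is.na(lfc) | is.na(fdr) | bad01(fdr) | bad01(p)
  if (any(bad))
    message("rejecting ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  keep <- !bad
  EnrichmentResults(as.character(df[[columnMap[["gene_id"]]]])[keep],
                    lfc[keep], p[keep], fdr[keep], cls[keep],
                    metadata = list(source = path,
                                    n_rejected = sum(bad)))
}

#' Write the per-RNA KD/wt DoA summary as TSV
#'
#' @param summary data.frame from [summarizeKdWtDoA()].
#' @param path file path.
#' @export
writeKdWtSummary <- function(summary, path) .writeTsv(summary, path)
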