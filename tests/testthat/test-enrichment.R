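makeCountSet <- function(m, nA = NULL) {
  if (is.null(nA)) nA <- ncol(m) / 2
  LCMCountSet(m, domain = rep(c("apical", "basal"),
                              c(nA, ncol(m) - nA)))
}

test_that("median-of-ratios size factors follow their definition", {
  # identical columns: every ratio is 1
  m <- matrix(c(10, 20, 30), nrow = 3, ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(sizeFactorsMedianRatio(m)), rep(1, 4))

  # second sample exactly double: factors 1/sqrt(2), sqrt(2)
  m2 <- cbind(s1 = c(4, 10, 30), s2 = c(8, 20, 60))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(sizeFactorsMedianRatio(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # a gene with a zero anywhere is excluded from the reference set:
  # the outlier row cannot shift the medians
  m3 <- rbind(m2, gz = c(0, 1e6))
  expect_equal(sizeFactorsMedianRatio(m3), sizeFactorsMedianRatio(m2))

  # no reference gene at all
  m4 <- cbind(s1 = c(0, 5), s2 = c(5, 0))
  rownames(m4) <- c("g1", "g2")
  expect_error(sizeFactorsMedianRatio(m4), "nonzero counts in")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  m <- matrix(rnbinom(400, mu = 100, size = 10), nrow = 50)
  dimnames(m) <- list(paste0("g", 1:50), paste0("s", 1:8))
  expect_equal(unname(sizeFactorsMedianRatio(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("enrichment test computes the documented fold change and p-values", {
  # 1-gene hand oracle: normalized A = {8,8}, B = {2,2}, pc = 0.5
  m <- rbind(g1 = c(8, 8, 2, 2), g2 = c(10, 10, 10, 10))
  colnames(m) <- c("A1", "A2", "B1", "B2")
  res <- testEnrichment(makeCountSet(m), sizeFactors = rep(1, 4))
  expect_equal(res["g1", "log2fc"], log2(8.5 / 2.5), tolerance = 1e-12)
  # symmetric gene: log2fc exactly 0, degenerate p = 1
  expect_equal(res["g2", "log2fc"], 0)
  expect_equal(res["g2", "p_value"], 1)
  expect_true("g2" %in% S4Vectors::metadata(res)$degenerate_genes)
})

test_that("per-gene Welch p-values match the closed-form oracle", {
  set.seed(31)
  m <- matrix(rnbinom(80, mu = 200, size = 20), nrow = 10)
  dimnames(m) <- list(paste0("g", 1:10), c(paste0("A", 1:4), paste0("B", 1:4)))
  sf <- rep(1, 8)
  res <- testEnrichment(makeCountSet(m), sizeFactors = sf)
  lg <- log2(m + 0.5)
  for (g in 1:10) {
    o <- oracleWelchT(lg[g, 1:4], lg[g, 5:8])
    expect_equal(res$p_value[g], o$p, tolerance = 1e-10)
  }
})

test_that("relabeling apical and basal negates fold changes, p unchanged", {
  sim <- simulateLcmCounts(nGenes = 150, seed = 8)
  m <- counts(sim$counts)
  res <- testEnrichment(makeCountSet(m, 4))
  swapped <- testEnrichment(
    LCMCountSet(m, domain = rep(c("basal", "apical"), each = 4)))
  expect_equal(swapped$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  # class counts map oocyte<->muscle and apical<->basal
  ca <- classCounts(classifyGenes(res))
  cb <- classCounts(classifyGenes(swapped))
  expect_equal(ca[["bona_fide_apical"]], cb[["bona_fide_basal"]])
  expect_equal(ca[["oocyte_contaminant"]], cb[["muscle_contaminant"]])
  expect_equal(ca[["muscle_contaminant"]], cb[["oocyte_contaminant"]])
})

test_that("all-zero genes are dropped and reported", {
  m <- rbind(g1 = c(5, 6, 7, 8), gz = c(0, 0, 0, 0), g3 = c(9, 8, 7, 6))
  colnames(m) <- c("A1", "A2", "B1", "B2")
  expect_message(res <- testEnrichment(makeCountSet(m)), "1 gene")
  expect_equal(rownames(res), c("g1", "g3"))
  expect_equal(S4Vectors::metadata(res)$dropped_all_zero, 1L)
})

test_that("Benjamini-Hochberg step-up matches hand cases and p.adjust", {
  expect_equal(benjaminiHochberg(0.04), 0.04)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(benjaminiHochberg(numeric(0)), numeric(0))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(37)
    expect_equal(benjaminiHochberg(p), p.adjust(p, "BH"),
                 tolerance = 1e-14)
  }
})

test_that("classification applies the FDR gate and fold-change boundaries", {
  mk <- function(lfc, fdr)
    EnrichmentResults(paste0("g", seq_along(lfc)), lfc,
                      rep(NA_real_, length(lfc)), fdr)
  res <- classifyGenes(mk(
    lfc = c(4.0, 3.0, -5.0, -3.0, -3.5, 0, 0.001, -0.001, 1),
    fdr = c(0.01, 0.01, 0.5, 0.01, 0.01, 0.01, 0.05, 0.05, 0.1)))
  expect_equal(res$loc_class,
               c("oocyte_contaminant",   # log2fc > 3
                 "bona_fide_apical",     # boundary: 0 < lfc <= 3
                 "not_significant",      # fails the FDR gate
                 "bona_fide_basal",      # boundary: -3 <= lfc < 0
                 "muscle_contaminant",   # log2fc < -3
                 "not_significant",      # lfc exactly 0
                 "bona_fide_apical",
                 "bona_fide_basal",
                 "not_significant"))     # fdr == threshold: strict gate
  cc <- classCounts(res)
  expect_equal(sum(cc[1:5]), nrow(res))
  expect_equal(cc[["apical_total"]],
               cc[["bona_fide_apical"]] + cc[["oocyte_contaminant"]])
})

test_that("through-origin regression matches the normal-equations oracle", {
  # perfect fits make lm's summary warn about unreliable R^2; the
  # coefficient itself is exact
  expect_equal(suppressWarnings(
    fitValidationRegression(c(1, 2), c(2, 4)))$coefficient, 2)
  perfect <- suppressWarnings(fitValidationRegression(1:5, 1:5))
  expect_equal(perfect$coefficient, 1)
  expect_equal(perfect$adj_r_squared, 1)
  expect_equal(perfect$degrees_of_freedom, 4L)

  set.seed(13)
  x <- rnorm(16); y <- 0.95 * x + rnorm(16, sd = 0.3)
  fit <- fitValidationRegression(x, y)
  o <- oracleOriginFit(x, y)
  expect_equal(fit$coefficient, o$slope, tolerance = 1e-10)
  expect_equal(fit$coefficient_se, o$se, tolerance = 1e-10)
  expect_equal(fit$degrees_of_freedom, o$df)
  expect_equal(fit$adj_r_squared, o$adj_r2, tolerance = 1e-10)
  expect_error(fitValidationRegression(c(0, 0), c(1, 2)), "all zero")
})
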