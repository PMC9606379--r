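test_that("degree of apicality follows the background-subtracted ratio", {
  expect_equal(degreeOfApicality(10, 10, 2), 1)
  expect_equal(degreeOfApicality(8, 4, 2), 3)
  expect_equal(degreeOfApicality(4, 8, 2), 1 / 3)
  expect_error(degreeOfApicality(8, 2, 2), "basal")
  expect_error(degreeOfApicality(2, 8, 2), "apical")
  # scale invariance of the background-corrected signals
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 3, 10); b <- runif(1, 3, 10); bg <- runif(1, 0, 2)
    k <- runif(1, 0.1, 5)
    expect_equal(degreeOfApicality(bg + k * (a - bg), bg + k * (b - bg), bg),
                 degreeOfApicality(a, b, bg), tolerance = 1e-12)
  }
})

test_that("KD/wt and mutant/mean-wt DoA ratios behave as ratios", {
  expect_equal(kdWtDoA(2, 2), 1)
  expect_equal(kdWtDoA(5, 2), 2.5)
  expect_error(kdWtDoA(-1, 2), "> 0")
  set.seed(2)
  a <- runif(20, 0.1, 5); b <- runif(20, 0.1, 5)
  expect_equal(kdWtDoA(a, b) * kdWtDoA(b, a), rep(1, 20),
               tolerance = 1e-12)

  expect_equal(nullVsWtDoA(2, c(2, 2)), 1)
  expect_equal(nullVsWtDoA(3, c(1, 2)), 2)
  expect_equal(nullVsWtDoA(3, 1.5), kdWtDoA(3, 1.5))
  expect_error(nullVsWtDoA(2, numeric(0)), "non-empty")
})

test_that("invalid measurements are excluded from DoA tables, not clamped", {
  meas <- data.frame(group_id = c("s1", "s1", "s2", "s2"),
                     cell_type = c("wt", "kd", "wt", "kd"),
                     apical_mfi = c(8, 6, 4, 4), basal_mfi = c(4, 3, 3, 1),
                     bg_mfi = c(2, 2, 2, 2))
  expect_message(tbl <- doaTable(meas), "1 measurement")
  expect_equal(nrow(tbl), 3L)
  expect_equal(attr(tbl, "n_excluded"), 1L)
  # stack s2 lost its kd measurement, so it cannot be paired
  expect_message(paired <- pairedKdWtDoA(tbl), "without a wt/kd pair")
  expect_equal(paired$kd_wt_doa, (4 / 1) / (6 / 2))
})

test_that("one-sample t against 1 matches closed forms and the CDF oracle", {
  # exact null with zero variance: no evidence, flagged
  degen <- oneSampleTVsOne(c(1, 1, 1))
  expect_true(degen@degenerate)
  expect_equal(pValue(degen), 1)
  degen2 <- oneSampleTVsOne(c(2, 2, 2))
  expect_true(degen2@degenerate)
  expect_equal(pValue(degen2), 0)

  # df = 2 closed form: p = 1 - t/sqrt(t^2 + 2)
  tt <- oneSampleTVsOne(c(2.0, 2.2, 1.8))
  expect_equal(tt@statistic, 8.660254, tolerance = 1e-6)
  expect_equal(tt@df, 2)
  expect_equal(pValue(tt), 1 - tt@statistic / sqrt(tt@statistic^2 + 2),
               tolerance = 1e-10)
  expect_equal(pValue(tt), 0.01307, tolerance = 1e-3)

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(7, mean = 1.3, sd = 0.4)
    o2 <- oracleOneSampleT(x, alternative = "two.sided")
    expect_equal(pValue(oneSampleTVsOne(x)), o2$p, tolerance = 1e-8)
    pl <- pValue(oneSampleTVsOne(x, "less"))
    pg <- pValue(oneSampleTVsOne(x, "greater"))
    expect_equal(pl, oracleOneSampleT(x, alternative = "less")$p,
                 tolerance = 1e-8)
    expect_equal(pl + pg, 1, tolerance = 1e-12)  # continuous statistic
  }
  expect_error(oneSampleTVsOne(1), "at least 2")
})

test_that("total signal ratio detects degradation and is sum-symmetric", {
  m <- list(apical_mfi = 8, basal_mfi = 4, bg_mfi = 2)
  expect_equal(totalSignalRatio(m, m), 1)
  half <- list(apical_mfi = 4, basal_mfi = 2, bg_mfi = 0)
  full <- list(apical_mfi = 8, basal_mfi = 4, bg_mfi = 0)
  expect_equal(totalSignalRatio(half, full), 0.5)
  swapped <- list(apical_mfi = 4, basal_mfi = 8, bg_mfi = 2)
  expect_equal(totalSignalRatio(swapped, m), 1)
  expect_error(totalSignalRatio(m, list(apical_mfi = 1, basal_mfi = 1,
                                        bg_mfi = 2)), "positive")
})

test_that("two-sample t matches Student and Welch oracles", {
  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(pValue(same), 1)
  shifted <- twoSampleT(c(1, 2, 3), c(11, 12, 13), pooled = TRUE)
  expect_lt(pValue(shifted), 0.01)

  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(9, sd = 2)
    w <- twoSampleT(a, b); s <- twoSampleT(a, b, pooled = TRUE)
    ow <- oracleWelchT(a, b); os <- oraclePooledT(a, b)
    expect_equal(pValue(w), ow$p, tolerance = 1e-8)
    expect_equal(w@df, ow$df, tolerance = 1e-8)
    expect_equal(pValue(s), os$p, tolerance = 1e-8)
    expect_lte(w@df, s@df + 1e-12)  # Satterthwaite never exceeds pooled df
  }
  # equality of dfs iff equal variances and n
  eq <- twoSampleT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(eq@df, 4, tolerance = 1e-12)
})

test_that("one-way ANOVA and Tukey match the sums-of-squares oracle", {
  const <- anovaTukey(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_true(const$anova@degenerate)
  expect_equal(const$anova@statistic, 0)
  expect_equal(pValue(const$anova), 1)
  expect_true(all(const$tukey$p_adj == 1))

  # two groups: F = t^2 of the pooled test, identical p
  a <- c(1.2, 1.9, 2.4, 1.7); b <- c(2.8, 3.1, 2.2)
  two <- anovaTukey(list(a = a, b = b))
  tt <- twoSampleT(a, b, pooled = TRUE)
  expect_equal(two$anova@statistic, tt@statistic^2, tolerance = 1e-10)
  expect_equal(pValue(two$anova), pValue(tt), tolerance = 1e-10)

  groups <- list(g1 = c(1.0, 1.4, 0.9), g2 = c(2.1, 2.5, 1.8),
                 g3 = c(1.2, 1.1, 1.5, 1.3))
  res <- anovaTukey(groups)
  o <- oracleAnovaF(groups)
  expect_equal(res$anova@statistic, o$f, tolerance = 1e-10)
  expect_equal(res$anova@df, o$df)
  expect_equal(pValue(res$anova), o$p, tolerance = 1e-10)
  # Tukey-Kramer p for unequal n against the studentized range directly
  i <- which(res$tukey$comparison == "g2-g1")
  se <- sqrt(o$ssw / sum(lengths(groups) - 1) *
               (1 / 3 + 1 / 3) / 2)
  q <- abs(mean(groups$g2) - mean(groups$g1)) / se
  expect_equal(res$tukey$p_adj[i],
               stats::ptukey(q, 3, sum(lengths(groups)) - 3,
                             lower.tail = FALSE), tolerance = 1e-8)
  expect_error(anovaTukey(list(a = 1, b = c(1, 2))), "at least 2 values")
})

test_that("A/B ratio test composes the per-pair ratio with the one-sample t", {
  same <- abRatioVsOne(c(2, 3, 4), c(2, 3, 4))
  expect_true(same@degenerate)
  expect_equal(pValue(same), 1)
  r <- c(1.1, 1.2, 1.3)
  expect_equal(pValue(abRatioVsOne(r, rep(1, 3))),
               pValue(oneSampleTVsOne(r)))
  expect_error(abRatioVsOne(c(1, 2), c(1, 2, 3)), "paired")
  expect_error(abRatioVsOne(c(1, 2), c(1, 0)), "> 0")
  # parameter recovery: apical enrichment factor 1.3 with noise
  set.seed(6)
  b <- runif(30, 5, 10)
  a <- 1.3 * b * (1 + rnorm(30, 0, 0.1))
  ratios <- a / b
  expect_lt(abs(mean(ratios) - 1.3), 3 * sd(ratios) / sqrt(30))
  expect_lt(pValue(abRatioVsOne(a, b)), 0.05)
})

test_that("KD/wt DoA summary aggregates per RNA with stars", {
  sim <- simulatePolarityMeasurements(nGroupsWt = 6, nGroupsKd = 6,
                                      trueDoaWt = 2, kdEffect = 2,
                                      noiseCv = 0.05, rnaId = "zip",
                                      condition = "KhcRNAi", seed = 10)
  sm <- summarizeKdWtDoA(doaTable(sim$measurements))
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n, 6L)
  expect_lt(abs(sm$mean_kd_wt_doa - 2), 0.3)
  expect_true(sm$significance %in% c("*", "**", "***"))
  expect_equal(significanceStars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})
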