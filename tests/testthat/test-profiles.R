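uniformProfile <- function(n = 101, value = 1)
  AxisProfile(seq(0, 1, length.out = n), rep(value, n))

test_that("profile normalization maps to the 0-1 range and is idempotent", {
  p <- AxisProfile(c(0, 1, 2), c(2, 4, 6))
  np <- normalizeProfile(p)
  expect_equal(profileValues(np), c(0, 0.5, 1))
  expect_equal(profilePositions(np), c(0, 0.5, 1))
  expect_true(isNormalized(np))
  expect_equal(profileValues(normalizeProfile(np)), profileValues(np))

  expect_message(flat <- normalizeProfile(AxisProfile(0:2, c(5, 5, 5))),
                 "constant")
  expect_equal(profileValues(flat), c(0, 0, 0))
  expect_true(flat@constant)

  expect_error(AxisProfile(c(0, 1), c(1, 2)), "at least 3")
  expect_error(AxisProfile(c(0, 1, 1), c(1, 2, 3)), "increasing")
})

test_that("half-area position: uniform, analytic step, and symmetries", {
  expect_equal(auc50Position(uniformProfile()), 0.5)

  # step of height 3 on [0, 0.5) and 1 on [0.5, 1]: the half-area point
  # solves 3x = 2/2, i.e. x = 1/3
  x <- seq(0, 1, length.out = 4001)
  step <- AxisProfile(x, ifelse(x < 0.5, 3, 1))
  expect_equal(auc50Position(step), 1 / 3, tolerance = 1e-3)

  set.seed(7)
  for (i in 1:5) {
    v <- runif(51, 0.2, 2)
    p <- AxisProfile(seq(0, 1, length.out = 51), v)
    # reversal antisymmetry is trapezoid-exact
    r <- AxisProfile(seq(0, 1, length.out = 51), rev(v))
    expect_equal(auc50Position(r), 1 - auc50Position(p),
                 tolerance = 1e-12)
    # invariance under intensity scaling
    ps <- AxisProfile(seq(0, 1, length.out = 51), 5.7 * v)
    expect_equal(auc50Position(ps), auc50Position(p), tolerance = 1e-12)
  }
  expect_error(auc50Position(AxisProfile(0:3, rep(0, 4))), "zero total area")
})

test_that("measured half-area position recovers generator truth on noise-free profiles", {
  for (bias in c(-2, -0.5, 0, 1, 3)) {
    sim <- simulateAxisProfiles(nPositions = 101, apicalBias = bias,
                                noiseSd = 0, nProfiles = 1, seed = 1)
    expect_lt(abs(auc50Position(sim$profiles[[1]]) -
                    sim$truth$true_auc50[1]), 1 / 100)
  }
})

test_that("auc50 group comparison is the Welch test on per-profile positions", {
  a <- c(0.3, 0.31, 0.29); b <- c(0.5, 0.51, 0.49)
  cmp <- compareAuc50(a, b)
  expect_lt(pValue(cmp), 0.01)
  expect_equal(pValue(cmp), pValue(twoSampleT(a, b)), tolerance = 1e-15)
  ident <- compareAuc50(c(0.4, 0.5), c(0.4, 0.5))
  expect_equal(pValue(ident), 1)
})

test_that("subdomain fractions follow the region geometry", {
  u <- uniformProfile()
  fr <- subdomainFractions(u, apicalBoundary = 0.5)
  expect_equal(unname(fr), c(100 / 6, 100 / 3, 50), tolerance = 1e-9)
  expect_equal(sum(fr), 100, tolerance = 1e-9)

  # all signal strictly inside the apical-most sixth
  x <- seq(0, 1, length.out = 1201)
  v <- ifelse(x < 1 / 6 - 0.01, 1, 0)
  apical6 <- AxisProfile(x, v)
  fr6 <- subdomainFractions(apical6, apicalBoundary = 0.5)
  expect_equal(unname(fr6), c(100, 0, 0), tolerance = 1e-9)

  # closed form for arbitrary boundary with uniform signal
  for (b in c(0.3, 0.5, 0.8)) {
    fr <- subdomainFractions(u, apicalBoundary = b)
    expect_equal(unname(fr), 100 * c(b / 3, 2 * b / 3, 1 - b),
                 tolerance = 1e-9)
  }

  # sums to 100 whenever signal survives the threshold
  set.seed(8)
  for (i in 1:5) {
    p <- AxisProfile(seq(0, 1, length.out = 31), runif(31))
    expect_equal(sum(subdomainFractions(p, 0.4, threshold = 0.2)), 100,
                 tolerance = 1e-9)
  }

  expect_error(subdomainFractions(u, apicalBoundary = 1.5), "inside")
  expect_error(subdomainFractions(u, apicalBoundary = 0.5, threshold = 2),
               "no quantifiable signal")
})

test_that("line-scan normalization preserves channels and requires one grid", {
  x <- seq(0, 1, length.out = 21)
  ch1 <- AxisProfile(x, sin(pi * x) + 1, channel = "BicD")
  ch2 <- AxisProfile(x, 3 * (sin(pi * x) + 1), channel = "Dhc")
  out <- linescanProfiles(list(ch1, ch2))
  expect_equal(vapply(out, profileChannel, ""), c("BicD", "Dhc"))
  # proportional channels normalize to identical curves
  expect_equal(profileValues(out[[1]]), profileValues(out[[2]]),
               tolerance = 1e-12)
  # single channel identical to normalizeProfile
  expect_equal(profileValues(linescanProfiles(list(ch1))[[1]]),
               profileValues(normalizeProfile(ch1)))
  bad <- AxisProfile(seq(0, 2, length.out = 21), sin(pi * x) + 1)
  expect_error(linescanProfiles(list(ch1, bad)), "same position grid")
})

bumpProfile <- function(centers, x = seq(0, 1, length.out = 201), w = 0.03) {
  v <- rep(0, length(x))
  for (ct in centers) v <- pmax(v, pmax(1 - abs(x - ct) / w, 0))
  normalizeProfile(AxisProfile(x, v))
}

test_that("peak coincidence counts a-peaks near b-peaks", {
  a <- bumpProfile(c(0.2, 0.6))
  expect_equal(peakCoincidence(a, a, tolerance = 0.05), 1)
  far <- bumpProfile(0.8)
  expect_equal(peakCoincidence(bumpProfile(0.2), far, tolerance = 0.1), 0)
  half <- bumpProfile(c(0.21, 0.9))
  expect_equal(peakCoincidence(a, half, tolerance = 0.05), 0.5)
  flat <- normalizeProfile(AxisProfile(seq(0, 1, length.out = 201),
                                       seq(1, 2, length.out = 201)))
  expect_error(peakCoincidence(flat, a, tolerance = 0.05), "no peaks")
  expect_error(peakCoincidence(a, bumpProfile(0.5), tolerance = -1), "> 0")
})

test_that("coincidence of random peaks matches the analytic coverage rate", {
  # one a-peak at 0.5, one uniformly placed b-peak on [0.15, 0.85]:
  # coverage probability of |pa - pb| <= 0.07 is 0.14 / 0.7 = 0.2
  set.seed(9)
  hits <- vapply(1:200, function(i) {
    peakCoincidence(bumpProfile(0.5), bumpProfile(runif(1, 0.15, 0.85)),
                    tolerance = 0.07)
  }, 1)
  expect_lt(abs(mean(hits) - 0.2), 3 * sqrt(0.2 * 0.8 / 200) + 0.02)
})
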