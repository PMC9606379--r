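# Independent brute-force oracles. These never call the package's own code
# paths: plain arithmetic, closed forms and enumeration only.

oracleOneSampleT <- function(x, mu = 1, alternative = "two.sided") {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), n - 1),
              less = stats::pt(t, n - 1),
              greater = stats::pt(t, n - 1, lower.tail = FALSE))
  list(t = t, df = n - 1, p = p)
}

oracleWelchT <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# one-way ANOVA from explicit sums of squares
oracleAnovaF <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups); N <- length(y)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, df = c(k - 1, N - k), ssb = ssb, ssw = ssw,
       p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
oracleWilcoxonExact <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  all.w <- apply(utils::combn(m + n, m), 2L,
                 function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(all.w <= w), mean(all.w >= w)))
}

# through-origin least squares from the normal equations
oracleOriginFit <- function(x, y) {
  slope <- sum(x * y) / sum(x^2)
  n <- length(x)
  rss <- sum((y - slope * x)^2)
  se <- sqrt(rss / (n - 1) / sum(x^2))
  r2 <- 1 - rss / sum(y^2)
  list(slope = slope, se = se, df = n - 1,
       adj_r2 = 1 - (1 - r2) * n / (n - 1))
}

# trapezoidal area, written out longhand
oracleTrapz <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1))
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  a
}
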