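# Axis-profile statistics: 0-1 normalization, the 50% cumulative-AUC
# localization proxy, subdomain integrated-density fractions, and line-scan
# peak coincidence. Integration is trapezoidal throughout.

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Normalize an axis profile to the 0-1 range
#'
#' Min-max normalization of intensity values and affine mapping of the
#' positions onto `[0, 1]` (0 stays the apical end). A constant profile has
#' no dynamic range; its values map to all zeros, the `constant` flag is
#' set, and a message is emitted. Idempotent.
#'
#' @param p an [AxisProfile-class].
#' @return the normalized profile (flag `normalized` set).
#' @examples
#' p <- AxisProfile(c(0, 1, 2), c(2, 4, 6))
#' profileValues(normalizeProfile(p))  # 0, 0.5, 1
#' @rdname normalizeProfile
#' @export
setMethod("normalizeProfile", "AxisProfile", function(p) {
  pos <- p@positions
  pos <- (pos - pos[1]) / (pos[length(pos)] - pos[1])
  v <- p@values
  rng <- range(v)
  constant <- diff(rng) == 0
  if (constant) {
    message("constant profile ", sQuote(p@profileId),
            ": normalized values set to 0")
    v <- rep(0, length(v))
  } else {
    v <- (v - rng[1]) / diff(rng)
  }
  AxisProfile(pos, v, profileId = p@profileId, channel = p@channel,
              normalized = TRUE, constant = constant)
})

#' Position of 50% cumulative area under the curve
#'
#' Integrates the profile from the apical end by the trapezoidal rule and
#' returns the position at which the cumulative area reaches half of the
#' total, located by linear interpolation of the cumulative area within the
#' bracketing segment (a flat plateau at exactly 50% resolves to its
#' apical-most point). Apically concentrated profiles give values below the
#' midpoint of the axis; the statistic is invariant under scaling of the
#' intensities.
#'
#' @param p an [AxisProfile-class] with strictly positive total area.
#' @return the half-area position (in the profile's position units; in
#'   `[0, 1]` for normalized profiles).
#' @examples
#' u <- AxisProfile(seq(0, 1, length.out = 11), rep(2, 11))
#' auc50Position(u)  # 0.5
#' @rdname auc50Position
#' @export
setMethod("auc50Position", "AxisProfile", function(p) {
  x <- p@positions; v <- p@values
  inc <- diff(x) * (head(v, -1) + v[-1]) / 2
  cum <- c(0, cumsum(inc))
  total <- cum[length(cum)]
  if (total <= 0) stop("profile has zero total area")
  half <- total / 2
  i <- which(cum >= half)[1]
  if (i == 1L) return(x[1])
  denom <- cum[i] - cum[i - 1]
  frac <- if (denom > 0) (half - cum[i - 1]) / denom else 0
  x[i - 1] + frac * (x[i] - x[i - 1])
})

#' Compare half-area positions between two groups of profiles
#'
#' Welch two-sample two-sided t-test on per-profile `auc50` positions, the
#' comparison used for treatment-versus-control localization shifts.
#'
#' @param groupA,groupB numeric vectors of half-area positions (each
#'   n >= 2), e.g. from `vapply(profiles, auc50Position, 1)`.
#' @return a [TestResult-class].
#' @export
compareAuc50 <- function(groupA, groupB) twoSampleT(groupA, groupB,
                                                    pooled = FALSE)

#' Subdomain integrated-density fractions
#'
#' Splits the axis into three subdomains: apical-cortical (the apical-most
#' third of the apical region `[0, apicalBoundary]`), subapical (the
#' remaining two-thirds of the apical region) and basal (everything beyond
#' `apicalBoundary`). Values below `threshold` are zeroed (signal
#' thresholding), the thresholded curve is integrated trapezoidally per
#' subdomain (with interpolated knots inserted at the subdomain borders),
#' and each integral is expressed as a percentage of the total.
#'
#' @param p an [AxisProfile-class].
#' @param apicalBoundary position of the apical/basal split, strictly
#'   inside the profile's span.
#' @param threshold non-negative intensity threshold.
#' @return named numeric: `pct_apical_cortical`, `pct_subapical`,
#'   `pct_basal`, summing to 100.
#' @examples
#' u <- AxisProfile(seq(0, 1, length.out = 101), rep(1, 101))
#' subdomainFractions(u, apicalBoundary = 0.5)
#' @export
subdomainFractions <- function(p, apicalBoundary, threshold = 0) {
  x <- p@positions; v <- p@values
  if (apicalBoundary <= x[1] || apicalBoundary >= x[length(x)])
    stop("'apicalBoundary' must lie strictly inside the profile span")
  if (threshold < 0) stop("'threshold' must be >= 0")
  v[v < threshold] <- 0
  if (all(v == 0))
    stop("no quantifiable signal: all values fall below the threshold")
  cuts <- c(x[1] + (apicalBoundary - x[1]) / 3, apicalBoundary)
  xa <- sort(unique(c(x, cuts)))
  va <- approx(x, v, xout = xa)$y
  segArea <- function(lo, hi) {
    sel <- xa >= lo & xa <= hi
    .trapz(xa[sel], va[sel])
  }
  areas <- c(pct_apical_cortical = segArea(x[1], cuts[1]),
             pct_subapical = segArea(cuts[1], cuts[2]),
             pct_basal = segArea(cuts[2], x[length(x)]))
  100 * areas / sum(areas)
}

#' Normalize a set of line-scan channels measured on one cross-section
#'
#' Applies [normalizeProfile()] to each channel of a multi-channel line
#' scan; all channels must share the same position grid. Channel order and
#' labels are preserved.
#'
#' @param channels list of [AxisProfile-class] objects on one grid.
#' @return list of normalized profiles in the input order.
#' @export
linescanProfiles <- function(channels) {
  if (!length(channels)) stop("'channels' must be non-empty")
  ref <- channels[[1]]@positions
  same <- vapply(channels, function(ch)
    length(ch@positions) == length(ref) && all(ch@positions == ref), TRUE)
  if (!all(same)) stop("all channels must share the same position grid")
  lapply(channels, normalizeProfile)
}

# local maxima with topographic prominence >= floor; returns positions
.findPeaks <- function(x, v, prominence) {
  n <- length(v)
  idx <- which(v[-c(1, n)] >= v[-c(n - 1, n)] & v[-c(1, n)] >= v[-(1:2)] &
                 (v[-c(1, n)] > v[-c(n - 1, n)] | v[-c(1, n)] > v[-(1:2)])) + 1L
  if (!length(idx)) return(numeric(0))
  prom <- vapply(idx, function(i) {
    higherL <- which(v[seq_len(i - 1)] > v[i])
    left <- if (length(higherL)) min(v[(max(higherL) + 1):(i - 1)])
            else min(v[seq_len(i)])
    higherR <- which(v[(i + 1):n] > v[i]) + i
    right <- if (length(higherR)) min(v[(i + 1):(min(higherR) - 1)])
             else min(v[i:n])
    v[i] - max(left, right)
  }, 1)
  x[idx[prom >= prominence]]
}

#' Fraction of peaks in one channel coinciding with peaks in another
#'
#' Detects local intensity maxima with topographic prominence of at least
#' `prominence` (default 0.1 of the normalized range) in both channels and
#' returns the fraction of `a`-peaks lying within `tolerance` of some
#' `b`-peak — a quantitative co-localization proxy for dual-channel line
#' scans. `a` having no peaks is an error (no denominator), distinct from a
#' coincidence of 0.
#'
#' @param a,b normalized [AxisProfile-class] objects on the same grid.
#' @param tolerance positive position tolerance (in position units).
#' @param prominence minimum peak prominence.
#' @return fraction in `[0, 1]`.
#' @export
peakCoincidence <- function(a, b, tolerance, prominence = 0.1) {
  if (tolerance <= 0) stop("'tolerance' must be > 0")
  if (!a@normalized || !b@normalized)
    stop("profiles must be normalized (see normalizeProfile)")
  if (length(a@positions) != length(b@positions) ||
      any(a@positions != b@positions))
    stop("profiles must share the same position grid")
  pa <- .findPeaks(a@positions, a@values, prominence)
  if (!length(pa)) stop("no peaks detected in profile 'a'")
  pb <- .findPeaks(b@positions, b@values, prominence)
  if (!length(pb)) return(0)
  mean(vapply(pa, function(p) any(abs(p - pb) <= tolerance), TRUE))
}
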