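# Seeded generators with ground truth. Each call uses one local RNG stream
# (withLocalSeed); the caller's RNG state is never touched.

.locClasses <- c("bona_fide_apical", "bona_fide_basal",
                 "oocyte_contaminant", "muscle_contaminant",
                 "not_significant")
.truthClasses <- c("bona_fide_apical", "bona_fide_basal",
                   "oocyte_contaminant", "muscle_contaminant",
                   "not_enriched")

#' Simulate a two-domain LCM count table with known localization truth
#'
#' Draws negative-binomial counts for a gene-by-sample design with
#' `nReplicates` apical and `nReplicates` basal samples. A configurable
#' fraction of genes is apically or basally enriched with absolute log2 fold
#' changes inside `enrichedLfcRange` (bona fide localizers, bounded by the
#' contaminant threshold at 3), and further fractions emulate cross-tissue
#' contaminants: strongly expressed in one domain and nearly absent
#' (expected count `contaminantDepletedMean`, default 0.5) in the other, so
#' their absolute log2 fold change is at least `contaminantLfcMin` (> 3).
#'
#' Counts for gene g, sample j are NB with mean `sf_j * mu_gd(j)` and size
#' `1/dispersion` (variance `mu + dispersion * mu^2`); `dispersion = 0`
#' gives Poisson counts. Per-sample library-size factors `sf_j` are
#' log-normal with unit mean and coefficient of variation `librarySizeCv`.
#'
#' @param nGenes number of genes (>= 0).
#' @param nReplicates replicates per domain (>= 2).
#' @param baselineLogRange log10 range of baseline mean counts; defaults to
#'   `c(1.7, 3)`, i.e. means of roughly 50-1000.
#' @param dispersion NB dispersion (reciprocal of the size parameter), >= 0.
#' @param fracApical,fracBasal,fracOocyte,fracMuscle class fractions in
#'   `[0, 1]`, summing to at most 1; remaining genes are unenriched.
#' @param enrichedLfcRange range of absolute log2 fold changes for bona fide
#'   localizers; must lie within `(0, 3]`.
#' @param contaminantLfcMin minimum absolute log2 fold change of
#'   contaminants; must exceed 3.
#' @param contaminantDepletedMean expected count of a contaminant in its
#'   depleted domain (small but nonzero so fold changes stay defined).
#' @param librarySizeCv coefficient of variation of library-size factors.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return a list with `counts` (an [LCMCountSet-class]) and `truth`, a
#'   data.frame with one row per gene: `id`, `true_class` (one of
#'   `bona_fide_apical`, `bona_fide_basal`, `oocyte_contaminant`,
#'   `muscle_contaminant`, `not_enriched`), `true_lfc` and
#'   `true_baseline_mean`.
#' @examples
#' sim <- simulateLcmCounts(nGenes = 100, seed = 1)
#' table(sim$truth$true_class)
#' @export
simulateLcmCounts <- function(nGenes = 2000L, nReplicates = 4L,
                              baselineLogRange = c(1.7, 3),
                              dispersion = 0.05,
                              fracApical = 0.15, fracBasal = 0.10,
                              fracOocyte = 0.01, fracMuscle = 0.02,
                              enrichedLfcRange = c(1.5, 2.5),
                              contaminantLfcMin = 5,
                              contaminantDepletedMean = 0.5,
                              librarySizeCv = 0.1, seed = NULL) {
  if (nGenes < 0) stop("'nGenes' must be >= 0")
  if (nReplicates < 2) stop("'nReplicates' must be >= 2")
  fracs <- c(fracApical, fracBasal, fracOocyte, fracMuscle)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1)
    stop("class fractions must lie in [0, 1] and sum to at most 1")
  if (length(baselineLogRange) != 2L || diff(baselineLogRange) < 0)
    stop("'baselineLogRange' must be an increasing pair")
  if (length(enrichedLfcRange) != 2L || enrichedLfcRange[1] <= 0 ||
      enrichedLfcRange[2] > 3 || diff(enrichedLfcRange) < 0)
    stop("'enrichedLfcRange' must lie within (0, 3]")
  if (contaminantLfcMin <= 3)
    stop("'contaminantLfcMin' must exceed the contaminant boundary of 3")
  if (dispersion < 0 || librarySizeCv < 0)
    stop("'dispersion' and 'librarySizeCv' must be >= 0")

  withLocalSeed(seed, {
    ids <- if (nGenes > 0) sprintf("gene%05d", seq_len(nGenes)) else character(0)
    nPerClass <- floor(nGenes * fracs)
    cls <- rep(.truthClasses[c(1:4, 5)],
               times = c(nPerClass, nGenes - sum(nPerClass)))
    cls <- if (nGenes > 0) sample(cls) else character(0)

    baseline <- 10^runif(nGenes, baselineLogRange[1], baselineLogRange[2])
    lfc <- numeric(nGenes)
    muA <- muB <- baseline
    enr <- cls %in% c("bona_fide_apical", "bona_fide_basal")
    if (any(enr)) {
      mag <- runif(sum(enr), enrichedLfcRange[1], enrichedLfcRange[2])
      sgn <- ifelse(cls[enr] == "bona_fide_apical", 1, -1)
      lfc[enr] <- sgn * mag
      # split the fold change symmetrically around the baseline
      muA[enr] <- baseline[enr] * 2^(lfc[enr] / 2)
      muB[enr] <- baseline[enr] * 2^(-lfc[enr] / 2)
    }
    cont <- cls %in% c("oocyte_contaminant", "muscle_contaminant")
    if (any(cont)) {
      hi <- pmax(baseline[cont],
                 contaminantDepletedMean * 2^contaminantLfcMin)
      sgn <- ifelse(cls[cont] == "oocyte_contaminant", 1, -1)
      lfc[cont] <- sgn * log2(hi / contaminantDepletedMean)
      muA[cont] <- ifelse(sgn > 0, hi, contaminantDepletedMean)
      muB[cont] <- ifelse(sgn > 0, contaminantDepletedMean, hi)
    }

    nS <- 2L * nReplicates
    sf <- if (librarySizeCv > 0) {
      sdl <- sqrt(log1p(librarySizeCv^2))
      rlnorm(nS, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else rep(1, nS)
    mu <- cbind(matrix(muA, nGenes, nReplicates),
                matrix(muB, nGenes, nReplicates))
    mu <- sweep(mu, 2L, sf, `*`)
    m <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nGenes, nS)
    } else matrix(rpois(length(mu), lambda = mu), nGenes, nS)
    dimnames(m) <- list(ids, c(paste0("A", seq_len(nReplicates)),
                               paste0("B", seq_len(nReplicates))))
    cset <- LCMCountSet(m, domain = rep(c("apical", "basal"),
                                        each = nReplicates))
    truth <- data.frame(id = ids, true_class = cls, true_lfc = lfc,
                        true_baseline_mean = baseline,
                        stringsAsFactors = FALSE)
    list(counts = cset, truth = truth)
  })
}

#' Simulate paired smFISH polarity measurements
#'
#' Emulates mean-fluorescence-intensity (m.f.i.) measurements of an RNA's
#' apical and basal signal in paired wild-type/knockdown cell groups sharing
#' an image stack. For each group, the basal signal is
#' `background + signal * (1 + e)` and the apical signal is
#' `background + signal * doa * (1 + e')`, with independent Gaussian
#' relative noise of standard deviation `noiseCv` (resampled while
#' `1 + e <= 0.05` so every measurement stays above background; resampling
#' events are reported via a message). Knockdown groups use
#' `doa = trueDoaWt * kdEffect`.
#'
#' Stack `i` contributes a wild-type measurement when `i <= nGroupsWt` and a
#' knockdown measurement when `i <= nGroupsKd`; the shared `group_id`
#' (`"stack<i>"`) is the pairing key used by [pairedKdWtDoA()].
#'
#' @param nGroupsWt,nGroupsKd numbers of wild-type / knockdown cell groups.
#' @param trueDoaWt true wild-type degree of apicality (> 0).
#' @param kdEffect multiplicative knockdown effect on the DoA (1 = none).
#' @param backgroundMean background m.f.i.
#' @param signalMean basal signal amplitude above background.
#' @param noiseCv relative noise SD (>= 0).
#' @param rnaId,condition labels copied into the output.
#' @param seed integer seed.
#'
#' @return a list with `measurements` (data.frame with columns `group_id`,
#'   `rna_id`, `condition`, `cell_type`, `apical_mfi`, `basal_mfi`,
#'   `bg_mfi`) and `truth` (list with `true_doa_wt`, `kd_effect`).
#' @examples
#' sim <- simulatePolarityMeasurements(trueDoaWt = 2, kdEffect = 1.5,
#'                                     noiseCv = 0, seed = 1)
#' head(sim$measurements)
#' @export
simulatePolarityMeasurements <- function(nGroupsWt = 10L, nGroupsKd = 10L,
                                         trueDoaWt = 2, kdEffect = 1,
                                         backgroundMean = 10,
                                         signalMean = 100, noiseCv = 0.1,
                                         rnaId = "rna", condition = "cond",
                                         seed = NULL) {
  if (nGroupsWt < 1 || nGroupsKd < 1)
    stop("'nGroupsWt' and 'nGroupsKd' must be >= 1")
  if (trueDoaWt <= 0 || kdEffect <= 0)
    stop("'trueDoaWt' and 'kdEffect' must be > 0")
  if (noiseCv < 0 || backgroundMean < 0 || signalMean <= 0)
    stop("invalid noise, background or signal configuration")

  withLocalSeed(seed, {
    nResample <- 0L
    relNoise <- function(n) {
      e <- 1 + rnorm(n, 0, noiseCv)
      bad <- which(e <= 0.05)
      while (length(bad)) {
        nResample <<- nResample + length(bad)
        e[bad] <- 1 + rnorm(length(bad), 0, noiseCv)
        bad <- bad[e[bad] <= 0.05]
      }
      e
    }
    oneType <- function(n, type, doa) {
      if (n == 0L) return(NULL)
      data.frame(group_id = paste0("stack", seq_len(n)),
                 rna_id = rnaId, condition = condition, cell_type = type,
                 apical_mfi = backgroundMean +
                   signalMean * doa * relNoise(n),
                 basal_mfi = backgroundMean + signalMean * relNoise(n),
                 bg_mfi = backgroundMean, stringsAsFactors = FALSE)
    }
    meas <- rbind(oneType(nGroupsWt, "wt", trueDoaWt),
                  oneType(nGroupsKd, "kd", trueDoaWt * kdEffect))
    if (nResample > 0)
      message("resampled ", nResample,
              " noise draws to keep signal above background")
    list(measurements = meas,
         truth = list(true_doa_wt = trueDoaWt, kd_effect = kdEffect))
  })
}

# exponential axis shape: f(x) = exp(-bias * x); bias > 0 piles mass apically
.profileShape <- function(x, bias) {
  if (abs(bias) < 1e-12) rep(1, length(x)) else exp(-bias * x)
}

# exact half-area position of the noise-free exponential shape on [0, 1]
.analyticAuc50 <- function(bias) {
  if (abs(bias) < 1e-12) return(0.5)
  -log(1 - 0.5 * (1 - exp(-bias))) / bias
}

#' Simulate apical-basal axis intensity profiles
#'
#' Generates intensity profiles over `nPositions` evenly spaced positions on
#' `[0, 1]` (0 = apical end). The noise-free shape is `exp(-apicalBias * x)`:
#' positive bias concentrates signal apically, negative bias basally, 0 is
#' uniform. Gaussian noise of SD `noiseSd` is added and clipped at 0. The
#' returned truth holds the half-area position of the noise-free shape,
#' computed from the closed-form integral (not from the sampled grid).
#'
#' @param nPositions grid size (>= 3).
#' @param apicalBias shape parameter; 0 = uniform.
#' @param noiseSd additive noise SD (>= 0) relative to a unit-amplitude shape.
#' @param nProfiles number of profiles.
#' @param channel channel label.
#' @param seed integer seed.
#'
#' @return list with `profiles` (list of [AxisProfile-class]) and `truth`, a
#'   data.frame with `id` and `true_auc50`.
#' @examples
#' sim <- simulateAxisProfiles(apicalBias = 2, noiseSd = 0, seed = 1)
#' sim$truth$true_auc50[1]
#' @export
simulateAxisProfiles <- function(nPositions = 101L, apicalBias = 0,
                                 noiseSd = 0, nProfiles = 5L,
                                 channel = "ch1", seed = NULL) {
  if (nPositions < 3) stop("'nPositions' must be >= 3")
  if (nProfiles < 1) stop("'nProfiles' must be >= 1")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  withLocalSeed(seed, {
    x <- seq(0, 1, length.out = nPositions)
    shape <- .profileShape(x, apicalBias)
    ids <- sprintf("profile%03d", seq_len(nProfiles))
    profiles <- lapply(ids, function(id) {
      v <- pmax(shape + rnorm(nPositions, 0, noiseSd), 0)
      AxisProfile(x, v, profileId = id, channel = channel)
    })
    truth <- data.frame(id = ids,
                        true_auc50 = .analyticAuc50(apicalBias),
                        stringsAsFactors = FALSE)
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate paired ribosome-footprint and RNA-seq TPM tables
#'
#' Emulates the input of a translation-efficiency meta-analysis: two gene
#' groups (`apical` and `basal`) with log-normal RNA abundances, where the
#' basal group's log2 translation efficiency (RFP TPM / RNA TPM) is shifted
#' upward by `shift` relative to the apical group. All TPM values are
#' strictly positive.
#'
#' @param nGenesPerGroup genes per group (>= 2).
#' @param shift log2 translation-efficiency difference (basal minus apical).
#' @param sdLog2Te SD of per-gene log2 TE around its group mean.
#' @param seed integer seed.
#'
#' @return data.frame with columns `gene_id`, `loc_class`
#'   (`bona_fide_apical` / `bona_fide_basal`), `rfp_tpm`, `rna_tpm`.
#' @examples
#' tab <- simulateTpmTables(nGenesPerGroup = 50, shift = 2, seed = 1)
#' @export
simulateTpmTables <- function(nGenesPerGroup = 200L, shift = 0,
                              sdLog2Te = 0.5, seed = NULL) {
  if (nGenesPerGroup < 2) stop("'nGenesPerGroup' must be >= 2")
  if (sdLog2Te < 0) stop("'sdLog2Te' must be >= 0")
  withLocalSeed(seed, {
    n <- 2L * nGenesPerGroup
    cls <- rep(c("bona_fide_apical", "bona_fide_basal"),
               each = nGenesPerGroup)
    rna <- rlnorm(n, meanlog = log(50), sdlog = 1)
    te <- 2^(ifelse(cls == "bona_fide_basal", shift, 0) +
               rnorm(n, 0, sdLog2Te))
    data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
               loc_class = cls, rfp_tpm = rna * te, rna_tpm = rna,
               stringsAsFactors = FALSE)
  })
}
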