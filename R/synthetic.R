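#' Simulate a BOLD time series from known ordinality tuning
#'
#' Generates `series = predictBold(truth) + noise` for one recording site,
#' with white Gaussian or AR(1) noise. The noise amplitude can be given
#' directly (`noiseSd`) or via a target signal-to-noise ratio (`snr`, the
#' ratio of noiseless-signal variance to noise variance), in which case the
#' noise standard deviation is derived from the realized signal variance.
#'
#' @param design a [RunDesign-class].
#' @param mu,sigma true tuning parameters.
#' @param gain,offset true response amplitude and baseline.
#' @param noiseSd noise standard deviation (ignored when `snr` is given).
#' @param snr optional target signal-to-noise variance ratio.
#' @param noiseModel `"white"` or `"ar1"`.
#' @param arCoef AR(1) coefficient in (-1, 1); the innovation variance is
#'   scaled so the marginal noise variance matches the requested amplitude.
#' @param hrf HRF used by the forward model.
#' @param seed RNG seed; the draw is deterministic per seed.
#' @return list with `series` (numeric vector) and `truth` (one-row
#'   data.frame recording every generating parameter).
#' @export
simulateSite <- function(design, mu, sigma, gain = 1, offset = 0,
                         noiseSd = 0.5, snr = NULL, noiseModel = "white",
                         arCoef = 0.5, hrf = canonicalHRF(), seed = NULL) {
  signal <- predictBold(design, logGaussianTuning(mu, sigma), hrf,
                        gain = gain, offset = offset)
  if (!is.null(snr)) {
    stopifnot(snr > 0)
    noiseSd <- sd(signal) / sqrt(snr)
  }
  stopifnot(noiseSd >= 0, abs(arCoef) < 1)
  n <- length(signal)
  noise <- .withSeed(seed, {
    if (noiseModel == "ar1") {
      innov <- rnorm(n, sd = noiseSd * sqrt(1 - arCoef^2))
      as.numeric(stats::filter(innov, arCoef, method = "recursive"))
    } else {
      rnorm(n, sd = noiseSd)
    }
  })
  list(series = signal + noise,
       truth = data.frame(mu = mu, sigma = sigma, fwhm = fwhm(mu, sigma),
                          gain = gain, offset = offset, noise_sd = noiseSd,
                          noise_model = noiseModel,
                          snr = if (is.null(snr)) NA_real_ else snr,
                          seed = if (is.null(seed)) NA_integer_ else seed))
}

#' Simulate a population of tuned sites under two stimulus conditions
#'
#' Draws true preferred ordinalities over [1, 7] (by default skewed toward
#' low ranks, mirroring the empirical over-representation of early
#' positions), assigns tuning widths through a width law, and renders each
#' source site's noiseless signal under both condition designs. Each source
#' site is replicated `k` times with shared signal and independent noise,
#' emulating upsampling of acquired voxels onto a finer representation;
#' replicates share an `upsampling_group` identifier.
#'
#' The width law is stated on the scale the group trend test measures --
#' linear-rank FWHM: `fwhm = widthIntercept + widthSlope * mu`, from which
#' the log-domain width follows as
#' `sigma = asinh(fwhm / (2 mu)) / sqrt(2 ln 2)`. Slope 0 therefore makes
#' FWHM genuinely independent of preferred rank (the null of the trend
#' test); note that a constant *log-domain* width would not, since linear
#' FWHM scales with `mu` at fixed `sigma`. The `"log-affine"` law
#' `sigma = widthIntercept + widthSlope * ln(mu)` is available for
#' experiments parameterized in log units.
#'
#' @param nSites number of source sites.
#' @param designA,designB run designs of the two stimulus conditions.
#' @param muDistribution `"lowskew"` (default; `1 + 6 * Beta(1, 2)`) or
#'   `"uniform"` over [1, 7].
#' @param widthLaw `"fwhm-linear"` (default) or `"log-affine"`; see Details.
#' @param widthIntercept,widthSlope width-law parameters; slope `>= 0` gives
#'   widths non-decreasing in preferred rank on the law's scale.
#' @param gain,offset shared response amplitude and baseline.
#' @param noiseSd,snr noise amplitude, as in [simulateSite()].
#' @param k upsampling factor (replicates per source site).
#' @param hrf HRF of the forward model.
#' @param seed RNG seed.
#' @return list with matrices `seriesA`, `seriesB` (rows = `nSites * k`
#'   sites) and `truth` (per-row generating parameters including
#'   `upsampling_group`).
#' @export
simulatePopulation <- function(nSites, designA, designB,
                               muDistribution = c("lowskew", "uniform"),
                               widthLaw = c("fwhm-linear", "log-affine"),
                               widthIntercept = 1.5, widthSlope = 0.5,
                               gain = 1, offset = 0, noiseSd = 0.5,
                               snr = NULL, k = 1, hrf = canonicalHRF(),
                               seed = 1L) {
  muDistribution <- match.arg(muDistribution)
  widthLaw <- match.arg(widthLaw)
  stopifnot(k >= 1, nSites >= 1)
  .withSeed(seed, {
    mu <- if (muDistribution == "uniform") runif(nSites, 1, 7)
          else 1 + 6 * rbeta(nSites, 1, 2)
    sigma <- if (widthLaw == "fwhm-linear") {
      fw <- widthIntercept + widthSlope * mu
      if (any(fw <= 0)) stop("width law produced nonpositive FWHM")
      asinh(fw / (2 * mu)) / sqrt(2 * log(2))
    } else {
      widthIntercept + widthSlope * log(mu)
    }
    if (any(sigma <= 0)) stop("width law produced nonpositive sigma")
    nT_A <- length(activeOrdinality(designA))
    nT_B <- length(activeOrdinality(designB))
    total <- nSites * k
    seriesA <- matrix(NA_real_, total, nT_A)
    seriesB <- matrix(NA_real_, total, nT_B)
    for (s in seq_len(nSites)) {
      tun <- logGaussianTuning(mu[s], sigma[s])
      sigA <- predictBold(designA, tun, hrf, gain, offset)
      sigB <- predictBold(designB, tun, hrf, gain, offset)
      nsd <- if (!is.null(snr)) sd(sigA) / sqrt(snr) else noiseSd
      rows <- (s - 1) * k + seq_len(k)
      seriesA[rows, ] <- matrix(rep(sigA, k), k, byrow = TRUE) +
        matrix(rnorm(k * nT_A, sd = nsd), k)
      seriesB[rows, ] <- matrix(rep(sigB, k), k, byrow = TRUE) +
        matrix(rnorm(k * nT_B, sd = nsd), k)
    }
    truth <- data.frame(
      site_id = sprintf("site_%04d", seq_len(total)),
      upsampling_group = rep(sprintf("vox_%04d", seq_len(nSites)), each = k),
      mu = rep(mu, each = k), sigma = rep(sigma, each = k),
      fwhm = rep(fwhm(mu, sigma), each = k),
      gain = gain, offset = offset,
      stringsAsFactors = FALSE)
    list(seriesA = seriesA, seriesB = seriesB, truth = truth)
  })
}

#' Region table from included pRF fits
#'
#' Builds the pooled per-site table consumed by the group statistics
#' ([widthTrendTest()], [coverageByRank()]): one row per included site with
#' its preferred ordinality, FWHM and upsampling group.
#'
#' @param fits fit table with `r2_crossval`/`included` already applied.
#' @param truth optional truth table from [simulatePopulation()] supplying
#'   `upsampling_group`.
#' @param participant,region,cluster labels attached to all rows.
#' @return data.frame with columns `participant_id`, `region`, `cluster_id`,
#'   `site_id`, `preferred_ordinality`, `fwhm`, `upsampling_group`.
#' @export
regionTableFromFits <- function(fits, truth = NULL, participant = "p01",
                                region = "parietal", cluster = "c01") {
  keep <- fits$included
  out <- data.frame(participant_id = participant, region = region,
                    cluster_id = cluster,
                    site_id = fits$site_id[keep],
                    preferred_ordinality = fits$mu[keep],
                    fwhm = fits$fwhm[keep],
                    stringsAsFactors = FALSE)
  out$upsampling_group <- if (!is.null(truth))
    truth$upsampling_group[match(out$site_id, truth$site_id)] else NA_character_
  out
}

#' Plant tuned and null units over a snake dataset
#'
#' Ground-truth generator for the selectivity screen: unit responses are the
#' log-Gaussian tuning amplitude at each image's ordinality plus Gaussian
#' noise, optionally plus a stimulus-set nuisance term (a negative control
#' that the compound selection rule must reject). Rows of `tuningSpecs` with
#' `mu = NA` produce pure-noise units.
#'
#' @param labels label table from [generateSnakeDataset()].
#' @param tuningSpecs data.frame with columns `mu`, `sigma` and optionally
#'   `gain` (default 1) and `setEffect` (response added to all images of the
#'   irregular set; default 0). One row per unit.
#' @param noiseSd noise standard deviation.
#' @param seed RNG seed.
#' @return a unit response table ([unitResponseTable()]) with the truth
#'   stored in its `metadata`.
#' @export
plantCNNUnits <- function(labels, tuningSpecs, noiseSd = 0.2, seed = 1L) {
  nU <- nrow(tuningSpecs); nI <- nrow(labels)
  gain <- tuningSpecs$gain %||% rep(1, nU)
  setEff <- tuningSpecs$setEffect %||% rep(0, nU)
  isIrr <- as.numeric(labels$set == "irregular")
  Y <- .withSeed(seed, {
    Y <- matrix(rnorm(nU * nI, sd = noiseSd), nU, nI)
    for (u in seq_len(nU)) {
      if (!is.na(tuningSpecs$mu[u]))
        Y[u, ] <- Y[u, ] + gain[u] *
          logGaussianResponse(labels$ordinality, tuningSpecs$mu[u],
                              tuningSpecs$sigma[u])
      if (setEff[u] != 0) Y[u, ] <- Y[u, ] + setEff[u] * isIrr
    }
    Y
  })
  se <- unitResponseTable(Y, labels)
  S4Vectors::metadata(se)$truth <- tuningSpecs
  se
}
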