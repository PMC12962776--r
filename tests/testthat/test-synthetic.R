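test_that("site simulation is seed-deterministic and stores its truth", {
  d <- buildRunDesign()
  a <- simulateSite(d, 3, 0.5, snr = 2, seed = 7)
  b <- simulateSite(d, 3, 0.5, snr = 2, seed = 7)
  cc <- simulateSite(d, 3, 0.5, snr = 2, seed = 8)
  expect_identical(a$series, b$series)
  expect_false(identical(a$series, cc$series))
  expect_equal(a$truth$mu, 3)
  expect_equal(a$truth$fwhm, fwhm(3, 0.5))
})

test_that("noise-free sites return exactly their generating grid point", {
  d <- buildRunDesign()
  g <- smallGrid()
  s <- simulateSite(d, g$mu[40], g$sigma[40], noiseSd = 0, seed = 1)
  f <- fitPRFGrid(s$series, d, grid = g)
  expect_equal(f$mu, g$mu[40])
  expect_equal(f$sigma, g$sigma[40])
})

test_that("empirical signal-to-noise matches the requested level", {
  d <- buildRunDesign()
  snrHat <- vapply(1:100, function(i) {
    sig <- predictBold(d, logGaussianTuning(3, 0.5))
    s <- simulateSite(d, 3, 0.5, snr = 2, seed = 500 + i)
    var(sig) / var(s$series - sig)
  }, numeric(1))
  expect_lt(abs(mean(snrHat) - 2) / 2, 0.10)
})

test_that("AR(1) noise keeps the requested marginal variance and autocorrelation", {
  d <- buildRunDesign()
  sims <- vapply(1:200, function(i) {
    s <- simulateSite(d, 3, 0.5, gain = 0, noiseSd = 0.8, noiseModel = "ar1",
                      arCoef = 0.6, seed = 900 + i)
    x <- s$series
    c(var(x), cor(x[-1], x[-length(x)]))
  }, numeric(2))
  expect_equal(mean(sims[1, ]), 0.64, tolerance = 0.05)
  expect_equal(mean(sims[2, ]), 0.6, tolerance = 0.05)
})

test_that("population replicates share truth and group identifiers", {
  d <- buildRunDesign()
  pop <- simulatePopulation(10, d, d, k = 3, seed = 3)
  expect_equal(nrow(pop$seriesA), 30)
  expect_equal(length(unique(pop$truth$upsampling_group)), 10)
  grp <- split(pop$truth$mu, pop$truth$upsampling_group)
  expect_true(all(vapply(grp, function(v) length(unique(v)) == 1, logical(1))))
  # same seed reproduces the dataset exactly
  pop2 <- simulatePopulation(10, d, d, k = 3, seed = 3)
  expect_identical(pop$seriesA, pop2$seriesA)
})

test_that("the width law controls the FWHM-rank relation on the correct scale", {
  d <- buildRunDesign()
  null <- simulatePopulation(200, d, d, widthSlope = 0, widthIntercept = 3,
                             muDistribution = "uniform", seed = 5)
  expect_lt(diff(range(null$truth$fwhm)), 1e-9)      # slope 0: constant FWHM
  pos <- simulatePopulation(200, d, d, widthSlope = 0.5, widthIntercept = 1.5,
                            muDistribution = "uniform", seed = 5)
  expect_equal(cor(pos$truth$mu, pos$truth$fwhm), 1, tolerance = 1e-9)
})

test_that("planted units give ground truth for the selectivity screen", {
  lab <- syntheticLabels(nPerCell = 8)
  se <- plantCNNUnits(lab, data.frame(mu = 1, sigma = 0.4), noiseSd = 0,
                      seed = 1)
  scr <- screenSelectivity(se)
  expect_true(scr$selected[1])
  expect_equal(scr$preferred_ordinality[1], 1)
  seN <- plantCNNUnits(lab, data.frame(mu = NA, sigma = NA, setEffect = 1),
                       noiseSd = 0.05, seed = 2)
  expect_false(screenSelectivity(seN)$selected[1])
})

test_that("planted populations are detected with high sensitivity and few false picks", {
  lab <- syntheticLabels(nPerCell = 16)
  mus <- rep(1:5, each = 100)
  resp <- ordinalPRF:::logGaussianResponse(lab$ordinality, 2, 0.5)
  noiseSd <- sd(resp) / sqrt(5)                      # SNR 5
  specs <- data.frame(mu = c(mus, rep(NA, 1500)),
                      sigma = c(rep(0.5, 500), rep(NA, 1500)))
  se <- plantCNNUnits(lab, specs, noiseSd = noiseSd, seed = 71)
  scr <- screenSelectivity(se)
  # the ordinality effect is essentially always detected; the compound rule
  # caps attainable selection sensitivity near 0.9 * ~1.0 because ~9.75% of
  # tuned units draw a chance-significant set or interaction p
  expect_gt(mean(scr$p_ordinality[1:500] < 0.05), 0.9)
  expect_gt(mean(scr$selected[1:500]), 0.85)
  fpr <- mean(scr$selected[501:2000])
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / 1500))
})

test_that("full planted chain recovers a positive width-rank association", {
  oneRep <- function(rep) {
    seed <- 1000 + rep
    cfgS <- snakeDatasetConfig(10, "straight", repetitions = 1, seed = seed)
    cfgI <- snakeDatasetConfig(10, "irregular", repetitions = 4, seed = seed + 1)
    lab10 <- rbind(generateSnakeDataset(cfgS), generateSnakeDataset(cfgI))
    lab16 <- generateSnakeDataset(snakeDatasetConfig(16, "irregular",
                                                     repetitions = 5, seed = seed + 2))
    lab20 <- generateSnakeDataset(snakeDatasetConfig(20, "irregular",
                                                     repetitions = 5, seed = seed + 3))
    mus <- rep(1:5, length.out = 60)
    specs <- data.frame(mu = c(mus, rep(NA, 240)),
                        sigma = c(0.25 + 0.12 * log(mus), rep(NA, 240)))
    se10 <- plantCNNUnits(lab10, specs, noiseSd = 0.12, seed = seed + 4)
    scr <- screenSelectivity(se10)
    if (!sum(scr$selected)) return(c(NA, NA))
    sets <- list(se10,
                 plantCNNUnits(lab16, specs, noiseSd = 0.12, seed = seed + 5),
                 plantCNNUnits(lab20, specs, noiseSd = 0.12, seed = seed + 6))
    fits <- list()
    for (se in sets) {
      cv <- poolTuningCurves(se, scr)
      for (d in split(cv, cv$preferred)) {
        f <- fitCurveGaussian(d$mean, d$ordinality)
        if (!f$degenerate) fits[[length(fits) + 1]] <- c(f$center, f$fwhm)
      }
    }
    m <- do.call(rbind, fits)
    t <- widthRankTau(m[, 2], m[, 1])
    c(t$tau, t$p)
  }
  res <- t(vapply(1:50, oneRep, numeric(2)))
  expect_gte(mean(res[, 1] > 0 & res[, 2] < 0.05, na.rm = TRUE), 0.8)
})
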