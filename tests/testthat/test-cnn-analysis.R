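test_that("the vectorized ANOVA screen agrees with stats::aov", {
  lab <- syntheticLabels(nPerCell = 4)
  set.seed(31)
  specs <- data.frame(mu = c(2, NA, NA), sigma = c(0.5, NA, NA),
                      setEffect = c(0, 0.8, 0))
  se <- plantCNNUnits(lab, specs, noiseSd = 0.3, seed = 32)
  scr <- screenSelectivity(se)
  Y <- SummarizedExperiment::assay(se, "activations")
  for (u in 1:3) {
    d <- data.frame(y = Y[u, ], ord = factor(lab$ordinality),
                    set = factor(lab$set))
    a <- stats::anova(stats::lm(y ~ ord * set, data = d))
    expect_equal(scr$p_ordinality[u], a["ord", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(scr$p_set[u], a["set", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(scr$p_interaction[u], a["ord:set", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("planted tuned units are recovered with their preferred rank", {
  lab <- syntheticLabels(nPerCell = 16)
  mus <- rep(1:5, each = 20)
  # SNR 5: noise sd set from the planted response's variance over the labels
  resp <- ordinalPRF:::logGaussianResponse(lab$ordinality, 2, 0.5)
  noiseSd <- sd(resp) / sqrt(5)
  specs <- data.frame(mu = mus, sigma = 0.5)
  se <- plantCNNUnits(lab, specs, noiseSd = noiseSd, seed = 41)
  scr <- screenSelectivity(se)
  # the ordinality effect itself is detected essentially always; the compound
  # rule additionally drops ~9.75% of genuinely tuned units whose (null)
  # set or interaction p lands below 0.05 by chance
  expect_gt(mean(scr$p_ordinality < 0.05), 0.95)
  expect_gt(mean(scr$selected), 0.85)
  ok <- scr$selected
  expect_gt(mean(scr$preferred_ordinality[ok] == mus[ok]), 0.9)
})

test_that("the compound selection rule stays at or below its nominal level", {
  lab <- syntheticLabels(nPerCell = 16)
  specs <- data.frame(mu = rep(NA_real_, 2000), sigma = NA_real_)
  se <- plantCNNUnits(lab, specs, noiseSd = 1, seed = 43)
  scr <- screenSelectivity(se)
  expect_lte(mean(scr$selected), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("set-driven and flat units are rejected by the rule", {
  lab <- syntheticLabels(nPerCell = 8)
  specs <- data.frame(mu = c(NA, NA), sigma = c(NA, NA), setEffect = c(2, 0))
  se <- plantCNNUnits(lab, specs, noiseSd = 0.1, seed = 44)
  Y <- SummarizedExperiment::assay(se, "activations")
  Y[2, ] <- 0                                   # dead unit
  scr <- screenSelectivity(unitResponseTable(Y, lab))
  expect_false(scr$selected[1])
  expect_lt(scr$p_set[1], 0.05)
  expect_false(scr$selected[2])
  expect_equal(scr$p_ordinality[2], 1)
})

test_that("unbalanced designs are refused by the screen", {
  lab <- syntheticLabels(nPerCell = 4)
  lab <- lab[-1, ]
  se <- unitResponseTable(matrix(rnorm(2 * nrow(lab)), 2), lab)
  expect_error(screenSelectivity(se), "unbalanced|balance")
})

test_that("pooled curves normalize to [0, 1] and peak at the preferred rank", {
  lab <- syntheticLabels(nPerCell = 8)
  specs <- data.frame(mu = c(3, 3, 2), sigma = c(0.4, 0.4, 0.3))
  se <- plantCNNUnits(lab, specs, noiseSd = 0.01, seed = 51)
  # selectivity fixed by construction: the pooling contract is under test
  scr <- data.frame(unit_id = sprintf("unit_%05d", 1:3),
                    selected = TRUE, preferred_ordinality = c(3, 3, 2))
  curves <- poolTuningCurves(se, scr)
  for (d in split(curves, curves$preferred)) {
    expect_equal(max(d$mean), 1, tolerance = 0.05)
    expect_equal(min(d$mean), 0, tolerance = 0.05)
    expect_equal(d$ordinality[which.max(d$mean)], d$preferred[1])
  }
  # two near-identical units pooled: standard errors collapse toward zero
  two <- curves[curves$preferred == 3, ]
  expect_true(all(two$se < 0.02))
  expect_equal(two$n_units[1], 2)
})

test_that("a single selected unit's pooled curve is its own normalized curve", {
  lab <- syntheticLabels(nPerCell = 8)
  se <- plantCNNUnits(lab, data.frame(mu = 2, sigma = 0.4),
                      noiseSd = 0.01, seed = 52)
  scr <- data.frame(unit_id = "unit_00001", selected = TRUE,
                    preferred_ordinality = 2)
  curves <- poolTuningCurves(se, scr)
  expect_equal(max(curves$mean), 1)
  expect_equal(min(curves$mean), 0)
  expect_equal(curves$n_units, rep(1, 5))
})

test_that("Gaussian curve fits recover exact parameters and absorb baselines", {
  x <- 1:8
  y <- 0.2 + 0.8 * exp(-(x - 3)^2 / 2)
  f <- fitCurveGaussian(y, x)
  expect_equal(f$center, 3, tolerance = 1e-6)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-4)
  f2 <- fitCurveGaussian(y + 5, x)
  expect_equal(f2$center, f$center, tolerance = 1e-6)
  expect_equal(f2$fwhm, f$fwhm, tolerance = 1e-4)
  expect_equal(f2$baseline, f$baseline + 5, tolerance = 1e-4)
})

test_that("edge and degenerate curves are flagged rather than trusted", {
  delta <- c(1, 0, 0, 0, 0)
  f <- fitCurveGaussian(delta, 1:5)
  expect_lt(abs(f$center - 1), 0.75)
  expect_lt(f$fwhm, 2)
  flat <- fitCurveGaussian(rep(0.4, 5), 1:5)
  expect_true(flat$degenerate)
  expect_error(fitCurveGaussian(c(1, 2, 3)), "length")
})

test_that("width-rank association behaves at its extremes", {
  t1 <- widthRankTau(1:5, 1:5)
  expect_equal(t1$tau, 1)
  t2 <- widthRankTau(5:1, 1:5)
  expect_equal(t2$tau, -1)
  expect_gt(t2$p, 0.5)
  expect_warning(t3 <- widthRankTau(rep(1, 4), 1:4), "tied")
  expect_equal(t3$p, 1)
})

test_that("one-tailed tau p-values are calibrated under a permutation null", {
  set.seed(61)
  ps <- vapply(1:1000, function(i) {
    widthRankTau(rnorm(15), rnorm(15))$p
  }, numeric(1))
  # the exact null distribution is discrete: P(P <= u) = u holds exactly at
  # every achievable p, so compare the empirical CDF there (99% KS band)
  for (u in sort(unique(ps)))
    expect_lt(abs(mean(ps <= u) - u), 1.63 / sqrt(1000))
})

test_that("the exact signed-rank floor for 5 folds is 1/32", {
  expect_equal(exactSignedRankP(c(0.6, 0.7, 0.55, 0.8, 0.65)), 1 / 32)
  expect_equal(round(exactSignedRankP(rep(0.54, 5)), 3), 0.031)
  expect_equal(exactSignedRankP(rep(0.5, 5)), 1)  # all at chance
  expect_lt(exactSignedRankP(c(0.4, 0.7, 0.8, 0.9, 0.6)), 0.1)
})

test_that("a separable code decodes first-vs-rest perfectly at the p floor", {
  lab <- syntheticLabels(nPerCell = 8)
  X <- matrix(rnorm(3 * nrow(lab), sd = 0.01), 3)
  X[1, ] <- X[1, ] + as.numeric(lab$ordinality == 1)
  res <- svmFirstVsRest(list(activations = X, labels = lab), seed = 2)
  expect_equal(res$foldAccuracy, rep(1, 5))
  expect_equal(res$p, 1 / 32)
})

test_that("noise features decode at chance with a calibrated test", {
  set.seed(63)
  lab <- syntheticLabels(nPerCell = 8)
  res <- t(vapply(1:200, function(i) {
    X <- matrix(rnorm(5 * nrow(lab)), 5)
    r <- svmFirstVsRest(list(activations = X, labels = lab), seed = i)
    c(r$mean, r$p)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) - 0.5), 0.03)
  expect_lte(mean(res[, 2] < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("stratification fails loudly when a class is too small", {
  lab <- syntheticLabels(nPerCell = 8)
  keep <- c(which(lab$ordinality == 1)[1:3], which(lab$ordinality != 1))
  lab2 <- lab[keep, ]
  X <- matrix(rnorm(2 * nrow(lab2)), 2)
  expect_error(svmFirstVsRest(list(activations = X, labels = lab2)),
               "stratification")
})
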