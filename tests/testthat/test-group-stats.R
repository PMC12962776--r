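test_that("a perfectly monotone width-rank relation gives rho 1 and a floor p", {
  set.seed(1)
  po <- sort(runif(100, 1, 7))
  tab <- data.frame(preferred_ordinality = po,
                    fwhm = 0.5 + po * 1.2,
                    upsampling_group = sprintf("g%03d", 1:100))
  res <- widthTrendTest(tab, nPerm = 2000, seed = 3)
  expect_equal(res$rho, 1)
  expect_lte(res$p, 0.001)
  expect_gte(res$p, 1 / (res$nPerm + 1))
})

test_that("permutation p-values are calibrated under a group-level null", {
  set.seed(11)
  ps <- vapply(1:500, function(r) {
    widthTrendTest(nullRegionTable(20, 3), nPerm = 99)$p
  }, numeric(1))
  # uniformity (allowing for the 1/100 permutation lattice)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # type-I error at or below nominal, within Monte Carlo tolerance
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("group-level permutation stays valid under upsampling where site-level inflates", {
  set.seed(13)
  runBoth <- function() {
    m <- 25; k <- 5
    po <- runif(m, 1, 7); fw <- runif(m, 1, 6)
    tab <- data.frame(
      preferred_ordinality = rep(po, each = k) + rnorm(m * k, sd = 0.05),
      fwhm = rep(fw, each = k) + rnorm(m * k, sd = 0.05),
      upsampling_group = rep(sprintf("g%02d", 1:m), each = k))
    siteTab <- tab; siteTab$upsampling_group <- NULL
    c(widthTrendTest(tab, nPerm = 99)$p,
      suppressWarnings(widthTrendTest(siteTab, nPerm = 99)$p))
  }
  ps <- t(vapply(1:300, function(r) runBoth(), numeric(2)))
  groupRate <- mean(ps[, 1] <= 0.05)
  siteRate <- mean(ps[, 2] <= 0.05)
  tol <- 2 * sqrt(0.05 * 0.95 / 300)
  expect_lte(groupRate, 0.05 + tol)
  expect_gt(siteRate, 0.10)  # replication without group blocking inflates
})

test_that("missing upsampling groups fall back to site level with a warning", {
  tab <- nullRegionTable(10, 2)
  tab$upsampling_group <- NULL
  expect_warning(widthTrendTest(tab, nPerm = 49), "site level")
})

test_that("trend test input contracts are enforced", {
  expect_error(widthTrendTest(nullRegionTable(10, 1)[0, ], nPerm = 9), "empty")
  tab <- data.frame(preferred_ordinality = c(1, 1, 2), fwhm = 1:3,
                    upsampling_group = c("a", "b", "c"), region = "parietal")
  expect_error(widthTrendTest(tab, region = "parietal"), "3 distinct")
})

test_that("coverage fractions follow the binning conventions", {
  tab <- data.frame(preferred_ordinality = rep(1, 10))
  expect_equal(unname(coverageByRank(tab)), c(1, rep(0, 6)))
  # 3.5 falls in bin 3 under half-open [3, 4); 7 in the closed last bin
  tab2 <- data.frame(preferred_ordinality = c(3.5, 7, 6.999))
  cov <- coverageByRank(tab2)
  expect_equal(unname(cov[c("rank3", "rank6", "rank7")]), c(1, 1, 1) / 3)
})

test_that("uniform preferences give near-uniform coverage, invariant to duplication", {
  set.seed(7)
  tab <- data.frame(preferred_ordinality = sample(1:7, 700, replace = TRUE))
  cov <- coverageByRank(tab)
  expect_equal(sum(cov), 1)
  # binomial tolerance: 4 sd of a 1/7 proportion at n = 700
  expect_true(all(abs(cov - 1 / 7) < 4 * sqrt((1 / 7) * (6 / 7) / 700)))
  dup <- tab[rep(seq_len(nrow(tab)), each = 3), , drop = FALSE]
  expect_equal(coverageByRank(dup), cov)
})

test_that("identical conditions give perfect per-cluster agreement", {
  set.seed(15)
  fits <- data.frame(site_id = sprintf("s%03d", 1:60), mu = runif(60, 1, 7))
  clus <- data.frame(site_id = fits$site_id,
                     cluster_id = rep(sprintf("c%d", 1:6), each = 10))
  res <- conditionAgreement(fits, fits, clus)
  expect_equal(res$r, rep(1, 6), tolerance = 1e-12)
  expect_true(all(res$significant))
})

test_that("Benjamini-Hochberg adjustment matches a hand-computed oracle", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  # step-up: adj_i = min_{j >= i} p_(j) * n / j, computed by hand
  handAdj <- c(min(0.01 * 4 / 1, 0.02 * 4 / 2, 0.04 * 4 / 3, 0.5),
               min(0.02 * 4 / 2, 0.04 * 4 / 3, 0.5),
               min(0.04 * 4 / 3, 0.5),
               0.5)
  expect_equal(p.adjust(p, "BH"), handAdj)
  # at q = 0.05 the first two survive (0.04 <= 0.05 < 0.0533)
  expect_equal(handAdj < 0.05, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("agreement stays calibrated for independent preferences", {
  set.seed(17)
  frac <- vapply(1:300, function(r) {
    ids <- sprintf("s%03d", 1:72)
    fA <- data.frame(site_id = ids, mu = runif(72, 1, 7))
    fB <- data.frame(site_id = ids, mu = runif(72, 1, 7))
    clus <- data.frame(site_id = ids,
                       cluster_id = rep(sprintf("c%02d", 1:12), each = 6))
    mean(conditionAgreement(fA, fB, clus)$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 2 * sqrt(0.05 * 0.95 / (300 * 12)))
})

test_that("small clusters are skipped with a warning", {
  fits <- data.frame(site_id = sprintf("s%d", 1:8), mu = runif(8, 1, 7))
  clus <- data.frame(site_id = fits$site_id,
                     cluster_id = c(rep("big", 6), "tiny", "tiny2"))
  expect_warning(res <- conditionAgreement(fits, fits, clus), "skipped")
  expect_equal(res$cluster_id, "big")
})
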