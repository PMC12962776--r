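# Independent oracles used across tests. These deliberately avoid the
# vectorized code paths of the package: the brute-force fitter loops over
# candidates one at a time through predictBold(), and the convolution oracle
# is a plain O(n^2) sum.

bruteForceFit <- function(y, design, hrf, grid) {
  best <- NULL
  ord <- order(grid$sigma, grid$mu)
  for (i in ord) {
    tun <- logGaussianTuning(grid$mu[i], grid$sigma[i])
    pred <- predictBold(design, tun, hrf)
    if (sd(pred) < 1e-12) next
    r <- cor(y, pred)
    if (!is.finite(r) || r < 0) next          # nonnegative-gain constraint
    if (is.null(best) || r > best$r + 1e-12)
      best <- list(mu = grid$mu[i], sigma = grid$sigma[i], r = r)
  }
  best
}

directConvolve <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (l in seq_len(min(t, length(kernel))))
      out[t] <- out[t] + x[t - l + 1] * kernel[l]
  }
  out
}

# a small candidate grid that still strictly contains the presented range
smallGrid <- function(nMu = 24, nSigma = 12)
  defaultPRFGrid(muRange = c(0.8, 20), nMu = nMu,
                 sigmaRange = c(0.08, 2), nSigma = nSigma)

# an iid null region table with group structure
nullRegionTable <- function(nGroups = 20, k = 3) {
  data.frame(preferred_ordinality = runif(nGroups * k, 1, 7),
             fwhm = runif(nGroups * k, 1, 6),
             upsampling_group = rep(sprintf("g%03d", seq_len(nGroups)), each = k))
}

# balanced two-set label table without rendering (for screen tests)
syntheticLabels <- function(nPerCell = 16, ordinalities = 1:5) {
  g <- expand.grid(ordinality = ordinalities, set = c("straight", "irregular"),
                   rep = seq_len(nPerCell), stringsAsFactors = FALSE)
  g$image_id <- sprintf("img_%05d", seq_len(nrow(g)))
  g
}
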