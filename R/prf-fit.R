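#' Default candidate grid for the pRF search
#'
#' Preferred ordinality is log-spaced over a range that strictly contains the
#' presented ranks (and the baseline rank), so that solutions outside the
#' stimulus range -- including baseline-preferring sites -- are representable
#' and in-range estimates are not merely the best of a truncated set.
#' Log-domain width is log-spaced for finer resolution at narrow tunings.
#'
#' @param muRange range of candidate preferred ordinalities.
#' @param nMu number of preferred-ordinality candidates.
#' @param sigmaRange range of candidate log-domain widths.
#' @param nSigma number of width candidates.
#' @return data.frame with columns `mu` and `sigma`, one row per candidate.
#' @export
defaultPRFGrid <- function(muRange = c(0.9, 40), nMu = 80,
                           sigmaRange = c(0.05, 3), nSigma = 40) {
  stopifnot(muRange[1] > 0, sigmaRange[1] > 0)
  mu <- exp(seq(log(muRange[1]), log(muRange[2]), length.out = nMu))
  sigma <- exp(seq(log(sigmaRange[1]), log(sigmaRange[2]), length.out = nSigma))
  expand.grid(mu = mu, sigma = sigma, KEEP.OUT.ATTRS = FALSE)
}

# internal: per-rank regressors for a design -- the indicator time course of
# each distinct presented rank convolved with the unit-sum HRF kernel.
# Predictions for any tuning are then X %*% response(ranks).
.designRegressors <- function(design, hrf) {
  ord <- activeOrdinality(design)
  ranks <- sort(unique(ord))
  kernel <- .hrfKernelAtTR(hrf, design@trSeconds)
  X <- vapply(ranks, function(r) .causalConvolve(as.numeric(ord == r), kernel),
              numeric(length(ord)))
  list(X = X, ranks = ranks)
}

# internal: candidate response matrix (n_candidates x n_ranks)
.candidateResponses <- function(grid, ranks) {
  lr <- log(ranks)
  t(vapply(seq_len(nrow(grid)),
           function(i) exp(-(lr - log(grid$mu[i]))^2 / (2 * grid$sigma[i]^2)),
           numeric(length(ranks))))
}

#' Fit the ordinality pRF model by grid search
#'
#' For every candidate (preferred ordinality, width) pair the predicted BOLD
#' time course is formed by evaluating the log-Gaussian tuning curve at each
#' volume's presented ordinality and convolving with the HRF. The winning
#' candidate maximizes the Pearson correlation between prediction and data,
#' under a nonnegative-gain constraint (anticorrelated candidates are
#' skipped); gain and offset then follow by ordinary least squares. Ties are
#' broken toward smaller width, then smaller preferred ordinality.
#'
#' Sites whose preferred ordinality falls outside the presented rank range
#' are retained in the output but flagged not included; zero-variance series
#' are flagged degenerate with zero variance explained.
#'
#' @param series numeric vector (one site) or matrix with one row per site
#'   and one column per post-discard volume.
#' @param design the [RunDesign-class] the series were recorded under.
#' @param hrf an [HRFParams-class] or numeric kernel at the TR.
#' @param grid data.frame of candidates with columns `mu`, `sigma`; the
#'   candidate preferred ordinalities must strictly contain the presented
#'   range.
#' @param siteIds optional site identifiers.
#' @return data.frame with one row per site: `site_id`, `mu`, `sigma`,
#'   `fwhm`, `gain`, `offset`, `r2_within`, `r2_crossval` (NA until
#'   cross-validation), `included`, `degenerate`.
#' @export
fitPRFGrid <- function(series, design, hrf = canonicalHRF(),
                       grid = defaultPRFGrid(), siteIds = NULL) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  series <- as.matrix(series)
  nT <- length(activeOrdinality(design))
  if (ncol(series) != nT)
    stop(sprintf("series has %d samples per site but the post-discard design has %d volumes",
                 ncol(series), nT))
  if (nrow(grid) == 0) stop("candidate grid is empty")
  rr <- design@rankRange
  if (min(grid$mu) >= rr[1] || max(grid$mu) <= rr[2])
    stop("grid preferred-ordinality range must strictly contain the presented range")
  if (is.null(siteIds)) siteIds <- rownames(series)
  if (is.null(siteIds)) siteIds <- sprintf("site_%04d", seq_len(nrow(series)))

  # tie-break order: smaller sigma, then smaller mu, first maximum wins
  gord <- order(grid$sigma, grid$mu)
  grid <- grid[gord, , drop = FALSE]

  reg <- .designRegressors(design, hrf)
  P <- reg$X %*% t(.candidateResponses(grid, reg$ranks))   # nT x ncand
  Pm <- colMeans(P)
  Pc <- sweep(P, 2, Pm)
  sdP <- sqrt(colSums(Pc^2) / (nT - 1))
  okP <- sdP > 1e-12

  Ym <- rowMeans(series)
  Yc <- series - Ym
  sdY <- sqrt(rowSums(Yc^2) / (nT - 1))

  corr <- (Yc %*% Pc) / (nT - 1)               # nsites x ncand covariances
  corr <- sweep(corr, 2, sdP, "/")
  corr <- sweep(corr, 1, sdY, "/")
  corr[, !okP] <- -Inf
  corr[corr < 0] <- -Inf                       # gain >= 0 constraint
  corr[!is.finite(corr)] <- -Inf

  best <- max.col(corr, ties.method = "first")
  bc <- corr[cbind(seq_len(nrow(series)), best)]
  degenerate <- !is.finite(bc) | sdY <= 1e-12
  bc[degenerate] <- 0

  mu <- grid$mu[best]; sigma <- grid$sigma[best]
  gain <- ifelse(degenerate, 0, bc * sdY / sdP[best])
  offset <- Ym - gain * Pm[best]
  r2 <- bc^2
  mu[degenerate] <- NA_real_; sigma[degenerate] <- NA_real_
  included <- !degenerate & mu >= rr[1] & mu <= rr[2]

  data.frame(site_id = siteIds,
             mu = mu, sigma = sigma,
             fwhm = ifelse(degenerate, NA_real_, fwhm(mu, sigma)),
             gain = gain, offset = offset,
             r2_within = r2, r2_crossval = NA_real_,
             included = included, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Cross-condition validation of fitted pRF parameters
#'
#' Evaluates frozen tuning parameters (fitted on one stimulus condition) on
#' the time series of the complementary condition. Variance explained is the
#' squared Pearson correlation between the frozen-parameter prediction and
#' the held-out series, clipped at zero for anticorrelated predictions (gain
#' is constrained nonnegative throughout).
#'
#' @param fits data.frame from [fitPRFGrid()] for the training condition.
#' @param series held-out series, vector or matrix in the same site order.
#' @param design the held-out condition's [RunDesign-class].
#' @param hrf HRF used for the prediction.
#' @return numeric vector of cross-validated variance explained, one per site.
#' @export
crossValidate <- function(fits, series, design, hrf = canonicalHRF()) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  series <- as.matrix(series)
  nT <- length(activeOrdinality(design))
  if (ncol(series) != nT)
    stop("held-out series length does not match the held-out design")
  if (nrow(series) != nrow(fits))
    stop("fits and held-out series disagree on the number of sites")
  reg <- .designRegressors(design, hrf)
  out <- rep(NA_real_, nrow(fits))
  ok <- which(!fits$degenerate & is.finite(fits$mu))
  if (length(ok)) {
    R <- .candidateResponses(fits[ok, c("mu", "sigma")], reg$ranks)
    P <- reg$X %*% t(R)                        # nT x n_ok
    Pc <- sweep(P, 2, colMeans(P))
    Yc <- series[ok, , drop = FALSE] - rowMeans(series[ok, , drop = FALSE])
    num <- colSums(t(Yc) * Pc)
    den <- sqrt(colSums(Pc^2) * rowSums(Yc^2))
    r <- ifelse(den > 1e-12, num / den, 0)
    out[ok] <- pmax(r, 0)^2
  }
  out[fits$degenerate] <- 0
  out
}

#' Two-condition cross-validation with the inclusion rule
#'
#' Runs cross-validation in both directions (parameters from condition A
#' evaluated on condition B's series, and vice versa), averages the two
#' cross-validated variances per site, and applies the inclusion rule: a site
#' is included when its preferred ordinality lies in the presented range and
#' its averaged cross-validated variance explained reaches `threshold`.
#'
#' @param fitsA,fitsB fit tables from [fitPRFGrid()] for the two conditions,
#'   with matching `site_id` order.
#' @param seriesA,seriesB the two conditions' series matrices.
#' @param designA,designB the two conditions' designs.
#' @param hrf HRF used for predictions.
#' @param threshold minimum averaged cross-validated variance explained
#'   (default 0.20).
#' @return list with elements `fitsA` and `fitsB`, each with `r2_crossval`
#'   filled in (the per-site average over both directions) and `included`
#'   updated.
#' @export
crossValidatePair <- function(fitsA, seriesA, designA, fitsB, seriesB, designB,
                              hrf = canonicalHRF(), threshold = 0.20) {
  if (!identical(fitsA$site_id, fitsB$site_id))
    stop("the two conditions' fits must cover the same sites in the same order")
  cvA <- crossValidate(fitsA, seriesB, designB, hrf)  # A's params on B's data
  cvB <- crossValidate(fitsB, seriesA, designA, hrf)
  avg <- (cvA + cvB) / 2
  for (nm in c("fitsA", "fitsB")) {
    f <- get(nm)
    f$r2_crossval <- avg
    rr <- if (nm == "fitsA") designA@rankRange else designB@rankRange
    f$included <- !f$degenerate & is.finite(f$mu) &
      f$mu >= rr[1] & f$mu <= rr[2] & !is.na(avg) & avg >= threshold
    assign(nm, f)
  }
  list(fitsA = fitsA, fitsB = fitsB)
}
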