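#' End-to-end network ordinality analysis
#'
#' Runs the full network arm on a pair of stimulus configurations: renders
#' the straight and irregular screening sets, collects analysis-layer
#' responses, screens units for ordinality selectivity, pools tuning curves
#' of the selected units, fits a Gaussian to each pooled curve, and tests
#' whether fitted width grows with preferred rank. The pipeline is
#' weight-agnostic: with random weights it still completes, and an empty
#' selected-unit set simply yields `NULL` curve and trend results.
#'
#' @param model an [HCNN-class].
#' @param configStraight,configIrregular straight and irregular
#'   [snakeDatasetConfig()]s with equal images per (ordinality x set) cell.
#' @param alpha selectivity screen level.
#' @param verbose print forward-pass progress.
#' @return list with `responses` (unit response table), `selectivity`,
#'   `nSelected`, and -- when any unit is selected -- `curves`,
#'   `gaussianFits` (one row per pooled curve) and `widthTrend`
#'   (tau and one-tailed p), otherwise `NULL` for those elements.
#' @export
runNetworkOrdinalityAnalysis <- function(model, configStraight, configIrregular,
                                         alpha = 0.05, verbose = FALSE) {
  labS <- generateSnakeDataset(configStraight)
  labI <- generateSnakeDataset(configIrregular)
  respS <- unitResponses(model, configStraight, labS, verbose = verbose)
  respI <- unitResponses(model, configIrregular, labI, verbose = verbose)
  acts <- cbind(SummarizedExperiment::assay(respS, "activations"),
                SummarizedExperiment::assay(respI, "activations"))
  labels <- rbind(labS, labI)
  responses <- unitResponseTable(acts, labels)
  selectivity <- screenSelectivity(responses, alpha = alpha)
  out <- list(responses = responses, selectivity = selectivity,
              nSelected = sum(selectivity$selected),
              curves = NULL, gaussianFits = NULL, widthTrend = NULL)
  if (out$nSelected > 0) {
    curves <- poolTuningCurves(responses, selectivity)
    fits <- do.call(rbind, lapply(split(curves, curves$preferred), function(d) {
      f <- fitCurveGaussian(d$mean, d$ordinality)
      data.frame(preferred = d$preferred[1], center = f$center,
                 fwhm = f$fwhm, r2 = f$r2, degenerate = f$degenerate)
    }))
    rownames(fits) <- NULL
    out$curves <- curves
    out$gaussianFits <- fits
    ok <- !fits$degenerate
    if (sum(ok) >= 3 && length(unique(fits$fwhm[ok])) > 1 &&
        length(unique(fits$center[ok])) > 1)
      out$widthTrend <- widthRankTau(fits$fwhm[ok], fits$center[ok])
  }
  out
}
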