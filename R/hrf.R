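#' Canonical two-gamma HRF parameters
#'
#' Difference-of-gammas defaults in the canonical mold: a response gamma with
#' delay 6 s and dispersion 1 s (peaking near 5 s), an undershoot gamma with
#' delay 16 s and dispersion 1 s, and an undershoot one sixth the response
#' amplitude.
#'
#' @param peakDelay,undershootDelay,peakDispersion,undershootDispersion,undershootRatio
#'   see [HRFParams-class].
#' @return An [HRFParams-class] object.
#' @export
hrfParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      undershootRatio = 1 / 6) {
  new("HRFParams",
      peakDelay = peakDelay, undershootDelay = undershootDelay,
      peakDispersion = peakDispersion,
      undershootDispersion = undershootDispersion,
      undershootRatio = undershootRatio)
}

#' @rdname hrfParams
#' @export
canonicalHRF <- function() hrfParams()

#' Evaluate the two-gamma hemodynamic impulse response
#'
#' Samples the difference-of-gammas kernel
#' \deqn{h(t) = g(t; d_1/b_1, b_1) - c \, g(t; d_2/b_2, b_2)}
#' where \eqn{g} is the gamma density with the given shape and scale,
#' \eqn{d_1, d_2} the response and undershoot delays, \eqn{b_1, b_2} the
#' dispersions and \eqn{c} the undershoot ratio. The returned kernel is
#' normalized to unit peak.
#'
#' @param params an [HRFParams-class] object.
#' @param sampleRate sampling rate in Hz (e.g. `1/1.5` for TR 1.5 s).
#' @param duration kernel duration in seconds; should cover the undershoot
#'   tail (default 32 s).
#' @return numeric vector of kernel samples at times `0, 1/sampleRate, ...`.
#' @examples
#' h <- twoGammaHRF(canonicalHRF(), sampleRate = 10)
#' (which.max(h) - 1) / 10  # peak time near 5 s
#' @export
twoGammaHRF <- function(params, sampleRate, duration = 32) {
  stopifnot(sampleRate > 0)
  validObject(params)
  if (duration < 24)
    warning("duration below 24 s may truncate the undershoot tail")
  t <- seq(0, duration, by = 1 / sampleRate)
  h <- dgamma(t, shape = params@peakDelay / params@peakDispersion,
              scale = params@peakDispersion) -
    params@undershootRatio *
      dgamma(t, shape = params@undershootDelay / params@undershootDispersion,
             scale = params@undershootDispersion)
  h / max(h)
}

setMethod("show", "HRFParams", function(object) {
  cat(sprintf(paste0("HRFParams: response delay %.3g s (dispersion %.3g s), ",
                     "undershoot delay %.3g s (dispersion %.3g s), ratio %.3g\n"),
              object@peakDelay, object@peakDispersion,
              object@undershootDelay, object@undershootDispersion,
              object@undershootRatio))
})

# internal: resolve an HRF argument (params object or numeric kernel) to a
# kernel sampled at the design's TR, rescaled to unit sum so that convolution
# preserves steady-state amplitude (gain is then the asymptotic response to a
# sustained unit neural drive)
.hrfKernelAtTR <- function(hrf, trSeconds, duration = 32) {
  k <- if (is(hrf, "HRFParams")) twoGammaHRF(hrf, 1 / trSeconds, duration) else as.numeric(hrf)
  s <- sum(k)
  if (abs(s) < 1e-12) stop("HRF kernel integrates to ~0; cannot normalize")
  k / s
}

#' Predict a BOLD time course from a run design and a tuning function
#'
#' Computes the neural drive as the tuning-curve amplitude at each post-discard
#' volume's presented ordinality, convolves it causally with the hemodynamic
#' kernel sampled at the TR, and applies gain and offset. The kernel is
#' rescaled internally to unit sum, so under a sustained presentation of the
#' preferred rank the prediction settles at `offset + gain`.
#'
#' @param design a [RunDesign-class].
#' @param tuning a [LogGaussianTuning-class].
#' @param hrf an [HRFParams-class] or a numeric kernel already sampled at the
#'   design's TR.
#' @param gain nonnegative response amplitude.
#' @param offset additive baseline.
#' @return numeric vector, one value per post-discard volume.
#' @export
predictBold <- function(design, tuning, hrf = canonicalHRF(), gain = 1, offset = 0) {
  ord <- activeOrdinality(design)
  drive <- logGaussianResponse(ord, tuning@mu, tuning@sigma)
  kernel <- .hrfKernelAtTR(hrf, design@trSeconds)
  offset + gain * .causalConvolve(drive, kernel)
}

# causal discrete convolution, truncated to the input length
.causalConvolve <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out
}
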