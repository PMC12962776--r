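#' @import methods
#' @importFrom stats cor cor.test dgamma median optim p.adjust pf quantile
#'   rnorm runif sd setNames rbeta wilcox.test predict var aggregate
#' @importFrom utils head read.csv write.csv
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Run design of an ordinality mapping experiment
#'
#' A `RunDesign` holds the TR-locked sequence of presented ordinal positions
#' for one functional run: a number of initial volumes to discard, followed by
#' `cycleCount` identical cycles in which a marker steps up through the rank
#' range, rests at the baseline position, steps back down, and rests again.
#'
#' @slot trSeconds sampling interval (repetition time) in seconds.
#' @slot nVolumes total number of volumes acquired, including discards.
#' @slot presentedOrdinality integer vector, length `nVolumes`; the rank
#'   presented during each volume (baseline volumes carry `baselineRank`).
#' @slot nDiscard number of initial volumes dropped before model fitting.
#' @slot cycleCount number of stimulus cycles after the discarded volumes.
#' @slot rankRange inclusive range of the swept (non-baseline) ranks.
#' @slot baselineRank the rank encoding the baseline position; it enters the
#'   forward model as a presented ordinality like any other rank.
#' @export
setClass("RunDesign",
  representation(
    trSeconds = "numeric",
    nVolumes = "integer",
    presentedOrdinality = "integer",
    nDiscard = "integer",
    cycleCount = "integer",
    rankRange = "integer",
    baselineRank = "integer"
  )
)

setValidity("RunDesign", function(object) {
  msg <- character(0)
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a single positive number")
  if (length(object@presentedOrdinality) != object@nVolumes)
    msg <- c(msg, "presentedOrdinality length must equal nVolumes")
  if (length(object@rankRange) != 2L || diff(object@rankRange) < 0)
    msg <- c(msg, "rankRange must be an ordered pair")
  active <- if (object@nDiscard == 0L) object@presentedOrdinality
            else object@presentedOrdinality[-seq_len(object@nDiscard)]
  if (object@cycleCount > 0L && length(active) %% object@cycleCount != 0L)
    msg <- c(msg, "post-discard length must be divisible by cycleCount")
  nb <- active[active != object@baselineRank]
  if (length(nb) && (any(nb < object@rankRange[1]) || any(nb > object@rankRange[2])))
    msg <- c(msg, "non-baseline entries must lie within rankRange")
  # each cycle: ascending block, then descending block (its exact reverse),
  # each rank held for a fixed number of volumes
  if (object@cycleCount > 0L && length(active) %% object@cycleCount == 0L) {
    cyc <- matrix(active, ncol = object@cycleCount)
    for (j in seq_len(ncol(cyc))) {
      r <- rle(cyc[, j])
      keep <- r$values != object@baselineRank
      vals <- r$values[keep]; lens <- r$lengths[keep]
      if (length(vals) > 1L) {
        if (length(unique(lens)) != 1L)
          msg <- c(msg, sprintf("cycle %d: ranks are not held for equal volume counts", j))
        half <- length(vals) / 2
        if (half != floor(half) ||
            !all(vals[seq_len(half)] == rev(vals[half + seq_len(half)])) ||
            is.unsorted(vals[seq_len(half)], strictly = TRUE))
          msg <- c(msg, sprintf("cycle %d: ranks must ascend then descend symmetrically", j))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Log-Gaussian ordinality tuning
#'
#' Tuning of a neural population to ordinal rank, modeled as a Gaussian in
#' natural-log rank: the response to rank \eqn{x} is
#' \eqn{\exp(-(\ln x - \ln\mu)^2 / (2\sigma^2))}. `mu` is the preferred
#' ordinality (linear rank units) and `sigma` the tuning width in log units;
#' the derived full width at half maximum is reported in linear rank units.
#'
#' @slot mu preferred ordinality, a positive real in rank units.
#' @slot sigma tuning width (standard deviation) in natural-log rank units.
#' @export
setClass("LogGaussianTuning",
  representation(mu = "numeric", sigma = "numeric"))

setValidity("LogGaussianTuning", function(object) {
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    return("mu must be a single positive number")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a single positive number")
  TRUE
})

#' Two-gamma hemodynamic response parameters
#'
#' Parameters of the difference-of-gammas impulse response linking neural
#' activity to the BOLD signal: a positive response lobe followed by an
#' undershoot. Delays and dispersions are in seconds; `undershootRatio` is the
#' unitless amplitude of the undershoot gamma relative to the response gamma.
#'
#' @slot peakDelay response-lobe delay (s).
#' @slot undershootDelay undershoot delay (s); must exceed `peakDelay`.
#' @slot peakDispersion response dispersion (s).
#' @slot undershootDispersion undershoot dispersion (s).
#' @slot undershootRatio relative undershoot amplitude (unitless, >= 0).
#' @export
setClass("HRFParams",
  representation(
    peakDelay = "numeric",
    undershootDelay = "numeric",
    peakDispersion = "numeric",
    undershootDispersion = "numeric",
    undershootRatio = "numeric"
  )
)

setValidity("HRFParams", function(object) {
  p <- c(object@peakDelay, object@undershootDelay,
         object@peakDispersion, object@undershootDispersion)
  if (any(!is.finite(p)) || any(p <= 0))
    return("delays and dispersions must be positive and finite")
  if (object@undershootRatio < 0)
    return("undershootRatio must be nonnegative")
  if (object@peakDelay >= object@undershootDelay)
    return("the response peak must precede the undershoot")
  TRUE
})

#' Rendering specification for a snake stimulus
#'
#' Describes one "snake" image: a chain of `nCompartments` compartments
#' (rectangles or circles) laid out either in a straight line or as a seeded
#' self-avoiding chain on a jittered grid, with a single marked compartment.
#'
#' @slot nCompartments number of compartments in the chain.
#' @slot shape compartment shape, `"rectangle"` or `"circle"`.
#' @slot layout `"straight"` or `"irregular"`.
#' @slot orientation for straight layouts, `"horizontal"` or `"vertical"`.
#' @slot spacing for straight layouts, `"spaced"` or `"uninterrupted"`.
#' @slot markerRank 1-based rank of the marked compartment along the chain.
#' @slot directionalGradient if `TRUE`, compartment fill colors vary
#'   monotonically along the chain (red to yellow), giving the snake a
#'   visible start and end.
#' @slot canvasPixels (width, height) of the output raster.
#' @slot compartmentLengths optional per-compartment lengths in pixels for the
#'   variable-length control; empty means uniform lengths.
#' @slot layoutSeed RNG seed fixing the layout; rendering is deterministic
#'   given the seed.
#' @export
setClass("SnakeRenderSpec",
  representation(
    nCompartments = "integer",
    shape = "character",
    layout = "character",
    orientation = "character",
    spacing = "character",
    markerRank = "integer",
    directionalGradient = "logical",
    canvasPixels = "integer",
    compartmentLengths = "numeric",
    layoutSeed = "integer"
  )
)

setValidity("SnakeRenderSpec", function(object) {
  msg <- character(0)
  if (object@markerRank < 1L || object@markerRank > object@nCompartments)
    msg <- c(msg, "markerRank must lie in 1..nCompartments")
  if (!object@shape %in% c("rectangle", "circle", "polygon"))
    msg <- c(msg, "shape must be 'rectangle', 'circle' or 'polygon'")
  if (!object@layout %in% c("straight", "irregular"))
    msg <- c(msg, "layout must be 'straight' or 'irregular'")
  if (length(object@canvasPixels) != 2L || any(object@canvasPixels < 32L))
    msg <- c(msg, "canvasPixels must be a (width, height) pair of at least 32")
  if (length(object@compartmentLengths) &&
      length(object@compartmentLengths) != object@nCompartments)
    msg <- c(msg, "compartmentLengths must be empty or one length per compartment")
  if (length(msg)) msg else TRUE
})

#' Hierarchical convolutional network model
#'
#' Holds the layer plan and the weight tensors of the eight-block
#' convolutional architecture used for the ordinality analyses, plus the name
#' of the layer whose unit activations are screened.
#'
#' @slot spec data.frame describing the layer stack (type, feature maps,
#'   spatial size, kernel size).
#' @slot weights named list of per-layer parameter lists.
#' @slot analysisLayer name of the layer whose post-ReLU activations form the
#'   analysis unit set.
#' @export
setClass("HCNN",
  representation(spec = "data.frame", weights = "list", analysisLayer = "character"))
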