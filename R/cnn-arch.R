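#' @useDynLib ordinalPRF, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# block plan of the eight-stage architecture: channels in/out, kernel size,
# and whether a 2x2 max pool follows (after the first five blocks only)
.blockPlan <- function() {
  data.frame(
    block = 1:8,
    inMaps = c(3, 32, 48, 96, 192, 384, 768, 768),
    outMaps = c(32, 48, 96, 192, 384, 768, 768, 768),
    kernel = c(9, 9, 7, 5, 5, 5, 5, 5),
    pool = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Layer-by-layer plan of the hierarchical convolutional network
#'
#' Eight convolutional blocks (convolution, batch normalization, ReLU), with
#' 2x2 max pooling after the first five, then adaptive average pooling and a
#' 1,000-way linear classification head. Spatial sizes follow from a 224x224
#' input with stride-1 "same" convolutions.
#'
#' @return data.frame with one row per layer: `type`, `featureMaps`,
#'   `spatial` (output side length) and `kernel`.
#' @export
defaultArchitectureSpec <- function() {
  plan <- .blockPlan()
  rows <- list(data.frame(type = "Input", featureMaps = 3, spatial = 224,
                          kernel = NA_integer_))
  side <- 224
  for (i in seq_len(nrow(plan))) {
    rows[[length(rows) + 1]] <- data.frame(type = "Conv2d",
                                           featureMaps = plan$outMaps[i],
                                           spatial = side, kernel = plan$kernel[i])
    rows[[length(rows) + 1]] <- data.frame(type = "BatchNorm2d",
                                           featureMaps = plan$outMaps[i],
                                           spatial = side, kernel = NA_integer_)
    if (plan$pool[i]) {
      side <- side / 2
      rows[[length(rows) + 1]] <- data.frame(type = "MaxPool2d",
                                             featureMaps = plan$outMaps[i],
                                             spatial = side, kernel = NA_integer_)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(type = "AdaptiveAvgPool2d",
                                         featureMaps = 768, spatial = 1,
                                         kernel = NA_integer_)
  rows[[length(rows) + 1]] <- data.frame(type = "Linear", featureMaps = 1000,
                                         spatial = 1, kernel = NA_integer_)
  do.call(rbind, rows)
}

#' Build the hierarchical convolutional network
#'
#' Instantiates the eight-block architecture with He-initialized random
#' weights (or weights loaded from a file). Batch normalization layers start
#' as the identity (unit scale, zero shift, zero running mean, unit running
#' variance), as appropriate for an untrained network evaluated in inference
#' mode. The default analysis layer is the post-ReLU activation map of the
#' last convolutional block: 768 maps x 7 x 7 = 37,632 units.
#'
#' @param seed RNG seed for the weight initialization.
#' @param weightsFile optional path to an RDS checkpoint written by
#'   [saveWeights()]; layer shapes are validated and mismatches reported.
#' @param analysisLayer name of the analysis layer (`"conv8_relu"`).
#' @return an [HCNN-class] model.
#' @examples
#' m <- buildArchitecture(seed = 1)
#' analysisUnitCount(m)  # 37632
#' @export
buildArchitecture <- function(seed = 1L, weightsFile = NULL,
                              analysisLayer = "conv8_relu") {
  plan <- .blockPlan()
  weights <- .withSeed(seed, {
    w <- list()
    for (i in seq_len(nrow(plan))) {
      fanIn <- plan$kernel[i]^2 * plan$inMaps[i]
      w[[sprintf("conv%d", i)]] <- list(
        W = matrix(rnorm(fanIn * plan$outMaps[i], sd = sqrt(2 / fanIn)),
                   fanIn, plan$outMaps[i]),
        b = numeric(plan$outMaps[i]),
        bnGamma = rep(1, plan$outMaps[i]),
        bnBeta = numeric(plan$outMaps[i]),
        bnMean = numeric(plan$outMaps[i]),
        bnVar = rep(1, plan$outMaps[i]))
    }
    w$fc <- list(W = matrix(rnorm(768 * 1000, sd = sqrt(2 / 768)), 768, 1000),
                 b = numeric(1000))
    w
  })
  model <- new("HCNN", spec = defaultArchitectureSpec(), weights = weights,
               analysisLayer = analysisLayer)
  if (!is.null(weightsFile)) model <- loadWeights(model, weightsFile)
  model
}

#' Save and load network weights
#'
#' Weights are stored as a plain named list of numeric arrays (RDS). Loading
#' validates every layer's shape against the architecture and reports all
#' offending layers at once.
#'
#' @param model an [HCNN-class].
#' @param path checkpoint file path.
#' @export
saveWeights <- function(model, path) {
  saveRDS(model@weights, path)
  invisible(path)
}

#' @rdname saveWeights
#' @export
loadWeights <- function(model, path) {
  w <- readRDS(path)
  bad <- character(0)
  for (nm in names(model@weights)) {
    if (is.null(w[[nm]])) { bad <- c(bad, nm); next }
    for (part in names(model@weights[[nm]])) {
      ref <- model@weights[[nm]][[part]]
      got <- w[[nm]][[part]]
      if (is.null(got) || !identical(dim(ref), dim(got)) ||
          length(ref) != length(got))
        bad <- c(bad, paste0(nm, "$", part))
    }
  }
  if (length(bad))
    stop("checkpoint does not match the architecture at: ",
         paste(unique(bad), collapse = ", "))
  model@weights <- w
  model
}

setMethod("show", "HCNN", function(object) {
  cat(sprintf("HCNN: 8 convolutional blocks, 1000-way head; analysis layer '%s' (%d units)\n",
              object@analysisLayer, analysisUnitCount(object)))
})

#' @rdname buildArchitecture
#' @param model an [HCNN-class].
#' @export
analysisUnitCount <- function(model) 768L * 7L * 7L

# batch norm (inference) + ReLU on an H x W x C array
.bnRelu <- function(x, layer) {
  C <- dim(x)[3]
  sc <- layer$bnGamma / sqrt(layer$bnVar + 1e-5)
  sh <- layer$bnBeta - layer$bnMean * sc
  x <- sweep(x, 3, sc, "*")
  x <- sweep(x, 3, sh, "+")
  x[x < 0] <- 0
  x
}

#' Forward pass through the network
#'
#' Runs one preprocessed image (or a batch) through the convolutional stack.
#' Returns the flattened post-ReLU analysis-layer activations, the 1,000-way
#' head scores, or every stage's output shape.
#'
#' @param model an [HCNN-class].
#' @param x a preprocessed `224 x 224 x 3` array, or `224 x 224 x 3 x N`.
#' @param output `"analysis"` (default; 37,632-vector per image),
#'   `"logits"` (length-1,000 scores) or `"shapes"` (per-stage dimensions of
#'   a single forward pass).
#' @return matrix with one column per image (`"analysis"`/`"logits"`), or a
#'   data.frame of stage shapes.
#' @export
cnnForward <- function(model, x, output = c("analysis", "logits", "shapes")) {
  output <- match.arg(output)
  if (length(dim(x)) == 4) {
    cols <- lapply(seq_len(dim(x)[4]),
                   function(i) cnnForward(model, x[, , , i], output))
    return(do.call(cbind, cols))
  }
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  plan <- .blockPlan()
  shapes <- list(data.frame(stage = "input", height = dim(x)[1],
                            width = dim(x)[2], maps = dim(x)[3]))
  for (i in seq_len(nrow(plan))) {
    lw <- model@weights[[sprintf("conv%d", i)]]
    x <- .conv2dForward(x, lw$W, lw$b, plan$kernel[i])
    x <- .bnRelu(x, lw)
    shapes[[length(shapes) + 1]] <-
      data.frame(stage = sprintf("conv%d_relu", i), height = dim(x)[1],
                 width = dim(x)[2], maps = dim(x)[3])
    if (output == "analysis" && sprintf("conv%d_relu", i) == model@analysisLayer)
      return(matrix(as.numeric(x), ncol = 1))
    if (plan$pool[i]) {
      x <- .maxPool2x2(x)
      shapes[[length(shapes) + 1]] <-
        data.frame(stage = sprintf("pool%d", i), height = dim(x)[1],
                   width = dim(x)[2], maps = dim(x)[3])
    }
  }
  if (output == "shapes") {
    pooled <- apply(x, 3, mean)
    shapes[[length(shapes) + 1]] <- data.frame(stage = "avgpool", height = 1,
                                               width = 1, maps = length(pooled))
    shapes[[length(shapes) + 1]] <- data.frame(stage = "fc", height = 1,
                                               width = 1000, maps = 1)
    return(do.call(rbind, shapes))
  }
  pooled <- apply(x, 3, mean)
  logits <- drop(crossprod(model@weights$fc$W, pooled)) + model@weights$fc$b
  matrix(logits, ncol = 1)
}

#' Analysis-layer responses of the network to a snake dataset
#'
#' Renders each image of the dataset, preprocesses it, runs the forward pass
#' and collects the analysis-layer activations into a unit x image response
#' table.
#'
#' @param model an [HCNN-class].
#' @param config a [snakeDatasetConfig()].
#' @param labels label table from [generateSnakeDataset()]; generated from
#'   `config` if omitted.
#' @param verbose print progress every 50 images.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `activations` (units x images) and the label table as column data.
#' @export
unitResponses <- function(model, config, labels = NULL, verbose = FALSE) {
  if (is.null(labels)) labels <- generateSnakeDataset(config)
  nU <- analysisUnitCount(model)
  acts <- matrix(NA_real_, nU, nrow(labels))
  for (i in seq_len(nrow(labels))) {
    img <- preprocessImages(datasetImage(config, labels, i))
    acts[, i] <- cnnForward(model, img, output = "analysis")
    if (verbose && i %% 50 == 0)
      message(sprintf("  forward pass %d / %d", i, nrow(labels)))
  }
  unitResponseTable(acts, labels)
}
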