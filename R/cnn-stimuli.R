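#' Configuration of a factorial snake-image dataset
#'
#' Describes one of the factorial stimulus sets used to probe network units:
#' straight-line snakes cross repetitions x shapes x orientations x spacings
#' x marker positions; irregular snakes cross repetitions x shapes x marker
#' positions; the variable-length control crosses repetitions x marker
#' positions with rectangle compartments of randomly drawn lengths. The
#' snakes carry no directional cue, so the ordinality of a marker at position
#' `p` in an `n`-compartment snake is `min(p, n + 1 - p)`.
#'
#' @param nCompartments compartments per snake (10, 16 or 20 in the study
#'   sets; any value >= 2 is accepted).
#' @param order `"straight"` or `"irregular"`.
#' @param shapes compartment shapes crossed into the factorial design.
#' @param orientations,spacings straight-only factors.
#' @param repetitions repetitions of each factorial cell (each with a fresh
#'   layout).
#' @param variableLengths draw per-compartment lengths uniformly from 0.5x to
#'   1.5x the base length, decorrelating chain distance from rank
#'   (rectangle-only control set).
#' @param canvasPixels raster size; default 224 x 224 so no resizing is
#'   needed downstream.
#' @param seed base seed; every image's layout seed derives from it.
#' @return a classed list describing the dataset.
#' @export
snakeDatasetConfig <- function(nCompartments = 10, order = "straight",
                               shapes = c("circle", "rectangle"),
                               orientations = c("horizontal", "vertical"),
                               spacings = c("spaced", "uninterrupted"),
                               repetitions = if (order == "straight") 5 else 20,
                               variableLengths = FALSE,
                               canvasPixels = c(224L, 224L), seed = 1L) {
  stopifnot(nCompartments >= 2, repetitions >= 1,
            order %in% c("straight", "irregular"))
  if (variableLengths) {
    order <- "irregular"
    shapes <- "rectangle"
  }
  structure(list(nCompartments = as.integer(nCompartments), order = order,
                 shapes = shapes, orientations = orientations,
                 spacings = spacings, repetitions = as.integer(repetitions),
                 variableLengths = isTRUE(variableLengths),
                 canvasPixels = as.integer(canvasPixels),
                 seed = as.integer(seed)),
            class = "SnakeDatasetConfig")
}

#' Ordinality of a marker position in an undirected snake
#'
#' With no start/end cue, rank is counted from the nearer end:
#' `min(position, nCompartments + 1 - position)`.
#'
#' @param position 1-based marker position(s) along the chain.
#' @param nCompartments chain length.
#' @return integer ordinality labels.
#' @export
ordinalityFromPosition <- function(position, nCompartments) {
  stopifnot(all(position >= 1), all(position <= nCompartments))
  as.integer(pmin(position, nCompartments + 1 - position))
}

#' Generate the label table (and optionally the images) of a snake dataset
#'
#' Expands the full factorial design of a [snakeDatasetConfig()] into one row
#' per image. Image counts are a pure function of the configuration; layout
#' randomness only affects pixel content. Each row carries a derived layout
#' seed, so any single image can be re-rendered reproducibly with
#' [datasetImage()].
#'
#' @param config a `SnakeDatasetConfig`.
#' @param images if `TRUE`, also render all images into an
#'   `H x W x 3 x N` array (memory permitting); default labels only.
#' @return data.frame with columns `image_id`, `set`, `shape`, `orientation`,
#'   `spacing`, `rep`, `position`, `ordinality`, `n_compartments`,
#'   `layout_seed`, `distance_to_marker`; when `images = TRUE`, a list with
#'   elements `labels` and `images`.
#' @export
generateSnakeDataset <- function(config, images = FALSE) {
  n <- config$nCompartments
  if (config$order == "straight") {
    g <- expand.grid(rep = seq_len(config$repetitions), shape = config$shapes,
                     orientation = config$orientations,
                     spacing = config$spacings, position = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else if (config$variableLengths) {
    g <- expand.grid(rep = seq_len(config$repetitions), shape = config$shapes,
                     position = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$orientation <- NA_character_; g$spacing <- NA_character_
  } else {
    g <- expand.grid(rep = seq_len(config$repetitions), shape = config$shapes,
                     position = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$orientation <- NA_character_; g$spacing <- NA_character_
  }
  g$set <- if (config$order == "straight") "straight" else "irregular"
  g$ordinality <- ordinalityFromPosition(g$position, n)
  g$n_compartments <- n
  g$image_id <- sprintf("%s%02d_%05d", substr(g$set, 1, 3), n, seq_len(nrow(g)))
  # layout seed: shared by all marker positions of one factorial layout cell,
  # so moving the marker does not move the snake; kept below 2^31
  cell <- as.integer(interaction(
    g$rep, g$shape,
    ifelse(is.na(g$orientation), "", g$orientation),
    ifelse(is.na(g$spacing), "", g$spacing),
    drop = TRUE, lex.order = TRUE))
  g$layout_seed <- as.integer((config$seed * 10007L + cell * 131L +
                                 config$nCompartments) %% .Machine$integer.max)
  g <- g[, c("image_id", "set", "shape", "orientation", "spacing", "rep",
             "position", "ordinality", "n_compartments", "layout_seed")]
  # chain distance from the nearer end: the geometric quantity that tracks
  # the undirected ordinality label and that the variable-length control
  # decouples from it
  g$distance_to_marker <- vapply(seq_len(nrow(g)), function(i) {
    lay <- .snakeLayout(.rowToSpec(g[i, ], config))
    p <- g$position[i]
    min(lay$distance[p], lay$distance[n] - lay$distance[p])
  }, numeric(1))
  if (!images) return(g)
  H <- config$canvasPixels[2]; W <- config$canvasPixels[1]
  arr <- array(0, dim = c(H, W, 3, nrow(g)))
  for (i in seq_len(nrow(g))) arr[, , , i] <- datasetImage(config, g, i)
  list(labels = g, images = arr)
}

# internal: the render spec of one label row
.rowToSpec <- function(row, config) {
  lens <- numeric(0)
  if (config$variableLengths) {
    # per-layout lengths, uniform in [0.5, 1.5] x base, seeded by the layout
    lens <- .withSeed(row$layout_seed + 1L,
                      runif(config$nCompartments, 0.5, 1.5))
  }
  snakeRenderSpec(nCompartments = config$nCompartments,
                  shape = row$shape,
                  layout = config$order,
                  orientation = if (is.na(row$orientation)) "horizontal" else row$orientation,
                  spacing = if (is.na(row$spacing)) "spaced" else row$spacing,
                  markerRank = row$position,
                  directionalGradient = FALSE,
                  canvasPixels = config$canvasPixels,
                  compartmentLengths = lens,
                  layoutSeed = row$layout_seed)
}

#' @rdname generateSnakeDataset
#' @param labels label table from `generateSnakeDataset`.
#' @param i row index of the image to render.
#' @export
datasetImage <- function(config, labels, i) {
  renderSnakeImage(.rowToSpec(labels[i, ], config))
}

#' Preprocess images for the network
#'
#' Resizes the shorter side to `size` (bilinear), center-crops to
#' `size x size`, and normalizes each channel with the classification
#' training set's statistics: `(x - mean) / sd` per RGB channel.
#'
#' @param img an `H x W x 3` array, or `H x W x 3 x N`.
#' @param size target spatial size (default 224).
#' @param meanRGB,sdRGB per-channel normalization statistics.
#' @return array of the same arity with spatial size `size x size`.
#' @export
preprocessImages <- function(img, size = 224,
                             meanRGB = c(0.485, 0.456, 0.406),
                             sdRGB = c(0.229, 0.224, 0.225)) {
  if (length(dim(img)) == 4) {
    out <- array(0, dim = c(size, size, 3, dim(img)[4]))
    for (i in seq_len(dim(img)[4]))
      out[, , , i] <- preprocessImages(img[, , , i], size, meanRGB, sdRGB)
    return(out)
  }
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("input must be an RGB (H x W x 3) image")
  img <- .resizeShortCrop(img, size)
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - meanRGB[ch]) / sdRGB[ch]
  img
}

#' @rdname preprocessImages
#' @export
denormalizeImages <- function(img, meanRGB = c(0.485, 0.456, 0.406),
                              sdRGB = c(0.229, 0.224, 0.225)) {
  if (length(dim(img)) == 4) {
    for (i in seq_len(dim(img)[4]))
      img[, , , i] <- denormalizeImages(img[, , , i], meanRGB, sdRGB)
    return(img)
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] * sdRGB[ch] + meanRGB[ch]
  img
}

# bilinear resize of the shorter side to `size`, then center crop
.resizeShortCrop <- function(img, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H == size && W == size) return(img)
  sc <- size / min(H, W)
  nh <- max(size, round(H * sc)); nw <- max(size, round(W * sc))
  out <- array(0, dim = c(nh, nw, 3))
  ys <- (seq_len(nh) - 0.5) * (H / nh) + 0.5
  xs <- (seq_len(nw) - 0.5) * (W / nw) + 0.5
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  for (ch in 1:3) {
    A <- img[, , ch]
    out[, , ch] <- (1 - wy) * ((A[y0, x0, drop = FALSE] * rep((1 - wx), each = nh)) +
                                 A[y0, x1, drop = FALSE] * rep(wx, each = nh)) +
      wy * (A[y1, x0, drop = FALSE] * rep((1 - wx), each = nh) +
              A[y1, x1, drop = FALSE] * rep(wx, each = nh))
  }
  oy <- floor((nh - size) / 2); ox <- floor((nw - size) / 2)
  out[oy + seq_len(size), ox + seq_len(size), , drop = FALSE]
}
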