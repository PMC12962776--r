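#' Construct a snake rendering specification
#'
#' @param nCompartments number of compartments in the chain.
#' @param shape `"rectangle"`, `"circle"` or `"polygon"` (rendered as a
#'   circular compartment).
#' @param layout `"straight"` or `"irregular"` (seeded self-avoiding chain on
#'   a jittered grid).
#' @param orientation,spacing straight-layout factors.
#' @param markerRank chain position of the marked compartment (1-based).
#' @param directionalGradient color compartments along a red-to-yellow
#'   gradient so the chain has a visible direction (the fMRI-style stimulus);
#'   otherwise compartments are white and the marker red (the network-style
#'   stimulus).
#' @param canvasPixels (width, height) of the raster.
#' @param compartmentLengths optional per-compartment lengths (pixels along
#'   the chain axis) for the variable-length control.
#' @param layoutSeed seed fixing layout randomness; rendering is
#'   deterministic given the seed.
#' @return A [SnakeRenderSpec-class].
#' @export
snakeRenderSpec <- function(nCompartments = 30, shape = "rectangle",
                            layout = "irregular", orientation = "horizontal",
                            spacing = "spaced", markerRank = 1,
                            directionalGradient = TRUE,
                            canvasPixels = c(224L, 224L),
                            compartmentLengths = numeric(0),
                            layoutSeed = 1L) {
  new("SnakeRenderSpec",
      nCompartments = as.integer(nCompartments), shape = shape,
      layout = layout, orientation = orientation, spacing = spacing,
      markerRank = as.integer(markerRank),
      directionalGradient = isTRUE(directionalGradient),
      canvasPixels = as.integer(canvasPixels),
      compartmentLengths = as.numeric(compartmentLengths),
      layoutSeed = as.integer(layoutSeed))
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# internal: compute compartment geometry for a spec. Returns a list with
# per-compartment centers (cx, cy), half-sizes (hx, hy), the draw shape and
# the cumulative chain distance from compartment 1 to each compartment.
.snakeLayout <- function(spec) {
  .withSeed(spec@layoutSeed, {
    n <- spec@nCompartments
    W <- spec@canvasPixels[1]; H <- spec@canvasPixels[2]
    if (spec@layout == "straight") {
      horiz <- spec@orientation == "horizontal"
      axisLen <- if (horiz) W else H
      margin <- 10
      slot <- (axisLen - 2 * margin) / n
      fill <- if (spec@spacing == "uninterrupted") 1 else 0.68
      lens <- if (length(spec@compartmentLengths))
        spec@compartmentLengths else rep(slot * fill, n)
      gap <- if (spec@spacing == "uninterrupted") 0 else slot * (1 - fill)
      total <- sum(lens) + gap * (n - 1)
      if (total > axisLen - 2) {  # rescale to fit the canvas
        sc <- (axisLen - 2) / total
        lens <- lens * sc; gap <- gap * sc; total <- sum(lens) + gap * (n - 1)
      }
      start <- runif(1, 1, axisLen - total - 1)
      edges <- start + cumsum(c(0, head(lens, -1) + gap))
      centers <- edges + lens / 2
      cross <- min(slot * 1.4, 24)
      crossPos <- runif(1, cross / 2 + 2, (if (horiz) H else W) - cross / 2 - 2)
      if (horiz) {
        cx <- centers; cy <- rep(crossPos, n); hx <- lens / 2; hy <- rep(cross / 2, n)
      } else {
        cy <- centers; cx <- rep(crossPos, n); hy <- lens / 2; hx <- rep(cross / 2, n)
      }
    } else if (length(spec@compartmentLengths)) {
      # irregular chain with varied compartment lengths: the grid walk fixes
      # the turn sequence, step sizes follow the compartment lengths, and the
      # whole layout is rejection-sampled to stay overlap-free
      G <- max(6L, ceiling(sqrt(n * 2.8)))
      cell <- floor(min(W, H) / G)
      L <- spec@compartmentLengths / mean(spec@compartmentLengths)
      placed <- FALSE
      for (att in seq_len(60)) {
        path <- .selfAvoidingWalk(n, G, maxAttempts = 400)
        dirs <- diff(path)
        steps <- 0.5 * cell * (L[-n] + L[-1])
        pos <- apply(rbind(c(0, 0), dirs * steps), 2, cumsum)
        half <- 0.36 * cell * L
        if (.chainOverlaps(pos, half)) next
        ext <- apply(pos, 2, range)
        span <- ext[2, ] - ext[1, ] + 2 * max(half)
        sc <- min(1, (min(W, H) - 6) / max(span))
        pos <- pos * sc; half <- half * sc
        ext <- apply(pos, 2, range)
        cx <- pos[, 1] - mean(ext[, 1]) + W / 2
        cy <- pos[, 2] - mean(ext[, 2]) + H / 2
        hx <- half; hy <- half
        placed <- TRUE
        break
      }
      if (!placed)
        stop("failed to place a non-overlapping variable-length chain")
    } else {
      # self-avoiding chain on a jittered grid
      G <- max(6L, ceiling(sqrt(n * 2.8)))
      cell <- floor(min(W, H) / G)
      path <- .selfAvoidingWalk(n, G, maxAttempts = 400)
      jit <- cell * 0.08
      cx <- (path[, 1] - 0.5) * cell + runif(n, -jit, jit) + (W - G * cell) / 2
      cy <- (path[, 2] - 0.5) * cell + runif(n, -jit, jit) + (H - G * cell) / 2
      hx <- rep(cell * 0.36, n); hy <- rep(cell * 0.36, n)
    }
    dist <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
    list(cx = cx, cy = cy, hx = hx, hy = hy, shape = spec@shape, distance = dist)
  })
}

# TRUE when any non-consecutive pair of compartments overlaps
.chainOverlaps <- function(pos, half) {
  n <- nrow(pos)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < 1.02 * (half[i] + half[j]))
        return(TRUE)
    }
  }
  FALSE
}

# random self-avoiding walk of length n on a G x G grid, with restarts
.selfAvoidingWalk <- function(n, G, maxAttempts = 400) {
  if (n > G * G) stop("grid too small for the requested chain")
  steps <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (att in seq_len(maxAttempts)) {
    pos <- matrix(NA_integer_, n, 2)
    pos[1, ] <- c(sample.int(G, 1), sample.int(G, 1))
    visited <- matrix(FALSE, G, G)
    visited[pos[1, 1], pos[1, 2]] <- TRUE
    ok <- TRUE
    for (i in seq_len(n - 1)) {
      cand <- sweep(steps, 2, pos[i, ], "+")
      keep <- cand[, 1] >= 1 & cand[, 1] <= G & cand[, 2] >= 1 & cand[, 2] <= G
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand))
        cand <- cand[!visited[cand], , drop = FALSE]
      if (!nrow(cand)) { ok <- FALSE; break }
      nxt <- cand[sample.int(nrow(cand), 1), ]
      pos[i + 1, ] <- nxt
      visited[nxt[1], nxt[2]] <- TRUE
    }
    if (ok) return(pos)
  }
  stop(sprintf("failed to place a non-self-intersecting chain after %d attempts",
               maxAttempts))
}

# fill one compartment's pixels in an H x W x 3 image array
.drawCompartment <- function(img, cx, cy, hx, hy, shape, col) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- max(1L, round(cx - hx)); x1 <- min(W, round(cx + hx))
  y0 <- max(1L, round(cy - hy)); y1 <- min(H, round(cy + hy))
  if (x1 < x0 || y1 < y0) return(img)
  if (shape == "rectangle") {
    for (ch in 1:3) img[y0:y1, x0:x1, ch] <- col[ch]
  } else {
    xs <- x0:x1; ys <- y0:y1
    mask <- outer(((ys - cy) / hy)^2, ((xs - cx) / hx)^2, "+") <= 1
    for (ch in 1:3) {
      plane <- img[ys, xs, ch]
      plane[mask] <- col[ch]
      img[ys, xs, ch] <- plane
    }
  }
  img
}

#' Render a snake stimulus image
#'
#' Rasterizes the chain described by a [SnakeRenderSpec-class] onto a gray
#' canvas. With `directionalGradient` on, compartment fills run monotonically
#' from red to yellow along the chain and the marker fills its compartment in
#' black; otherwise compartments are white and the marker red. Rendering is
#' deterministic for a fixed `layoutSeed`, and the marker occupies exactly
#' one compartment.
#'
#' @param spec a [SnakeRenderSpec-class].
#' @return an H x W x 3 numeric array in [0, 1], with attributes `geometry`
#'   (per-compartment centers and half-sizes) and `distanceToMarker`
#'   (chain distance in pixels from the first compartment to the marker).
#' @export
renderSnakeImage <- function(spec) {
  validObject(spec)
  lay <- .snakeLayout(spec)
  W <- spec@canvasPixels[1]; H <- spec@canvasPixels[2]
  img <- array(0.5, dim = c(H, W, 3))
  n <- spec@nCompartments
  if (spec@directionalGradient) {
    cols <- cbind(1, seq(0, 0.9, length.out = n), 0)  # red -> yellow
    markerCol <- c(0, 0, 0)
  } else {
    cols <- matrix(1, n, 3)
    markerCol <- c(1, 0, 0)
  }
  for (i in seq_len(n)) {
    col <- if (i == spec@markerRank) markerCol else cols[i, ]
    img <- .drawCompartment(img, lay$cx[i], lay$cy[i], lay$hx[i], lay$hy[i],
                            lay$shape, col)
  }
  attr(img, "geometry") <- lay
  attr(img, "distanceToMarker") <-
    min(lay$distance[spec@markerRank],
        lay$distance[n] - lay$distance[spec@markerRank])
  img
}

#' Write a rendered snake image to PNG
#'
#' @param img array from [renderSnakeImage()].
#' @param path output file path.
#' @export
writeSnakePNG <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
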