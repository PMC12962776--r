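#' Read and write per-site fit tables
#'
#' The fit table CSV has one row per recording site with columns `site_id`,
#' `mu`, `sigma`, `fwhm`, `gain`, `offset`, `r2_within`, `r2_crossval`,
#' `included`, `degenerate`.
#'
#' @param fits fit table from [fitPRFGrid()].
#' @param path CSV file path.
#' @export
writeFitTable <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFitTable
#' @export
readFitTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Extract site time series from a 4-D NIfTI volume
#'
#' Reads a 4-D functional volume and an optional 3-D mask and returns the
#' masked voxels' time series as a sites x time matrix, ready for
#' [fitPRFGrid()] after discarding initial volumes.
#'
#' @param path path to a 4-D NIfTI file.
#' @param maskPath optional path to a 3-D mask (nonzero voxels kept).
#' @param discard number of initial volumes to drop (match the design's
#'   `nDiscard`).
#' @return matrix with one row per voxel (named by its linear index) and one
#'   column per retained volume.
#' @export
readSiteSeriesNifti <- function(path, maskPath = NULL, discard = 0) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) != 4) stop("expected a 4-D functional volume")
  nvox <- prod(d[1:3])
  mat <- matrix(as.numeric(vol), nvox, d[4])
  keep <- if (!is.null(maskPath)) {
    mask <- RNifti::readNifti(maskPath)
    if (!identical(dim(mask)[1:3], d[1:3]))
      stop("mask dimensions do not match the functional volume")
    which(as.numeric(mask) != 0)
  } else seq_len(nvox)
  out <- mat[keep, , drop = FALSE]
  if (discard > 0) out <- out[, -seq_len(discard), drop = FALSE]
  rownames(out) <- sprintf("vox_%06d", keep)
  out
}
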