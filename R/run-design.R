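#' Build the ordinality presentation time course of a functional run
#'
#' Constructs a [RunDesign-class] from timing parameters. One cycle steps the
#' marker through the swept ranks in ascending order (each rank held for
#' `volumesPerRank` volumes), shows the baseline position for
#' `baselineSeconds`, steps back down through the ranks in descending order,
#' and shows the baseline again. `nDiscard` initial volumes (encoded as
#' baseline) precede the first cycle and are dropped before fitting.
#'
#' The default configuration is a 276 s run: TR 1.5 s, ranks 1--7 held for
#' 2 volumes each, 12 s baseline epochs at rank 15, 4 cycles of 44 volumes,
#' and 8 discarded volumes, for 184 volumes in total.
#'
#' @param trSeconds repetition time in seconds.
#' @param volumesPerRank volumes spent on each swept rank position.
#' @param baselineSeconds duration of each baseline epoch in seconds; must be
#'   an integer multiple of `trSeconds`.
#' @param cycles number of cycles per run.
#' @param nDiscard initial volumes to discard before fitting.
#' @param rankRange inclusive range of swept ranks.
#' @param baselineRank rank encoding the baseline position.
#' @param nVolumes optional expected total volume count; an error names the
#'   mismatch if the timing parameters do not produce it.
#' @return A validated [RunDesign-class] object.
#' @examples
#' d <- buildRunDesign()
#' nVolumes(d)        # 184
#' designDuration(d)  # 276 seconds
#' @export
buildRunDesign <- function(trSeconds = 1.5, volumesPerRank = 2,
                           baselineSeconds = 12, cycles = 4, nDiscard = 8,
                           rankRange = c(1L, 7L), baselineRank = 15L,
                           nVolumes = NULL) {
  stopifnot(trSeconds > 0, volumesPerRank >= 1, cycles >= 1, nDiscard >= 0)
  rankRange <- as.integer(rankRange)
  if (rankRange[2] < rankRange[1])
    stop("rank range is empty")
  baselineVolumes <- baselineSeconds / trSeconds
  if (abs(baselineVolumes - round(baselineVolumes)) > 1e-9)
    stop("baselineSeconds must be an integer number of TRs")
  baselineVolumes <- as.integer(round(baselineVolumes))
  ranks <- seq(rankRange[1], rankRange[2])
  cycle <- c(rep(ranks, each = volumesPerRank),
             rep(baselineRank, baselineVolumes),
             rep(rev(ranks), each = volumesPerRank),
             rep(baselineRank, baselineVolumes))
  total <- nDiscard + cycles * length(cycle)
  if (!is.null(nVolumes) && nVolumes != total)
    stop(sprintf(paste0("inconsistent timing: cycle length %d x %d cycles + %d ",
                        "discarded volumes = %d volumes, but nVolumes = %d"),
                 length(cycle), cycles, nDiscard, total, nVolumes))
  ord <- c(rep(as.integer(baselineRank), nDiscard), rep(cycle, cycles))
  new("RunDesign",
      trSeconds = trSeconds,
      nVolumes = as.integer(total),
      presentedOrdinality = as.integer(ord),
      nDiscard = as.integer(nDiscard),
      cycleCount = as.integer(cycles),
      rankRange = rankRange,
      baselineRank = as.integer(baselineRank))
}

#' @describeIn buildRunDesign repetition time of a design, in seconds.
#' @param design a [RunDesign-class].
#' @export
trSeconds <- function(design) design@trSeconds

#' @describeIn buildRunDesign total number of volumes, including discards.
#' @export
nVolumes <- function(design) design@nVolumes

#' @describeIn buildRunDesign full presented-ordinality sequence.
#' @export
presentedOrdinality <- function(design) design@presentedOrdinality

#' @describeIn buildRunDesign number of discarded initial volumes.
#' @export
nDiscard <- function(design) design@nDiscard

#' @describeIn buildRunDesign presented ordinality after dropping discards;
#'   this is the sequence the pRF forward model consumes.
#' @export
activeOrdinality <- function(design) {
  if (design@nDiscard == 0L) return(design@presentedOrdinality)
  design@presentedOrdinality[-seq_len(design@nDiscard)]
}

#' @describeIn buildRunDesign run duration in seconds.
#' @export
designDuration <- function(design) design@nVolumes * design@trSeconds

#' @describeIn buildRunDesign baseline rank of the design.
#' @export
baselineRank <- function(design) design@baselineRank

setMethod("show", "RunDesign", function(object) {
  cat(sprintf("RunDesign: %d volumes at TR %.3g s (%.4g s run), %d discarded, %d cycles\n",
              object@nVolumes, object@trSeconds,
              object@nVolumes * object@trSeconds,
              object@nDiscard, object@cycleCount))
  cat(sprintf("  ranks %d..%d, baseline rank %d\n",
              object@rankRange[1], object@rankRange[2], object@baselineRank))
})

#' Serialize a run design to and from JSON
#'
#' @param design a [RunDesign-class].
#' @param path file path to write to or read from.
#' @return `writeRunDesign` invisibly returns `path`; `readRunDesign` returns
#'   the reconstructed [RunDesign-class].
#' @export
writeRunDesign <- function(design, path) {
  x <- list(tr_seconds = design@trSeconds,
            n_volumes = design@nVolumes,
            n_discard = design@nDiscard,
            cycle_count = design@cycleCount,
            rank_range = design@rankRange,
            baseline_rank = design@baselineRank,
            presented_ordinality = design@presentedOrdinality)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunDesign
#' @export
readRunDesign <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RunDesign",
      trSeconds = as.numeric(x$tr_seconds),
      nVolumes = as.integer(x$n_volumes),
      presentedOrdinality = as.integer(x$presented_ordinality),
      nDiscard = as.integer(x$n_discard),
      cycleCount = as.integer(x$cycle_count),
      rankRange = as.integer(x$rank_range),
      baselineRank = as.integer(x$baseline_rank))
}
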