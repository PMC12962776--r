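#' Width-versus-rank trend test with group-level permutation
#'
#' Tests whether tuning width (FWHM) increases with preferred ordinality
#' across all included sites of a cortical region pooled over participants.
#' The statistic is the Spearman rank correlation between FWHM and preferred
#' ordinality; its one-tailed p-value comes from a permutation distribution
#' in which the FWHM values are reassigned in blocks defined by
#' `upsampling_group` (the source acquisition voxel), so that sites sharing a
#' source -- and hence sharing noise -- permute together. When the grouping
#' column is absent, sites permute individually and a warning notes the
#' anticonservative risk.
#'
#' @param table data.frame with columns `preferred_ordinality`, `fwhm` and
#'   optionally `region` and `upsampling_group`.
#' @param region optional region label to filter on.
#' @param nPerm number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list with `rho` (observed Spearman correlation), `p` (one-tailed,
#'   at least `1/(nPerm+1)`), `nPerm` and `n` (number of sites).
#' @export
widthTrendTest <- function(table, region = NULL, nPerm = 10000, seed = NULL) {
  if (!is.null(region)) table <- table[table$region == region, , drop = FALSE]
  if (nrow(table) == 0) stop("region is empty")
  if (length(unique(table$preferred_ordinality)) < 3)
    stop("need at least 3 distinct preferred-ordinality values")
  if (!is.null(seed)) set.seed(seed)

  po <- table$preferred_ordinality
  fw <- table$fwhm
  rho <- cor(po, fw, method = "spearman")

  if (is.null(table$upsampling_group) || all(is.na(table$upsampling_group))) {
    warning("no upsampling_group column: permuting at site level, which risks anticonservative p-values under upsampling")
    groups <- split(seq_len(nrow(table)), seq_len(nrow(table)))
  } else {
    groups <- split(seq_len(nrow(table)), table$upsampling_group)
  }

  rpo <- rank(po); rfw <- rank(fw)
  rpoC <- rpo - mean(rpo); rfwC <- rfw - mean(rfw)
  denom <- sqrt(sum(rpoC^2) * sum(rfwC^2))
  m <- length(groups)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    idx <- unlist(groups[sample.int(m)], use.names = FALSE)
    rp <- sum(rpoC * rfwC[idx]) / denom
    if (rp >= rho) exceed <- exceed + 1L
  }
  list(rho = rho, p = (1 + exceed) / (nPerm + 1), nPerm = nPerm, n = nrow(table))
}

#' Cortical coverage by preferred ordinality
#'
#' Fraction of a region's included recording sites whose preferred ordinality
#' falls in each of the seven rank bins. Bins are half-open, `[k, k+1)` for
#' ranks 1..6, with the last bin `[7, 7]` closed. Sites weigh equally unless
#' per-site `weights` (e.g. surface areas) are supplied.
#'
#' @param table data.frame with a `preferred_ordinality` column and
#'   optionally `participant_id` and `region`.
#' @param participant,region optional filters.
#' @param weights optional per-site nonnegative weights, matching the rows of
#'   `table` after filtering.
#' @return named numeric vector of 7 fractions summing to 1.
#' @export
coverageByRank <- function(table, participant = NULL, region = NULL,
                           weights = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(participant)) keep <- keep & table$participant_id == participant
  if (!is.null(region)) keep <- keep & table$region == region
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0) stop("no sites for that participant/region")
  po <- table$preferred_ordinality
  if (any(po < 1 | po > 7)) stop("preferred_ordinality must lie in [1, 7]")
  bin <- pmin(floor(po), 6L)           # [k, k+1) for k = 1..6, [7,7] closed
  bin[po == 7] <- 7L
  if (is.null(weights)) weights <- rep(1, nrow(table))
  stopifnot(length(weights) == nrow(table), all(weights >= 0))
  out <- vapply(1:7, function(k) sum(weights[bin == k]), numeric(1))
  setNames(out / sum(out), paste0("rank", 1:7))
}

#' Between-condition agreement of preferred ordinality
#'
#' Per-cluster Pearson correlation of preferred ordinality between the two
#' stimulus conditions over matched sites, with Benjamini-Hochberg adjustment
#' across clusters. Clusters with fewer than 3 matched sites are skipped with
#' a warning.
#'
#' @param fitsA,fitsB fit tables with `site_id` and `mu` columns (one per
#'   condition).
#' @param clusters data.frame mapping `site_id` to `cluster_id`.
#' @param alpha adjusted significance level for the flags (default 0.05).
#' @return data.frame with one row per tested cluster: `cluster_id`, `n`,
#'   `r`, `p`, `p_adj`, `significant`.
#' @export
conditionAgreement <- function(fitsA, fitsB, clusters, alpha = 0.05) {
  m <- merge(fitsA[, c("site_id", "mu")], fitsB[, c("site_id", "mu")],
             by = "site_id", suffixes = c("_A", "_B"))
  m <- merge(m, clusters, by = "site_id")
  res <- lapply(split(m, m$cluster_id), function(d) {
    if (nrow(d) < 3 || sd(d$mu_A) == 0 || sd(d$mu_B) == 0) {
      warning(sprintf("cluster %s skipped: fewer than 3 matched sites or no variance",
                      d$cluster_id[1]))
      return(NULL)
    }
    ct <- cor.test(d$mu_A, d$mu_B, method = "pearson")
    data.frame(cluster_id = d$cluster_id[1], n = nrow(d),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) stop("no cluster with enough matched sites")
  rownames(res) <- NULL
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}
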