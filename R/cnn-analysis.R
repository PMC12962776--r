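#' Assemble a unit response table
#'
#' Wraps a units x images activation matrix and its per-image labels into a
#' `SummarizedExperiment` (assay `"activations"`, labels as column data).
#'
#' @param activations numeric matrix, one row per unit, one column per image.
#' @param labels data.frame of per-image labels with at least `ordinality`
#'   and `set` columns.
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
unitResponseTable <- function(activations, labels) {
  stopifnot(ncol(activations) == nrow(labels))
  if (is.null(rownames(activations)))
    rownames(activations) <- sprintf("unit_%05d", seq_len(nrow(activations)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(activations = activations),
    colData = S4Vectors::DataFrame(labels))
}

# internal: pull (matrix, labels) out of an SE or a list(activations, labels)
.responsesParts <- function(responses) {
  if (is(responses, "SummarizedExperiment")) {
    list(Y = SummarizedExperiment::assay(responses, "activations"),
         labels = as.data.frame(SummarizedExperiment::colData(responses)))
  } else {
    list(Y = responses$activations, labels = responses$labels)
  }
}

#' Screen units for ordinality selectivity
#'
#' Runs, for every unit, a balanced two-way fixed-effects ANOVA of activation
#' on ordinality and stimulus set (with interaction), implemented directly
#' from sums of squares -- the balanced design makes the decomposition exact
#' and lets tens of thousands of units be screened in one vectorized pass.
#' A unit is selected when the ordinality main effect is significant at
#' `alpha` while neither the stimulus-set main effect nor the interaction is.
#' Units with zero activation variance are reported unselected with p = 1.
#'
#' @param responses a unit response table ([unitResponseTable()]) whose
#'   labels have equally many images in every (ordinality x set) cell, with
#'   at least 2 replicates per cell.
#' @param alpha significance level of the compound rule (default 0.05).
#' @return data.frame with one row per unit: `unit_id`, `p_ordinality`,
#'   `p_set`, `p_interaction`, `selected`, `preferred_ordinality` (argmax of
#'   the per-ordinality mean response).
#' @export
screenSelectivity <- function(responses, alpha = 0.05) {
  parts <- .responsesParts(responses)
  Y <- parts$Y; labels <- parts$labels
  ordf <- factor(labels$ordinality)
  setf <- factor(labels$set)
  a <- nlevels(ordf); b <- nlevels(setf)
  if (b < 2) stop("need at least two stimulus sets")
  tab <- table(ordf, setf)
  if (length(unique(as.vector(tab))) != 1L)
    stop("unbalanced design: image counts per (ordinality x set) cell are ",
         paste(as.vector(tab), collapse = ", "))
  n <- unique(as.vector(tab))
  if (n < 2) stop("need at least 2 replicates per (ordinality x set) cell")
  N <- ncol(Y)

  # indicator-based means, vectorized over units
  cellf <- interaction(ordf, setf, lex.order = TRUE)
  Ma <- stats::model.matrix(~ ordf - 1); Ma <- sweep(Ma, 2, colSums(Ma), "/")
  Mb <- stats::model.matrix(~ setf - 1); Mb <- sweep(Mb, 2, colSums(Mb), "/")
  Mc <- stats::model.matrix(~ cellf - 1); Mc <- sweep(Mc, 2, colSums(Mc), "/")
  grand <- rowMeans(Y)
  Amean <- Y %*% Ma
  Bmean <- Y %*% Mb
  Cmean <- Y %*% Mc

  ssA <- (n * b) * rowSums((Amean - grand)^2)
  ssB <- (n * a) * rowSums((Bmean - grand)^2)
  ssCells <- n * rowSums((Cmean - grand)^2)
  ssAB <- pmax(ssCells - ssA - ssB, 0)
  ssTot <- rowSums((Y - grand)^2)
  ssE <- pmax(ssTot - ssCells, 0)
  # zero out floating-point residue so exact effects do not masquerade as
  # significant when the residual variance is itself exactly zero
  eps <- ssTot * 1e-10
  ssA[ssA <= eps] <- 0; ssB[ssB <= eps] <- 0
  ssAB[ssAB <= eps] <- 0; ssE[ssE <= eps] <- 0

  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfE <- a * b * (n - 1)
  mse <- ssE / dfE
  pOf <- function(ss, df) {
    f <- (ss / df) / mse
    p <- pf(f, df, dfE, lower.tail = FALSE)
    p[is.nan(f)] <- 1          # 0/0: no effect, no residual -> not significant
    p[is.infinite(f) & f > 0] <- 0
    p
  }
  pA <- pOf(ssA, dfA); pB <- pOf(ssB, dfB); pAB <- pOf(ssAB, dfAB)
  flat <- ssTot <= .Machine$double.eps * N
  pA[flat] <- 1; pB[flat] <- 1; pAB[flat] <- 1

  ordLevels <- as.numeric(levels(ordf))
  pref <- ordLevels[max.col(Amean, ties.method = "first")]
  data.frame(unit_id = rownames(Y) %||% sprintf("unit_%05d", seq_len(nrow(Y))),
             p_ordinality = pA, p_set = pB, p_interaction = pAB,
             selected = pA < alpha & pB >= alpha & pAB >= alpha & !flat,
             preferred_ordinality = pref,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled tuning curves of ordinality-selective units
#'
#' Each selected unit's per-ordinality mean response is min-max scaled to
#' [0, 1]; scaled curves are then averaged within groups of units sharing the
#' same preferred ordinality.
#'
#' @param responses a unit response table.
#' @param selectivity result of [screenSelectivity()] on (a screening run of)
#'   the same units.
#' @param ordinalityLevels ordinalities at which to evaluate the curves
#'   (default: all levels present in the labels).
#' @return data.frame in long form: `preferred`, `ordinality`, `mean`, `se`,
#'   `n_units`. Groups with no selected unit are omitted.
#' @export
poolTuningCurves <- function(responses, selectivity,
                             ordinalityLevels = NULL) {
  parts <- .responsesParts(responses)
  Y <- parts$Y; labels <- parts$labels
  if (is.null(ordinalityLevels))
    ordinalityLevels <- sort(unique(labels$ordinality))
  sel <- which(selectivity$selected)
  if (!length(sel)) stop("no selected units to pool")
  ordf <- factor(labels$ordinality, levels = ordinalityLevels)
  M <- stats::model.matrix(~ ordf - 1)
  M <- sweep(M, 2, pmax(colSums(M), 1), "/")
  curves <- Y[sel, , drop = FALSE] %*% M      # n_sel x n_levels
  rng <- apply(curves, 1, function(v) diff(range(v)))
  lo <- apply(curves, 1, min)
  scaled <- (curves - lo) / ifelse(rng > 0, rng, 1)
  pref <- selectivity$preferred_ordinality[sel]
  out <- lapply(sort(unique(pref)), function(p) {
    g <- scaled[pref == p, , drop = FALSE]
    data.frame(preferred = p, ordinality = ordinalityLevels,
               mean = colMeans(g),
               se = apply(g, 2, sd) / sqrt(nrow(g)),
               n_units = nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit a Gaussian to a tuning curve on the linear rank axis
#'
#' Least-squares fit of `baseline + amplitude * exp(-(x - center)^2 /
#' (2 spread^2))` with all four parameters free. Width is reported as
#' FWHM = 2 sqrt(2 ln 2) spread. A flat curve, or a fit that fails to
#' converge, is flagged degenerate and should be excluded from downstream
#' rank-correlation analyses.
#'
#' @param y curve values over the ranks `x`.
#' @param x rank axis (default `seq_along(y)`).
#' @return list with `center`, `fwhm`, `spread`, `amplitude`, `baseline`,
#'   `r2` and `degenerate`.
#' @export
fitCurveGaussian <- function(y, x = seq_along(y)) {
  stopifnot(length(y) >= 4, length(x) == length(y))
  if (diff(range(y)) <= .Machine$double.eps * 8)
    return(list(center = NA_real_, fwhm = NA_real_, spread = NA_real_,
                amplitude = 0, baseline = mean(y), r2 = NA_real_,
                degenerate = TRUE))
  start <- list(b = min(y), A = diff(range(y)), c = x[which.max(y)], s = diff(range(x)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + A * exp(-(x - c)^2 / (2 * s^2)),
                      start = start,
                      lower = c(b = -Inf, A = 0, c = min(x) - diff(range(x)),
                                s = 1e-3),
                      upper = c(b = Inf, A = Inf, c = max(x) + diff(range(x)),
                                s = 10 * diff(range(x))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a direct Nelder-Mead least-squares search
    obj <- function(p) sum((y - (p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2))))^2)
    op <- optim(unlist(start), obj)
    p <- op$par
    resid <- obj(p)
    r2 <- 1 - resid / sum((y - mean(y))^2)
    return(list(center = p[3], fwhm = 2 * sqrt(2 * log(2)) * abs(p[4]),
                spread = abs(p[4]), amplitude = p[2], baseline = p[1],
                r2 = r2, degenerate = !is.finite(r2) || r2 < 0))
  }
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(center = unname(cf["c"]), fwhm = 2 * sqrt(2 * log(2)) * unname(abs(cf["s"])),
       spread = unname(abs(cf["s"])), amplitude = unname(cf["A"]),
       baseline = unname(cf["b"]), r2 = r2, degenerate = FALSE)
}

#' Kendall rank correlation between tuning width and preferred rank
#'
#' One-tailed test for a positive association between fitted curve widths and
#' their centers (does width grow with preferred ordinality?).
#'
#' @param widths fitted FWHM values.
#' @param centers fitted curve centers (preferred ranks).
#' @return list with `tau` and one-tailed `p`.
#' @export
widthRankTau <- function(widths, centers) {
  stopifnot(length(widths) == length(centers))
  keep <- is.finite(widths) & is.finite(centers)
  widths <- widths[keep]; centers <- centers[keep]
  if (length(widths) < 3) stop("need at least 3 (width, center) pairs")
  if (length(unique(widths)) == 1 || length(unique(centers)) == 1) {
    warning("all values tied; no rank association measurable")
    return(list(tau = NA_real_, p = 1))
  }
  ct <- suppressWarnings(
    cor.test(centers, widths, method = "kendall", alternative = "greater"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Exact one-tailed Wilcoxon signed-rank test against a location
#'
#' Enumerates all sign assignments of the (tied-rank) absolute differences,
#' so the p-value stays exact even with tied fold accuracies, where the
#' textbook null distribution does not apply and standard implementations
#' fall back to a normal approximation. With n values all above `mu` the
#' smallest attainable one-tailed p is `2^-n` (1/32 for 5 folds).
#'
#' @param x observed values (e.g. cross-validation fold accuracies).
#' @param mu null location (default 0.5).
#' @return one-tailed p-value for `x > mu`.
#' @export
exactSignedRankP <- function(x, mu = 0.5) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n > 20) {
    wt <- suppressWarnings(wilcox.test(x, mu = mu, alternative = "greater"))
    return(wt$p.value)
  }
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  mean(W >= obs)
}

#' Decode "first" versus other ordinalities from unit responses
#'
#' Stratified k-fold cross-validation of a linear support vector machine
#' (C = 1) classifying images with ordinality 1 against all other
#' ordinalities, using the responses of the selected units as features. The
#' majority "rest" class is subsampled to balance each training fold, and
#' performance is the balanced accuracy per fold. Fold accuracies are tested
#' against chance (0.5) with a one-tailed Wilcoxon signed-rank test; with 5
#' folds all beating chance the attainable floor is 1/32.
#'
#' @param responses a unit response table of a fresh (held-out) image set,
#'   restricted to the selected units by the caller (or not; any feature
#'   matrix works).
#' @param nFolds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment and subsampling.
#' @return list with `foldAccuracy`, `mean` and `p` (Wilcoxon, one-tailed).
#' @export
svmFirstVsRest <- function(responses, nFolds = 5, seed = 1L) {
  parts <- .responsesParts(responses)
  X <- t(parts$Y)                             # images x features
  y <- factor(ifelse(parts$labels$ordinality == 1, "first", "rest"),
              levels = c("first", "rest"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  .withSeed(seed, {
    folds <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < nFolds)
        stop(sprintf("stratification error: class '%s' has fewer images than folds", cl))
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    acc <- vapply(seq_len(nFolds), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      firsts <- tr[y[tr] == "first"]; rests <- tr[y[tr] == "rest"]
      rests <- sample(rests, min(length(rests), length(firsts)))
      tri <- c(firsts, rests)
      m <- e1071::svm(X[tri, , drop = FALSE], y[tri], kernel = "linear",
                      cost = 1, scale = FALSE)
      pred <- predict(m, X[te, , drop = FALSE])
      mean(vapply(levels(y), function(cl)
        mean(pred[y[te] == cl] == cl), numeric(1)))
    }, numeric(1))
    list(foldAccuracy = acc, mean = mean(acc),
         p = exactSignedRankP(acc, mu = 0.5))
  })
}
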