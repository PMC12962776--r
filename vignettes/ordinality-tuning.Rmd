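---
title: "Modeling neural tuning to ordinal position: methods and design notes"
author: "ordinalPRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural tuning to ordinal position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordinalPRF)
```

## The problem

Ordinality is the rank of an item within an ordered sequence — 1st, 2nd,
3rd — independent of what the items are. `ordinalPRF` provides two analysis
arms for asking whether neural systems carry populations *tuned* to ordinal
position:

1. an **fMRI arm**: population receptive field (pRF) modeling of BOLD time
   series recorded while a marker steps through the positions of an
   elongated "snake" stimulus, yielding per-site estimates of preferred
   ordinality and tuning width, with cross-condition validation and
   group-level statistics;
2. a **network arm**: a hierarchical convolutional network (HCNN) probed
   with factorial snake-image sets, a per-unit ANOVA selectivity screen,
   pooled tuning curves, Gaussian width fits, and SVM rank decoding.

Because raw scans are not distributed with the package, a synthetic-data
module generates ground-truth test beds for every stage; all quantitative
claims made by the test suite are claims about these simulations.

## The pRF forward model

Tuning of the neural population at one recording site is modeled as a
Gaussian over natural-log rank,

$$r(x) = \exp\!\left(-\frac{(\ln x - \ln\mu)^2}{2\sigma^2}\right),$$

with preferred ordinality $\mu$ (rank units) and log-domain width $\sigma$
(dimensionless). Width is reported as the full width at half maximum in
linear rank units, $\mathrm{FWHM} = \mu\,(e^{\sigma c} - e^{-\sigma c})$
with $c = \sqrt{2\ln 2}$; the log-Gaussian's multiplicative symmetry means a
site preferring rank 3 responds equally to ranks 1.5 and 6.

A functional run (`buildRunDesign()`) presents ranks 1–7 in an ascending
staircase (2 volumes per rank at TR 1.5 s), a 12 s baseline at the snake's
middle position (the 15th compartment), the descending staircase, and the
baseline again; four such 44-volume cycles plus 8 discarded lead-in volumes
give 184 volumes (276 s). Three modeling conventions matter:

* **Baseline epochs enter the forward model as rank 15**, not as
  stimulus-off: the baseline marker is a presented ordinality like any
  other, and the candidate grid must therefore extend beyond 15 so
  baseline-preferring solutions are representable.
* **Discarded volumes precede cycle one** and are encoded as baseline; the
  fitted series starts exactly at the first cycle.
* Sub-second flicker and the behavioral catch events do not change which
  rank is marked at each TR, so the design is coded at TR resolution.

The predicted BOLD signal is the tuning amplitude at each volume's presented
rank, convolved with a two-gamma hemodynamic response function (response
delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6 —
peaking near 5 s), scaled by a nonnegative gain plus an offset.
`twoGammaHRF()` returns a unit-peak kernel for inspection; `predictBold()`
rescales it to unit sum so that *gain equals the steady-state response to
sustained preferred-rank stimulation*, which gives gain a physical unit (%
signal change) independent of TR.

## Fitting, cross-validation, exclusion

`fitPRFGrid()` evaluates a candidate grid, by default 80 preferred
ordinalities log-spaced over [0.9, 40] × 40 widths log-spaced over
[0.05, 3] (log spacing concentrates resolution where tuning curves change
fastest; the upper $\mu$ bound exceeds the baseline rank deliberately). The
winner maximizes Pearson correlation between prediction and data — with free
gain and offset this is equivalent to least squares — under a
nonnegative-gain constraint: tuned responses are modeled as positive BOLD
modulations, so anticorrelated candidates are skipped. Ties break toward
smaller width, then smaller preferred ordinality. Zero-variance series are
flagged degenerate with zero variance explained.

`estimateHRFAndRefit()` re-estimates the five HRF parameters by bounded
nonlinear least squares (L-BFGS-B), pooling residual error over the top
quartile of sites by variance explained (with a 0.2 floor), holding tuning
parameters fixed; all sites are then refit with the new kernel. Because the
refit grid contains the previous solution, pooled residual error over the
informing sites cannot increase; if the optimizer fails the initial kernel
is kept and flagged.

`crossValidatePair()` evaluates each condition's frozen parameters on the
complementary condition's series, averages the two cross-validated variances
per site, and applies the inclusion rule: preferred ordinality inside the
presented range (1–7) *and* averaged cross-validated variance explained of
at least 0.20. Variance explained is squared correlation, clipped at zero
for anticorrelated predictions, consistent with the nonnegative-gain
convention.

## Group statistics

`widthTrendTest()` pools included sites across participants within a region
and computes the Spearman correlation between FWHM and preferred ordinality,
with a one-tailed permutation p-value (default 10,000 permutations). Because
interpolation onto an anatomical grid upsamples each acquired voxel into
several sites that share noise, sites permute *in blocks* keyed by their
source voxel (`upsampling_group`); blocks are concatenated in permuted order
and re-paired with the preferred-ordinality vector. When the grouping is
missing, site-level permutation is used and a warning marks the
anticonservative risk — the test suite demonstrates the inflation this
avoids (~5× the nominal level at a replication factor of 5).

`coverageByRank()` bins preferred ordinality into half-open intervals
$[k, k+1)$ for $k = 1..6$ and the closed bin $[7, 7]$ — a convention fixed
here because any binning must be stated to be reproducible — and divides by
the region's site count (optional per-site area weights are supported;
counts are the default). `conditionAgreement()` correlates preferred
ordinality between stimulus conditions per cluster and controls the false
discovery rate across clusters with Benjamini–Hochberg.

## The network arm

`buildArchitecture()` instantiates the eight-block convolutional stack: 32,
48, 96, 192, 384, 768, 768, 768 feature maps with 9/9/7/5/5/5/5/5 kernels,
batch normalization and ReLU per block, 2×2 max pooling after the first
five blocks (224 → 7 spatial), adaptive average pooling, and a 1,000-way
linear head. The analysis layer is the last block's post-ReLU activation
map — 768 × 7 × 7 = 37,632 units; that count identifies the layer uniquely,
and post-ReLU is the default because those are the activations the next
layer actually sees. The forward pass is implemented in single-precision
im2col + GEMM (RcppArmadillo); weights are He-initialized from a seed or
loaded from a shape-validated checkpoint. The pipeline is deliberately
weight-agnostic: every analysis runs identically on random or trained
weights, and classifier training itself is out of scope for this package.

Snake stimuli (`generateSnakeDataset()`) are white rectangle/circle chains
on gray with one red marker, 224×224 so no resizing is needed. The snakes
carry no direction cue, so ordinality is counted from the nearer end:
$\min(p,\, n+1-p)$. The factorial sets reproduce the study's counts exactly
— straight 10-compartment: 5 reps × 2 shapes × 2 orientations × 2 spacings
× 10 positions = 400 (80 per ordinality); irregular 16- and 20-compartment:
640 and 800; variable-length control: 200. Irregular layouts are seeded
self-avoiding walks on a jittered grid, rejection-sampled to stay inside
the canvas. In the variable-length control the walk's step sizes follow
per-compartment lengths drawn uniformly from 0.5–1.5× the base length
(rectangles only; a "longer circle" is a size confound). Full
decorrelation of rank from chain distance is geometrically impossible when
distance is measured from the nearer end, so the control is assessed as
*dissociation*: the same rank occurs at clearly different distances
(within-rank spread several times the fixed-length case), and the label
table reports the residual correlation.

`screenSelectivity()` runs a per-unit two-way fixed-effects ANOVA
(ordinality × stimulus set, with interaction), computed directly from sums
of squares — exact for the balanced designs the generator guarantees, and
vectorized so that 37,632 units screen in well under a second. A unit is
*ordinality-selective* when the ordinality main effect is significant at
$\alpha = 0.05$ while neither the set effect nor the interaction is. Note a
structural property of this compound rule: for a genuinely tuned unit the
two nuisance p-values are null-uniform, so ~9.75% of truly tuned units are
dropped by chance regardless of signal strength; sensitivity of the
*selection* therefore saturates near 0.90 even though the ordinality effect
itself is detected essentially always. Orientation and spacing variants are
treated as replicates within the straight set, matching the two-level set
factor.

Selected units' per-ordinality means are min–max scaled to [0, 1] and
averaged within preferred-rank groups (`poolTuningCurves()`); each pooled
curve gets a free-baseline Gaussian fit on the linear rank axis
(`fitCurveGaussian()`, Levenberg–Marquardt with a Nelder–Mead fallback;
width reported as $2\sqrt{2\ln 2}\,s$), and `widthRankTau()` tests for a
positive width–rank association with a one-tailed Kendall correlation.
`svmFirstVsRest()` decodes "first" versus all other ranks with a linear SVM
(C = 1), stratified 5-fold cross-validation, the majority class subsampled
to balance each training fold, and balanced accuracy per fold. Fold
accuracies are tested against chance with an exact sign-flip enumeration of
the Wilcoxon signed-rank statistic — standard implementations switch to a
normal approximation under ties, losing the exact floor of $2^{-5} = 1/32
\approx 0.031$ that five above-chance folds attain.

## Synthetic ground truth

`simulateSite()` draws one BOLD series as forward prediction plus white or
AR(1) noise (AR(1) offered because BOLD noise is autocorrelated; innovations
are scaled so the marginal variance matches). Noise can be given as a target
signal-to-noise variance ratio. `simulatePopulation()` draws preferred
ordinalities over [1, 7] — by default skewed toward low ranks, echoing the
empirical over-representation of early positions, or uniform — and widths
from a width law stated on the FWHM scale:
$\mathrm{FWHM} = a + b\,\mu$, inverted to $\sigma$ via
$\mathrm{asinh}$. The FWHM parameterization is deliberate: at constant
*log-domain* width, linear FWHM grows proportionally to $\mu$, so only a law
stated in FWHM units makes "slope zero" a genuine null for the width–rank
trend test. Each source site can be replicated $k$ times with shared signal
and independent noise to emulate upsampling, giving the group-permutation
machinery something real to protect against. `plantCNNUnits()` builds unit
response tables from image labels with known tuning, optional set-nuisance
terms for negative controls, and stored truth records.

## Numerical choices and edge cases

* Grid fits break exact ties toward smaller $\sigma$, then smaller $\mu$.
* Candidates whose prediction is constant (extremely broad tuning) are
  skipped as uninformative; series with zero variance are flagged
  degenerate rather than fitted.
* ANOVA sums of squares below $10^{-10}\times$ the total are zeroed so that
  floating-point residue cannot masquerade as a significant effect when the
  residual variance is itself exactly zero; dead units report p = 1.
* Permutation p-values use the add-one estimator $(1 + \#\{r^* \ge r\}) /
  (n_\mathrm{perm} + 1)$ and can never be exactly zero.
* Gaussian curve fits on 4–10 points are honest about edge effects: a curve
  peaking at the first rank fits a truncated flank, and flat or
  non-converging curves are flagged and excluded from downstream rank
  correlations.
* Image rasters are row-major top-left origin; ranks are 1-based everywhere.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
sized for a single CPU core: 100-site recovery studies at SNR 1 (median
within-condition $R^2 \approx 0.5$), 500-repeat permutation calibrations at
99 permutations each, a 2,000-unit null screen, 50-repeat power studies of
300-site populations, and an end-to-end network run on 160 images
(straight × 1 repetition + irregular × 4 repetitions, balanced at 16 images
per ordinality × set cell). Monte Carlo assertions use the nominal level
plus two binomial standard errors of the repeat count. Study-scale
quantities that depend on undeposited scans or full ImageNet training —
group correlation coefficients, the 53% mean cross-validated variance
explained, the 345 selective units, trained-network decoding accuracy — are
documented but not reproduced.

## Limitations

The simulations emulate TR-locked tuned responses with stationary white or
AR(1) noise; they do not model physiological noise spectra, motion,
partial-volume effects, or anatomical geometry, so passing tests certify
the estimator chain, not robustness to every property of real scans.
Percent-signal conversion and detrending are the caller's responsibility;
the fitter consumes series as given and applies no spatial or temporal
smoothing. Cluster definitions are input labels, not computed anatomy.
Whether condition runs are averaged before fitting is likewise the caller's
choice: the fitter accepts either pre-averaged or raw series per condition.
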