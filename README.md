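# ordinalPRF

Tools for estimating neural tuning to **ordinal position** (1st, 2nd, 3rd, …)
in two kinds of systems:

* **fMRI recordings** — a population receptive field (pRF) analysis that
  models each recording site's BOLD response to a marker stepping through the
  positions of a "snake" stimulus, and
* **convolutional networks** — a screening pipeline that finds
  ordinality-selective units in a hierarchical CNN probed with factorial
  snake-image sets.

The package is aimed at researchers studying magnitude and sequence coding
who want a fully tested, simulation-backed implementation of this analysis
chain without access to raw scans: a seeded synthetic-data module generates
ground truth for every stage.

## The model

Tuning at one recording site is a Gaussian over log rank,

    r(x) = exp( -(ln x - ln mu)^2 / (2 sigma^2) ),

with preferred ordinality `mu` and log-domain width `sigma`; width is
reported as the full width at half maximum (FWHM) in linear rank units,
`mu * (exp(sigma*sqrt(2 ln 2)) - exp(-sigma*sqrt(2 ln 2)))`. The predicted
BOLD time course is the tuning amplitude at each volume's presented rank
convolved with a two-gamma hemodynamic response function; candidate
`(mu, sigma)` pairs are grid-searched for maximal correlation with the data
under a nonnegative-gain constraint. Parameters fitted on one stimulus
condition are validated on the other; sites are included when their
preferred ordinality lies in the presented range (1–7) and the averaged
cross-validated variance explained reaches 0.20. Group statistics test
whether tuning width grows with preferred rank (Spearman correlation with
group-level permutation, respecting upsampled data points) and how cortical
coverage distributes over ranks.

The network arm builds the eight-block architecture (final convolutional
stage 768 × 7 × 7 = 37,632 analysis units), renders factorial snake sets
(400 / 640 / 800 / 200 images), screens units with a balanced two-way ANOVA
(ordinality × stimulus set; selective units show an ordinality main effect
at p < 0.05 with no set or interaction effect), pools and fits Gaussian
tuning curves, and decodes "first vs. rest" with a linear SVM under an
exact signed-rank test against chance.

## Worked example

Simulate a two-condition population with tuning width increasing in rank,
fit the pRF model, cross-validate, and test the width–rank trend:

```r
library(ordinalPRF)

design <- buildRunDesign()       # 184 volumes, TR 1.5 s, 4 cycles, 276 s
pop    <- simulatePopulation(60, design, design, snr = 1.5, k = 2, seed = 42)

fitsA <- fitPRFGrid(pop$seriesA, design)
fitsB <- fitPRFGrid(pop$seriesB, design)
cv    <- crossValidatePair(fitsA, pop$seriesA, design,
                           fitsB, pop$seriesB, design)
fits  <- cv$fitsA
head(fits[, c("site_id", "mu", "fwhm", "r2_within", "r2_crossval", "included")], 4)
#>     site_id   mu fwhm r2_within r2_crossval included
#> 1 site_0001 4.19 4.18     0.612       0.630     TRUE
#> 2 site_0002 4.39 4.38     0.656       0.616     TRUE
#> 3 site_0003 2.35 2.35     0.557       0.597     TRUE
#> 4 site_0004 2.24 2.82     0.619       0.609     TRUE

region <- regionTableFromFits(fits, pop$truth)   # 116 of 120 sites included
trend  <- widthTrendTest(region, nPerm = 1999, seed = 1)
sprintf("rho = %.3f, one-tailed p = %.4f", trend$rho, trend$p)
#> "rho = 0.834, one-tailed p = 0.0005"

round(coverageByRank(region), 3)
#> rank1 rank2 rank3 rank4 rank5 rank6 rank7
#> 0.310 0.267 0.224 0.129 0.034 0.034 0.000
```

Each row of the fit table is one recording site: `mu` is its preferred
ordinality, `fwhm` its tuning width in rank units, `r2_within` the variance
explained in-condition and `r2_crossval` the average across the two
held-out directions. The positive `rho` with a permutation p-value near the
floor recovers the planted width increase, and coverage concentrates on low
ranks, as the generator's low-skewed preference distribution dictates.

For the network arm, `buildArchitecture()` + `runNetworkOrdinalityAnalysis()`
run stimuli → forward pass → ANOVA screen → pooled curves → width–rank test
end to end on any weights (random weights are fine; the analysis is
weight-agnostic).

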