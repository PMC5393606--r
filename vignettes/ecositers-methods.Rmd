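---
title: "Methods: hyper-temporal NDVI classification of ecological sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyper-temporal NDVI classification of ecological sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and procedures: what is
computed, under which assumptions, which knobs matter, and where the design
was genuinely open.

## The problem

Ecological sites are land classes defined by soil and climate, each with a
characteristic potential plant community. The same site can occupy several
alternative stable states — from intact grassland (state code 1) or savanna
(3) through shrub invasion (4, 5) to shrubland (6) and bare/annuals (7) — so
a single-date image cannot identify the site: the vegetation seen today may
be an alternative state that resembles a different site's reference
community. A dense multi-decadal NDVI series can, because the *response* of
vegetation to wet and dry spells is modulated by soil properties. The
pipeline therefore classifies pixels by their whole filtered NDVI time
series.

## Preprocessing model

Each pixel series on a regular 16-day grid is treated as an additive
composition

    y(t) = trend(t) + seasonal(t) + remainder(t)

estimated by the LOESS-based seasonal-trend decomposition (`stl`). Choices:

* **Period = 23 steps.** One year is 365.25/16 ≈ 22.8 sixteen-day steps; the
  decomposition needs an integer period. The ~0.2 step/year drift is absorbed
  by the seasonal smoothing.
* **Seasonal window "periodic", trend window ≈ 1.5 periods** (nearest odd
  integer, 35 steps): seasonal sub-series are averaged across years; the
  trend tracks multi-year wet/dry structure without chasing the seasonal
  cycle. No authoritative values exist for these windows; these are the
  cited decomposition's standard recommendations.
* **Seasonal centring.** `stl`'s seasonal component is not exactly zero-mean;
  the package moves its cycle mean into the trend so the seasonal component
  has zero mean over each full cycle, and recomputes the remainder as
  `y - trend - seasonal`, making additivity exact to machine precision.
* **Gap infilling** is linear in time between flanking observations; leading
  and trailing gaps are constant-extended from the nearest observation,
  because linear extrapolation can leave the physical NDVI range `[-1, 1]`.
  Observed values are never altered. Missingness is carried as an explicit
  logical mask, never as a sentinel value (sentinels collide with valid NDVI
  near -1). Interpolated series are clamped to `[-1, 1]`.
* **Filtering** keeps `trend + seasonal` and discards the remainder. The
  remainder mixes sensor noise with genuine signal the smoother could not
  fit; the small information loss is accepted for the signal-to-noise gain.

Degenerate inputs: an all-missing pixel is an error naming its 0-based
(row, col); series shorter than two periods cannot be decomposed.

## Classifier

A C-classification SVM with radial-basis kernel (libsvm via e1071),
one-vs-one multiclass voting, `scale = FALSE` (all covariates are NDVI on a
common physical scale). Class weights are inversely proportional to class
frequency, normalized to mean 1, so rare classes are not swamped by the
dominant one. Hyper-parameters come from an exhaustive grid search (default
C in 2^-2..2^8, gamma in 2^-8..2^2); ties are broken toward the smallest
cost, then the smallest gamma.

Two tuning evaluations are offered. Stratified k-fold (`method = "kfold"`)
is the textbook default. `method = "lgocv"` scores each grid point by
repeated random 70/30 holdouts — the same split style the validation uses —
and is what the pipeline paths use: on easily separable data stratified folds
can score 1.0 at *every* grid point, and the smallest-(C, gamma) tie rule
then selects a point that can underfit badly on unstratified splits (class
imbalance in a random training draw biases the one-vs-one votes when the
kernel is nearly flat). Scoring with the deployment split style removes that
failure mode; the tie rule itself is retained.

**Recursive feature elimination** ranks scenes (covariates) by a one-way
F ratio — between-class over within-class variance — and repeatedly drops the
10 lowest-scoring covariates, scoring each subset by cross-validated SVM
accuracy; the best-scoring subset wins, ties toward the smaller subset. The
filter score is a deliberate design decision: no authoritative definition of
SVM covariate importance exists for this protocol, and a filter is
deterministic and fast. This is flagged as the point where a reimplementation
is most likely to diverge from other implementations.

**Validation** is leave-group-out cross-validation: `reps` random splits
holding out `round(test_frac * n)` observations (defaults 100 and 0.30),
the SVM refit on each training portion with the *frozen* tuned
hyper-parameters, and all (prediction, reference) pairs pooled into one
error matrix. A split leaving a class absent from training is redrawn (at
most 10 times, then an error). With n = 176 points this pools
100 x round(0.3 x 176) = 5300 predictions; protocols that report "50 per
iteration" with 176 points are internally inconsistent (30% of 176 is 52.8),
so the package documents its own rounding rule rather than guessing.
Tuning happens once on the full data, not inside each repetition: the
alternative (nested tuning) is defensible but much slower, and the frozen
protocol matches the sequential description of tuning followed by
validation.

## Accuracy decomposition

Error matrices are oriented rows = prediction, columns = reference (QD/AD
are orientation-symmetric; user's and producer's accuracy are not). With
cell proportions p_ij and marginals p_i+, p_+i:

* PCC = 100 Σ p_ii; UA_i = 100 p_ii / p_i+; PA_i = 100 p_ii / p_+i.
  A zero marginal makes the ratio undefined; it is reported as `NA`, never 0,
  because a silent 0 would distort class summaries (this occurs in real
  soil-survey comparisons where a class is never predicted).
* QD = ½ Σ |p_i+ − p_+i| and AD = Σ min(p_i+, p_+i) − C, with
  QD + AD = 1 − C an algebraic identity the tests assert at machine
  precision.
* Reported values round half away from zero — integer percent for
  accuracies, two decimals for QD/AD — which reproduces every published
  value recomputable from the shipped matrices. One documented wrinkle: a
  91/176 = 51.7% accuracy rounds to 52 (the value the companion text
  prints) while the source table prints 51; and the 5x5 cross-validated
  matrix sums to 4970 with trace 3108, i.e. 62.54% → 63, where the source
  prints 62. Neither PCC is asserted as exact; the QD/AD values all
  reproduce.
* The PCC confidence interval is a two-sided percentile interval over the
  per-repetition PCC values (R's default type-7 quantiles).

## Standardized precipitation index

Daily precipitation is aggregated to complete calendar months (partial
boundary months dropped). For scale k, rolling k-month accumulations are
fitted *per calendar month* with a zero-inflated gamma,
H(x) = q + (1 − q) G(x), where q is the frequency of zero accumulations and
G a gamma CDF fitted to the positive values by maximum likelihood (Thom's
closed-form approximation is the starting point and the fallback when the
MLE fails); SPI = Φ⁻¹(H). Zero is the median for that calendar month;
±1 bounds the conventional "normal" band used for transition detection (the
exceptional anchors are ±2). Design points:

* The distribution family and fitting method are a decision — the canonical
  SPI construction — not prescribed by any source table; zero inflation is
  essential in deserts where whole months are rain-free.
* At least 30 accumulation windows are required per scale, else an error:
  tail quantiles from fewer windows are unreliable. A calendar month whose
  accumulations are all zero yields undefined (NA) SPI for that month.
* A point-mass month (every accumulation identical) maps to SPI 0 exactly
  — the value *is* the median.
* Sub-monthly scales are out of scope (unreliable in monsoonal climates due
  to the zero-inflation mass).

SPI is invariant to rescaling all precipitation by a positive constant
(probability-integral-transform property) and, on long stationary records,
calibrated: mean ≈ 0, SD ≈ 1, P(SPI ≤ −2) ≈ 0.023. The tests verify both.

**Transition detection** collapses SPI into dry/normal/wet bands at ±1 and
reports months where the band changes. **Importance alignment** is an
extension, not a prescribed procedure: the mean importance rank of scenes
within a window after a transition, minus the mean rank elsewhere, with a
permutation p-value (negative statistic = post-transition scenes matter
more). It turns a qualitative visual claim into a test; its null calibration
is itself tested.

## Synthetic scenes

The generator defines the study conditions for every end-to-end test. Pixel
NDVI for class c in state s:

    NDVI(t) = b_c + A_c · m_{c,s} · S(doy_t) · [(1 − λ_c) + λ_c g(P̄_τc(t))] + ε

* `S`: truncated-cosine bump peaking at day-of-year 260 (mid/late September
  biomass peak; winter dormancy), half-width 110 days.
* `g(x) = x/(x + h_c)`: saturating response to mean daily precipitation over
  the preceding τ_c days; λ_c ∈ [0, 1] interpolates between climate-invariant
  (0) and fully climate-driven (1) phenology.
* `ε`: i.i.d. Gaussian observation noise, clipped so NDVI stays in [-1, 1].
  Default SD 0.05 (typical single-scene NDVI noise); the low-noise recovery
  experiment uses 0.02.
* Precipitation: daily Bernoulli occurrence with higher probability inside
  the 1 July–1 October monsoon window, gamma-distributed amounts, and
  multi-year regime multipliers that scale expected monthly totals; defaults
  give ≈ 250 mm/yr with ~80% in the monsoon.
* The preset encodes the qualitative orderings of the field system, not
  measured values (none are published): five classes with winter baseline
  0.13–0.17 and reference amplitudes 0.15–0.38; four grassland-reference
  classes whose amplitude multiplier falls from 1.0 (state 1) to 0.28
  (state 7), and one savanna-reference class (Deep sand) rising from 0.55
  (state 3) to 1.0 (state 6).

This construction yields the two properties the diagnostics rely on:
degraded states of *different* classes converge spectrally (small amplitudes
shrink between-class distances), while reference states stay well separated;
and wet regimes raise peak-season NDVI for every class with λ > 0. What the
generator does **not** emulate: within-(class, state) pixel heterogeneity
beyond observation noise, spatially correlated noise, mixed pixels,
topographic effects, sensor changes. Consequently a passing recovery test
shows the pipeline is correct and self-consistent, not that real scenes will
reach the same accuracy — real-data accuracy is bounded by exactly the
heterogeneity the generator omits.

## Problem sizes used by the tests

Chosen as the package's own desk-scale defaults: the full recovery
experiment uses a 64x64-pixel scene on the complete 628-step grid with 50
samples per class and 100-repetition validation (a few minutes); the
degraded-state experiment runs ten seeded 20x20 scenes on a 15-year grid;
SPI calibration uses 40-year monthly records over 20 seeds; oracle
equivalence checks run on randomized instances of a few dozen elements.

## Known limitations

* The RFE importance measure is a filter score, not an SVM-derived weight;
  rankings are comparable across runs of this package but not across
  implementations.
* TIFF stack storage is 32-bit scaled to [0, 1]; round trips are exact to
  ~1e-7 in NDVI, and NDVI exactly -1 is nudged by ~2e-6 on write (the scaled
  value 0 is the nodata sentinel).
* Tuning once on the full data slightly optimistic-biases pooled LGOCV
  accuracy relative to fully nested tuning.
* The alignment statistic treats importance ranks as exchangeable under the
  null; serial correlation in importance would make the permutation p-value
  anti-conservative.
* Percentile CIs over repetitions understate uncertainty when repetitions
  share training data (they always do in LGOCV); they are comparison aids,
  not strict coverage statements.
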