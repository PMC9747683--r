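---
title: "Presence-only niche modelling and range dynamics with maxentsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only niche modelling and range dynamics with maxentsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentsdm)
```

## The model

`maxentsdm` fits presence-background species distribution models of the
maximum-entropy (Gibbs) family. Given presence localities and a background
sample of landscape cells with covariates $x$, the model is a probability
distribution over background cells

$$q_\beta(x) \propto \exp\big(\beta^\top f(x)\big),$$

where $f$ expands the raw covariates into *feature classes*: linear (L),
quadratic (Q), pairwise products (P), forward/reverse hinges (H; piecewise
ramps at empirical background-quantile knots) and thresholds (T; step
indicators at the same knots). All features are scaled to $[0,1]$ with
bounds frozen from the combined presence + background training sample, so
projections onto new climates are well defined; values outside the training
range are clamped by default.

Fitting maximizes the L1-penalized log gain

$$G(\beta) = \overline{\beta^\top f}_{\text{presence}}
  - \ln \overline{e^{\beta^\top f}}_{\text{background}}
  - \sum_j \lambda_j |\beta_j|,$$

by cyclic coordinate descent with soft-thresholding. Each coordinate update
uses a local quadratic model (gradient = presence mean minus model
expectation of the feature, curvature = model variance) and backtracks if
the exact penalized gain would decrease, so the gain trace is
non-decreasing; convergence is declared when a full sweep improves the gain
by less than `tol` ($10^{-5}$ by default, `max_iter` 1000 sweeps). With
$\lambda = 0$ and linear features the optimum satisfies exact moment
matching (presence feature means equal model expectations) — this, a
closed-form one-feature instance, and a dense grid-search maximizer are the
independent oracles in the test suite.

The per-feature penalties default to
$\lambda_j = \mathrm{rm} \cdot \beta_{\text{class}}(m) \cdot s_j / \sqrt{m}$,
with $m$ presences, $s_j$ the presence standard deviation of feature $j$
(floored at the background standard deviation $/\sqrt{m}$), and
$\beta_{\text{class}}$ the published per-class interpolation on sample
size (linear/quadratic/product: 1.0 at $m \le 10$, 0.2 at 30, 0.05 at 100;
hinge constant 0.5; threshold 2.0 at 10 to 1.0 at 100). The regularization
multiplier `rm` scales all of them and is the main tuning knob.

Predictions are reported on three scales: `raw` (the density, normalized so
training-background raws sum to 1), and two squashes into $[0,1]$ built
from the fitted distribution's entropy $H$: the default
`cloglog` $= 1 - \exp(-e^{H}\,\mathrm{raw})$ and
`logistic` $= e^{H}\mathrm{raw}/(1 + e^{H}\mathrm{raw})$. Cloglog is the
default because it is the default output of the MaxEnt 3.4.x generation of
tools, and the classification thresholds below are conventionally applied
to it.

## The protocol

The pipeline follows the standard presence-only workflow for multi-period
projection studies:

1. **Thinning.** Occurrence records are reduced to at most one per cell of
   the 2.5-arc-minute analysis grid (first record in input order wins;
   half-open cell boundaries, a point on an east/south boundary belongs to
   the next cell). This reduces spatial pseudo-replication at exactly the
   covariate resolution.
2. **Layer preparation.** Stacks are resampled to the analysis grid
   (bilinear for continuous layers, nearest for categorical), paleoclimate
   temperature layers stored in tenths of °C are divided by 10, and slope
   and aspect are derived from elevation by Horn's 3×3 method (aspect =
   compass bearing of the downhill direction, flat cells flagged −1;
   east–west cell size scaled by cos(latitude) at 111,195 m/degree).
3. **Screening.** Pairwise Pearson correlations over the background sample
   are combined with model percent contributions: variables contributing
   >10% are protected; within each pair with $|r| \ge 0.8$ (visited in
   descending $|r|$, alphabetical tie-break) the smaller contributor is
   dropped unless protected. An `always_keep` list gives expert judgment an
   escape hatch. The procedure is a fixpoint: re-screening survivors
   removes nothing.
4. **Tuning.** A grid over rm $\times$ feature classes (conventionally
   0.5–4 by 0.5 crossed with L, LQ, LQH, H, LQHP, LQHPT) is evaluated
   under a spatial partition — quadrant blocks split at the median
   longitude/latitude for $n \ge 25$ presences, leave-one-out jackknife
   below that. Reported per combination: train/test AUC and their
   difference, the 10% training omission rate (order-statistic threshold:
   the $(\lfloor 0.1n \rfloor + 1)$-th smallest training presence score),
   the continuous Boyce index (101 windows of width 0.1), and AICc with
   $k$ = nonzero coefficients (undefined when $k \ge n-1$). Selection is
   gates-then-minimum-AICc: candidates need delta AICc < 2, test AUC > 0.9
   and CBI > 0.5; among them the smallest delta AICc wins, ties broken by
   smaller AUC difference, smaller OR10, smaller rm, fewer feature
   classes. If no combination passes the gates the same ordering is
   applied to all defined-AICc combinations and the relaxation is logged.
   The blend of rules is deliberately codified with this precedence
   because the informal practice ("lowest AICc, but also high AUC/CBI and
   low overfitting") has no canonical order; making it deterministic is
   what lets two runs agree.
5. **Projection and ensembles.** The selected configuration is refitted on
   bootstrap replicates; replicate predictions are averaged on the
   continuous scale, then projections across periods are averaged
   arithmetically over climate models (GCMs) per period — ensemble first,
   threshold second. A cell is nodata if any ensemble member is nodata, so
   all periods share one support.
6. **Range dynamics.** Continuous maps are classified at 0.1/0.3/0.5
   (half-open upward: 0.3 is moderate, 0.5 is high) and binarized at 0.5
   for dynamics (0.1 for multi-species stacking). Areas use the spherical
   band formula $R^2 \Delta\lambda (\sin\varphi_t - \sin\varphi_b)$ with
   $R = 6371$ km. Change maps partition cells into absent / stable /
   expansion / contraction; centroids are area-weighted means of
   present-cell centers with haversine shift distances and initial
   bearings; species stacks count per-cell overlaps; refugia are the
   intersection of glacial-period and current binary ranges.

## The synthetic study system

Real workflows start from global climate rasters and curated occurrence
databases; the package instead validates every stage on a generated study
system with the same statistical structure:

- `make_env_stack()` builds smooth spatial fields as sums of 25 seeded
  Gaussian bumps per layer (configurable). Smooth low-frequency fields —
  not white noise — are used so hinge features and response curves are
  meaningfully exercised; 25 bumps (rather than a handful) give each field
  enough effective degrees of freedom that independent layers show near-zero
  sample correlation. Fields are empirically whitened and mixed with the
  Cholesky factor of the target correlation matrix, so the cross-layer
  sample correlation matches the target essentially exactly, then placed on
  bioclim-plausible scales. An elevation-like layer is appended.
- `make_truth()` defines a known suitability surface as a cloglog-style
  squash of a linear, linear+quadratic, or hinge predictor in standardized
  layers, rescaled to $[0,1]$; the generating coefficients are retained.
- `sample_presences()` draws cells proportional to truth × cell area,
  emitting records at cell centers (duplicates collapse under thinning,
  like real herbarium records).
- `make_scenario_series()` derives period/GCM variants: deterministic
  per-layer offsets per period (a glacial cooling, a future warming) plus
  seeded smooth noise per GCM.

What passing tests on this system do show: the fitter recovers a known
truth (Spearman $\rho > 0.9$ between true and fitted suitability at 200
presences / 2,000 background on a 100×100 grid, with the informative
variables taking the top contribution ranks), the selection rule prefers
richer feature classes when the truth is curved, and the downstream
analytics conserve area and respond to climate shifts in the right
direction. What they do not show: robustness to sampling bias, spatial
autocorrelation structures unlike smooth bumps, real multicollinearity
patterns of bioclim variables, or extrapolation far outside training
ranges — conclusions about real data still require the usual care.

## Numerical choices and edge cases

- Convergence: tolerance $10^{-5}$ on the penalized gain per sweep;
  coordinate updates are exact soft-threshold steps with backtracking
  halving, so the gain never decreases. Separation (unbounded gain when an
  unpenalized feature perfectly splits presences from background) is caught
  by the sweep limit and flagged with a warning.
- Constant features are dropped at construction; zero-variance layers
  yield NA correlations with a warning rather than an error.
- AICc is reported as missing when $k \ge n - 1$ and such combinations are
  disqualified from selection.
- The continuous Boyce index uses 101 windows of width 0.1 (common
  practice; window parameters are configurable). Note that with fixed-width
  windows CBI is only approximately invariant under strongly distorting
  monotone transforms of the scores, and its null distribution at a few
  hundred presences is wide (sd ≈ 0.3) because adjacent windows overlap
  heavily — single null draws are noisy, so calibration checks should
  average over replicates.
- Thinning keeps the first record per cell in input order — deterministic
  and documented, since the choice affects downstream fits.
- Ties in screening (equal contributions) drop the alphabetically later
  variable; tuning ties fall through a fixed tie-break chain. Every such
  tie-break exists to make reruns reproducible.
- All randomness flows from one master seed through named sub-seeds
  (stage:species:replicate), so a pipeline rerun with the same
  configuration is byte-identical.

## Fixture scale

The package's own tests and demonstration runs use desk-scale problem
sizes chosen to exercise every code path on a single CPU: recovery tests
at a 100×100 grid with 200 presences and 2,000 background cells; the
demonstration pipeline at a 60×60 grid, 4 layers, an rm {1, 1.5, 2} ×
fc {L, LQ, LQH} grid, 3 bootstrap replicates and 2 periods × 2 GCMs.
Production analyses would raise these to the conventional 10,000
background points, 10 replicates and the full 48-combination grid via the
configuration, with no code changes.

## Known limitations

- Rasters are read and written as ESRI ASCII grids (`.asc`) in WGS84; no
  other projections or container formats, and no vector masks beyond a
  raster mask layer.
- No categorical features, bias grids, target-group background, or
  MESS-style extrapolation surfaces (clamping only).
- The spatial block partition is the standard four lat/lon-median
  quadrants; buffered leave-one-out geographic schemes are out of scope.
- Centroids average latitudes/longitudes on the sphere with area weights,
  which is adequate for subcontinental extents but not for ranges spanning
  the antimeridian.
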