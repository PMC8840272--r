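---
title: "Subregional yield prediction from vegetation health indices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subregional yield prediction from vegetation health indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vhyield` implements a four-step framework for forecasting annual crop
yields from weekly satellite vegetation health records: (1) compute the
vegetation condition index (VCI) and thermal condition index (TCI) from
gridded NDVI and brightness-temperature stacks; (2) partition the region
into subregions whose VCI/TCI vary coherently, using spatial independent
component analysis (sICA) with a split-half reproducibility rule for the
number of components; (3) build per-subregion crop-year predictor tables
and detrended yield-anomaly responses; (4) train per-subregion,
per-season machine-learning models, with and without principal-component
predictor reduction, tuned by leave-one-out cross-validation. This
vignette records the model, its assumptions, and the design decisions a
maintainer would want justified.

## 1. Condition indices

For each grid cell, the indices rescale the raw variables against their
climatological range:

$$\mathrm{VCI} = \frac{\mathrm{NDVI}-\mathrm{NDVI}_{\min}}
 {\mathrm{NDVI}_{\max}-\mathrm{NDVI}_{\min}}\times 100,\qquad
\mathrm{TCI} = \frac{\mathrm{BT}_{\max}-\mathrm{BT}}
 {\mathrm{BT}_{\max}-\mathrm{BT}_{\min}}\times 100 .$$

Both range from 0 (severe stress) to 100 (favourable conditions); the TCI
is inverted because cool conditions favour vegetation. Choices made here:

* **Extrema.** `compute_climatology()` supports extrema per cell over the
  whole record or per cell-week across years. The default is per-week
  (`per_week = TRUE`): the indices are meant to measure the *weather*
  anomaly relative to what is normal for that time of year, which is the
  climatology reading of the definition. Both conventions are exposed
  because the formulas alone do not fix one.
* **Clipping.** When an input lies outside the climatology window (as
  happens whenever the climatology and evaluation periods differ), the
  index is clipped to [0, 100], preserving the stated range.
* **Smoothing.** The operational NDVI/BT products arrive already
  noise-filtered by the provider's processing chain, whose exact filters
  are not public. `smooth_stack()` therefore provides a configurable
  moving mean/median as a generic stand-in, with default `"none"`.
* **Weeks.** Years are fixed at 52 weekly slots; a 53rd ISO week in
  incoming tabular data is folded into week 52 so that every year
  contributes the same layout.

## 2. Regionalization by spatial ICA

The centred stack is modelled as $X(t,s) = A_j(t)\,S_j(s)$: rows of $S$
are spatial source maps, as statistically independent as possible over
cells, and columns of $A$ are their temporal courses. Cells are the ICA
samples; this is the *spatial* ICA convention, appropriate here because
the scientific object is a map of zones.

**Preprocessing.** Each cell's temporal mean is removed and the data are
whitened to $j$ components in the spatial second-moment metric. Spatial
means are deliberately *not* removed: zone-like maps with disjoint
support are exactly orthogonal in second moments, but become negatively
correlated once centred over cells (the indicators of a partition sum to
one), and a centred whitening then cannot represent them — in synthetic
experiments the attainable correlation with a planted zone map drops to
about $1/\sqrt2$ the moment cell-centring is applied.

**Estimation.** The rotation is FastICA with the logcosh contrast and
symmetric decorrelation (`ica::icafast`), run to a strict tolerance
(`tol = 1e-9`): loose stopping leaves the rotation partially mixed, which
silently destroys split-half reproducibility. Because the even logcosh
contrast cannot see the *skewness* that distinguishes a zone map from a
mixture of zone maps, `fit_sica()` runs several seeded restarts and keeps
the solution with the largest Jarque–Bera-type non-Gaussianity score
(squared skewness plus a quarter of squared excess kurtosis, summed over
components). In synthetic experiments with planted zones this recovers
each planted map with correlation above 0.98 for $K = 2\ldots5$ at
signal-to-noise ratio 5. Component sign and order remain unidentifiable,
so everything downstream uses absolute correlations and label maps.

**Choosing the number of components (ICA-by-blocks).** The record is
split into two blocks — by default alternating whole years, so both
blocks keep the full seasonal cycle; interleaved weeks and contiguous
halves are available for sensitivity checks. sICA is fitted on both
blocks for $j = 1 \ldots j_{\max}$ and the components are matched across
blocks through the order-$2j$ absolute correlation matrix of the stacked
components. The default pairing is a greedy one-to-one assignment
(largest remaining cross-correlation first), which reproduces the
sort-then-select reading of the procedure while guaranteeing one match
per component; correlations whose two-sided test (with $n$ = number of
cells) is insignificant at `alpha = 0.05` are zeroed first. The p-values
ignore spatial autocorrelation, which inflates significance; that matches
how such tests are commonly used on these data and is flagged as a
limitation. Both blocks start from the same seeded rotation, and
ambiguous profiles (minimum matched correlation between 0.2 and 0.95) are
refitted from fresh rotations, keeping the best-reproducing profile:
restart variability is a nuisance for the question "do the *data*
reproduce this component?".

**Selection rule.** Components reproduce across blocks while $j$ does not
exceed the true number of sources; redundant components absorb noise and
collapse. `select_optimal_j()` returns the largest $j$ whose matched
correlations *at that j* all clear a threshold (default 0.8 — the method
only says "relatively high", so the value is configurable). A stricter
cumulative rule (all smaller $j$ must also qualify) is available but is
fragile: for $1 < j < K$ the ICA problem is under-extracted and
ill-posed, and the two blocks can legitimately settle on different
mixtures even when the profile at $j = K$ is clean. An elbow rule and an
auto-expanding $j_{\max}$ (grow until the selection is stable twice,
capped at 20) are also provided.

**Labels and subregions.** `label_cells()` assigns each cell the
component with the largest absolute standardized loading (ties to the
lowest index; the absolute value makes the rule sign-proof). Each map is
standardized by its *median* and standard deviation: ICA leaves an
arbitrary constant offset in every map, and for zone-shaped maps the
median sits on the out-of-zone baseline, so in-zone cells stand out
after the shift. Mean-centring would drag the baseline towards the zone
and let it compete with genuine loadings. The rule assumes each zone
covers less than half the cells; with exactly two equal zones the median
is ambiguous and labelling degrades (a documented limitation).
`merge_label_maps()` intersects the VCI and TCI label maps: a subregion
is a connected set of cells sharing a (VCI label, TCI label) pair;
fragments below `min_cells` are absorbed into the neighbour with the
longest shared boundary, smallest first. User-supplied overrides are
applied last, supporting agronomically motivated splits (two zones with
identical index patterns but different cultivation systems) that the
statistics alone cannot make.

## 3. Predictors, responses, splits

* **Gap filling.** A missing (year, week) value is replaced by the mean
  of that calendar week over the other years; a week missing in *all*
  years is an error.
* **Spatial averages.** Unweighted means over a subregion's valid cells
  (cells at a 4-km grid are treated as equal-area; a cosine-latitude
  weighting is available).
* **Crop years.** For a season whose harvest ends in week $w$, crop year
  $i$ runs from week $w{+}1$ of calendar year $i{-}1$ through week $w$ of
  year $i$ — 52 weekly VCI plus 52 weekly TCI values per year, ordered
  from the first week after the previous harvest. The first crop year
  therefore needs the preceding calendar year's record. Harvest weeks are
  user-supplied configuration (YAML), not inferred from data.
* **Detrending.** Annual yield decomposes as $Y_i = T_i + dY_i$: a trend
  capturing environment and technology, and a weather-driven anomaly. The
  default trend is an OLS straight line — matching the "long-term steady
  change" framing — with loess optional for slowly bending trends.
  Additivity is exact by construction.
* **Stratified split.** Anomalies are cut into `n_strata = 5` quantile
  bins and test years are drawn proportionally from each bin, so both
  tails of the anomaly distribution appear in training and test. The
  global test count is `floor(test_fraction * n)` — a 25-year series at
  20% gives 20/5, a 23-year series 19/4 — with largest-remainder
  apportionment across bins so the global count is met exactly.

## 4. Models and evaluation

Nine learners are exposed (`vh_methods()`): linear and boosted linear
regression, support vector regression with linear, quadratic, cubic and
Gaussian kernels, and single, boosted and bagged regression trees. The
default is the boosted tree, the strongest performer in the motivating
application; deep learning is deliberately out of scope for samples of
20–40 years.

* **PCA step.** With `use_pca = TRUE`, predictors are standardized and
  projected on the principal components retaining
  `variance_target = 0.95` of the variance (a fixed retained count is also
  supported). The transform is refit *inside every leave-one-out fold* —
  leakage through a shared rotation would otherwise bias the validation
  score. With full variance retained and a linear learner, predictions
  provably coincide with the no-PCA fit (rotation invariance of least
  squares), which the tests assert.
* **Tuning.** Hyperparameters are tuned by leave-one-out cross-validation
  on the training years (the natural choice at n of about 20), over small
  documented grids: boosted tree `nrounds` 50/100/200, learning rate
  0.05/0.1, depth 1/2/3; Gaussian SVR over log grids in cost and kernel
  width; all grids configurable. Grid ties resolve to the first row; all
  stochastic learners are seeded and reproducible, and per-fold seeds are
  derived from the held-out year so the score is invariant to row order.
* **Trend handling.** The trend added back at prediction time is fitted
  on the training years only and extrapolated to test years:
  $\hat Y_i = \hat T(\text{year}_i) + \widehat{dY}_i$. Tables carrying
  only an anomaly column are modelled directly with zero trend.
* **Metrics.** RMSE and MAE (tons/hectare), each optionally divided by
  the mean test yield (percent-of-mean). Model improvement is
  $(\text{RMSE}_{\text{baseline}}-\text{RMSE}_{\text{candidate}})/
  \text{RMSE}_{\text{baseline}}\times100$, used both for PCA-ML vs
  ML-only and for subregional vs one-fits-all comparisons.
* **One-fits-all baseline.** One whole-region model per season, trained
  on region-wide averaged predictors and yields, then applied to each
  subregion's test years (the subregion's own predictor rows, the
  region's trend). Whether such a baseline should instead pool
  subregional rows is ambiguous; whole-region averages are the default
  and match the framework's description, pooling can be built by passing
  a stacked table.

## 5. The synthetic generator

`synthetic_truth()` fixes a planted connected partition (seeded region
growing), per-region temporal signals, and a yield process;
`make_vh_stacks()` and `make_yields()` then generate every dataset
deterministically from the truth and its seed.

* **Temporal signals** are sums of 2–3 random-phase harmonics at 1–4
  cycles per year plus a year-level random offset (the interannual
  variability that drives yield anomalies). Signals are redrawn until all
  pairwise correlations are at most 0.2, mimicking monsoon-driven
  subregional contrasts without real data.
* **Spatial structure.** Each cell scales its region's signal by a
  sensitivity gain, uniform on 0.8–1.2. The gain serves two purposes:
  real grids never respond perfectly uniformly within a zone, and
  perfectly flat indicators make the $K=2$ case degenerate (the second
  source collapses into the constant map). With zero noise, cells of one
  region are perfectly correlated (proportional); across regions,
  temporal correlations stay at or below 0.2.
* **Noise and SNR.** Cell noise is i.i.d. Gaussian with variance equal to
  the mean region-signal variance divided by the target SNR (default 5).
  Stacks are affinely rescaled into [0, 100] with one global map, which
  leaves all correlation structure untouched.
* **Yields.** $Y_i = a + b\,i + w^\top x_i + \varepsilon_i$ with the
  weight vector supported on the last 12 weeks of each index before
  harvest, scaled so the planted anomaly has standard deviation 0.25
  t/ha around a 5 t/ha, +0.03 t/ha/yr trend, with measurement noise 0.05
  t/ha — magnitudes chosen to resemble reported seasonal rice yields.
  The generated table carries the true decomposition
  (`trend_true`, `anomaly_true`, `eps`) for parameter-recovery tests.
* **Problem sizes.** The default desk scale is a 20 x 20 grid with 25
  years of weekly data: large enough for the spatial correlation tests
  (400 cells) and for 20/5 train/test splits, small enough that the full
  acceptance suite runs in minutes.

What passing these tests shows — and does not. The generator emulates the
*statistical* structure the framework assumes: coherent zones, mutually
near-uncorrelated seasonal courses, weather-driven anomalies linearly or
nonlinearly linked to within-season indices. It does not emulate real
geography: cloud contamination, spatially correlated noise, drifting
zone boundaries, trends in the indices themselves, or non-stationary
yield technology. Success on synthetic data validates the machinery, not
the agronomic claims on any particular real region.

## 6. Numerical choices and known limitations

* FastICA: `maxit = 1000`, `tol = 1e-9`, 4 scored restarts; non-convergence
  after all restarts produces a warning, not an error.
* Zone maps are only weakly non-Gaussian when many zones have similar
  size (Bernoulli-like sources near zero excess kurtosis): occasional
  hard instances at $K = 5$ can still defeat the split-half selection,
  which is why the model-order acceptance check is framed as a success
  rate rather than a guarantee.
* Correlation p-values ignore spatial autocorrelation (anti-conservative).
* Labelling by dominant |loading| weakens when a zone covers about half
  the grid (the two-zone case), because the median baseline of the zone
  map is then ill-defined.
* The one-cell-at-a-time grid connectivity is 4-neighbour; diagonal-only
  contacts count as disconnected.
* `stratified_split` uses `floor` for the global test count; with very
  small samples this can leave a single test year.
* Degenerate inputs error early and loudly: zero climatology range at a
  used cell, weeks missing in every year, empty subregions, test splits
  that would be empty or total.
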