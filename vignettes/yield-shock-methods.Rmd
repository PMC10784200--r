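---
title: "Modelling staple-crop yield loss after a global infrastructure collapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling staple-crop yield loss after a global infrastructure collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropshock)
```

## The problem

Industrial agriculture converts fossil energy into food: synthetic nitrogen,
pesticides, diesel-driven machinery and powered irrigation together account
for a large share of modern yields of the four crops that dominate human
calorie supply — corn, rice, soybean and wheat. A global catastrophic
infrastructure loss (GCIL) — a worldwide failure of the electrical grid and
the industry that hangs off it — would remove those inputs nearly
simultaneously. `cropshock` estimates the yield consequences in two stages:
a statistical response surface linking observed yields to observed input
intensities, and a pair of counterfactual input scenarios pushed through
that surface.

This vignette records the modelling choices, their assumptions, and the
places where the design was genuinely open.

## The response model

Yields are non-negative and strongly right-skewed, so per crop we fit a
gamma GLM with natural-log link:

$$Y \sim \mathrm{Gamma}(\alpha, \theta), \qquad
  \mu = \alpha\theta, \qquad
  \ln \mu = \beta_0 + \beta_1 x_1 + \dots + \beta_p x_p$$

The predictors are total nitrogen (`n_total`, kg ha⁻¹, fertilizer plus
manure), cumulated pesticides (kg ha⁻¹), the irrigated fraction of cropland
(0–1), a binary mechanization indicator, and three dummy-coded agro-climatic
class variables (thermal regime T1–T7, moisture regime M2–M6 by length of
growing period, soil/terrain class S1–S5 + L3). The model is deliberately
plain: linear terms on the log scale, no interactions, so each coefficient
reads as a multiplicative yield effect per unit of input.

Choices worth recording:

* **Dispersion/shape.** The gamma shape is the reciprocal of the Pearson
  dispersion from the calibration fit. The shape enters the reported
  log-likelihoods and hence the pseudo-R²; a deviance-based estimate would
  shift both log-likelihoods without much moving their ratio.
* **Reference levels.** Contrasts are against T1 (tropical lowland), M2
  (growing period < 120 days) and S1 (very steep terrain). When a dataset
  happens not to contain a configured reference level, the fitter falls back
  to the best-supported level with a message — contrast interpretation
  changes, estimability does not.
* **Confidence intervals** are Wald at 95%; with the calibration sizes this
  package targets (10³–10⁴ rows) profile intervals would differ negligibly.
* **Convergence.** IRLS is allowed up to 100 iterations; heavy lognormal
  input tails can slow convergence on unclipped synthetic data.
* **Validation.** 20% of rows are held out (seeded, default split seed
  20101). Fit quality is McFadden's
  $\rho^2 = 1 - \ln L_{model}/\ln L_{null}$ evaluated on the held-out rows,
  with the null an intercept-only gamma GLM fitted on the calibration set
  and both likelihoods using the full model's calibration shape. Whether the
  null should instead be refit on the validation rows is not decidable from
  first principles; using calibration-fitted quantities for both keeps the
  comparison honest to what was learned before seeing the validation data.
  Values of 0.2–0.4 are conventionally read as an excellent fit; small
  synthetic landscapes with modest signal produce much smaller values
  without that indicating a defect.
* **Per-factor maximum effect.** The largest effect a single input can have
  is measured by predicting at the observed minimum and maximum of that
  input with everything else held fixed, expressed relative to the
  maximum-input prediction. Under the log link with no interactions this is
  $\exp(\beta_j(x_{min}-x_{max})) - 1$ and provably independent of where the
  other inputs are held — a property the test suite checks directly.

## The cleaning ledger

Raw gridded layers are harmonized into a long per-(cell, crop) table and
then cleaned in a fixed order, each step appending to a telescoping report
(rows in, removed, out):

1. **Area filter.** Cells with under 100 ha of crop-specific harvested area
   are dropped — strictly below, so a 100-ha cell survives. These slivers
   are numerous but hold a small share of production; the report records
   that share so the filter's cost is visible.
2. **Missing data.** Rows missing pesticides or mechanization are removed
   (those layers are structurally sparse and no defensible imputation model
   exists). Small gaps in fertilizer and the class layers are forward-filled
   (last observation carried forward) within each crop in `cell_id`
   (row-major grid) order; a leading gap has nothing to carry and the row is
   dropped. The traversal order is a genuine free choice — forward filling
   is order-dependent — so it is fixed, documented, and enforced by the grid
   convention (rows north→south, columns west→east).
3. **Percentile trims.** Implausibly large values are removed per crop and
   per column: above the 99.9th percentile for fertilizer N, pesticides and
   yield, above the 99th for manure. Percentiles use linear interpolation
   between order statistics; values exactly at the threshold are retained
   (strictly-above removal). Thresholds land in the report.
4. **Nitrogen merge.** `n_total = n_fert + n_manure`, computed only after
   the component trims so source-specific errors are caught first, then
   itself trimmed at the 99.9th percentile.
5. **Class merge.** The sparsely observed cold thermal codes (temperate
   cool, boreal, arctic) collapse into one level; the two driest and two
   wettest moisture codes fuse pairwise. One shared merge map for all crops
   keeps the models comparable.

Multicollinearity is screened with generalized variance inflation factors,
$GVIF_j = \det(R_j)\det(R_{-j})/\det(R)$ over the correlation matrix of the
dummy-coded design, compared across predictors via $GVIF^{1/(2\,Df)}$ whose
square is held against the usual VIF thresholds of 5 and 10. The GVIF is
computed once on the full preprocessed table per crop; a singular design
yields flagged infinities rather than an error.

## The scenarios

**Phase 1** — the first year, stocks rationed:

* Fertilizer N is cut to the global production surplus. The bookkeeping
  computes each cell's fraction of global application
  ($N_{frac} = N_{fert}A/\sum N_{fert}A$), scales the global total by
  `14477/118763` (projected 2020 surplus over projected 2020 use, ≈ 12.2%),
  and reallocates. Algebraically this is uniform scaling of every cell's
  rate; both paths are implemented and asserted equal at machine precision,
  which guards against mis-transcribing the bookkeeping.
* Pesticides are scaled by the same fraction: no production-surplus data
  exist for pesticides, and their surplus share is taken to be in the same
  range as nitrogen's (≈ 10%). In the printed form of the pesticide total
  the global pesticide production figure enters both as divisor and factor
  and cancels, so its numeric value is never needed.
* Mechanization is unchanged: diesel stocks (147000 ktoe) cover the annual
  agricultural demand (111062 ktoe) for about 1.3 years, with gasoline
  reserved for critical transport. If a user supplies fuel figures covering
  less than a year, the pipeline zeroes phase-1 mechanization and warns —
  a logged departure from the stock assumption.
* Irrigation drops to its non-electricity-reliant share,
  $I_{gcil} = I_{AC}(1 - I_{RC})$, identically in both phases.

**Phase 2** — stocks depleted: fertilizer, pesticides and mechanization are
zero. Nitrogen comes only from the manure of draft cattle kept to work the
land: `area / ha_per_head` head per cell at an excretion rate of 39.77 kg N
head⁻¹ yr⁻¹. That rate is itself derivable from published 2014 totals
(131000 kt manure N × 43.7% cattle share / 1.44 × 10⁹ head ≈ 40), a
consistency the acceptance suite recomputes. The working capacity is 5 ha
per head — deliberately conservative against the 7.4 ha typical figure,
since modern cattle are not bred for draft work; 7.4 is selectable.

**Relative change.** Per cell,
$RC = (Y_{pred} - Y_{ref})/Y_{ref}$, clipped at zero from above: a predicted
yield *increase* under collapse conditions is read as "stable", not as a
gain. The reference is the observed baseline yield by default — the
headline quantity compares the post-catastrophe prediction with what the
cell actually produced. For the identity-limit check (surplus ratios 1, no
reliant irrigation, matching manure) the reference must be the model's own
baseline prediction, since prediction error against observations never
cancels exactly; `predict_phases(reference = "predicted")` exposes that
mode. Summaries weight RC by baseline production (yield × area) and yield
by harvested area, per crop × phase × continent with global rollups. The
confidence interval on a weighted mean uses a normal approximation with
effective sample size $(\sum w)^2/\sum w^2$ — a pragmatic choice; the
interval construction for weighted means is otherwise unspecified in this
kind of analysis.

## The synthetic landscape

The generator emulates the joint structure the analysis assumes, with known
ground truth:

* yields drawn from Gamma(α, μ/α) with α = 4 (coefficient of variation
  50%) and ln μ linear in the true inputs;
* right-skewed lognormal input rates (fertilizer N around 60 kg ha⁻¹,
  manure around 15, pesticides around 1.5, each with log-sd 0.8–0.9);
* harvested areas lognormal around 800 ha with log-sd 1.5, spanning
  sub-100-ha slivers (exercising the area filter) to multi-thousand-ha
  cells;
* blocky categorical class fields (one draw per 5×5-cell block by default)
  with deliberately rare cold thermal codes, so the class-merging step has
  real work;
* missing-at-random holes in pesticides and mechanization (10% each) plus
  small forward-fillable gaps in fertilizer and classes (2%);
* multiplicative ×10–×100 outliers injected into input-rate columns at rate
  0.002 *after* yields are computed — they are measurement errors, not
  signal, which is exactly what the percentile trim assumes;
* contiguous longitudinal region bands standing in for continents.

The default effect sizes make each input worth roughly a third to a half of
yield over its observed range (e.g. 0.004 per kg N with ranges of ~150 kg,
0.5 for full irrigation, 0.45 for mechanization) — the order of magnitude
such analyses report. Every column draws from its own seeded stream, so
switching missingness on or off does not perturb the yields; the test suite
relies on this.

What the generator does *not* emulate: spatial autocorrelation beyond the
blocky classes, realistic geography, measurement error in yields, or
confounding between inputs and climate (inputs are sampled independently of
the classes). Passing tests therefore demonstrate that the machinery is
correct — cleaning does what it claims, the fitter recovers known
coefficients, the scenario algebra conserves totals — not that real-world
yield reductions equal the synthetic ones. Reproducing published global
numbers requires the real source rasters, which are out of scope here.

## Verification and problem sizes

The test suite's heavier checks and the sizes they run at, chosen to keep a
full run around half a minute on one core:

* **Coefficient recovery**: 20 seeded replicates of a 155×155-cell
  landscape (≈ 20,000 rows per crop, two crops), no outliers or
  missingness; 95% Wald intervals must cover the generating coefficients in
  at least 90% of the 800 (coefficient, replicate) pairs. Observed coverage
  is ≈ 95%, i.e. nominal. Coverage is pooled across coefficients because
  the joint event "all ~20 coefficients covered at once" has probability
  ≈ 0.95²⁰ ≈ 0.36 per replicate even for a perfect fitter, and is therefore
  not a meaningful acceptance bar.
* **Conservation and equivalence**: 100 random small landscapes; rationed
  global totals equal ratio × baseline and the reallocation path equals
  uniform scaling, both at 10⁻¹³ relative tolerance.
* **GVIF**: 50 random all-continuous designs against the auxiliary
  regression oracle $1/(1-R^2)$ at 10⁻⁸, plus a cross-check against the
  standard automotive diagnostic implementation on a categorical design.
* **Identity limit and monotonicity**: scenario machinery must return
  exactly zero weighted change when nothing is rationed, and per-cell
  phase-2 change ≤ phase-1 change whenever all fitted input coefficients
  are non-negative.

## Known limitations

* Nearest-neighbour resampling is used for all layers, including rates;
  rates are intensive (per-hectare) so nothing needs conserving, but
  area-weighted aggregation would be preferable for strongly heterogeneous
  coarse cells. No reprojection beyond lat/lon is attempted.
* Raster IO is CSV-first; single-band TIFF matrices are readable (float
  TIFFs as stored, integer TIFFs on the [0,1] TIFF convention scale), but
  layers are written as CSV only, and NetCDF is not read. Cell tables
  round-trip bit-exactly through CSV.
* The forward-fill imputation is order-dependent by construction; the
  traversal order is fixed and documented rather than optimal.
* The scenarios hold cropped area, crop choice and farmer adaptation fixed;
  no trade, storage drawdown beyond the stated stocks, or livestock
  dynamics. These are scope boundaries, not oversights.
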