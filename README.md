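# cropshock

Modern staple-crop yields depend on industrial inputs: synthetic nitrogen,
pesticides, fuel-driven machinery, and powered irrigation. A worldwide loss of
electrical infrastructure — a severe solar storm, a high-altitude
electromagnetic pulse, a cascading cyber-attack — would cut all of them off at
once. `cropshock` is an R package for quantifying what that does to yields of
corn, rice, soybean and wheat. It is aimed at food-security and
catastrophic-risk researchers who want an auditable, testable version of this
kind of gridded yield analysis.

## The model

Per-cell yields on a 5-arcmin grid are modelled per crop with a gamma GLM and
natural-log link:

    Y ~ Gamma(shape, scale),  mu = shape * scale
    ln(mu) = b0 + b1*n_total + b2*pesticides + b3*irrigation_tot
           + b4*mechanized + class effects (thermal, moisture, soil/terrain)

with dummy-coded agro-climatic classes, no interactions, an 80/20
calibration/validation split, and McFadden's rho-squared
(`1 - lnL_model / lnL_null`) on the held-out fifth as the fit measure.
Before fitting, a cleaning ledger removes cells under 100 ha of harvested
area, drops rows missing pesticide/mechanization coverage, forward-fills
small gaps in fertilizer and class layers, trims values above the 99.9th
percentile (99th for manure), merges fertilizer and manure N into `n_total`,
collapses sparse class levels, and screens the predictors with generalized
variance inflation factors.

Two counterfactual input scenarios are then pushed through the fitted
response surface:

* **Phase 1** (first year): fertilizer and pesticides rationed to the global
  production surplus (about 12% of normal use, `14477/118763` kt N);
  machinery still runs because diesel stocks (147000 ktoe) cover the annual
  agricultural fuel demand (111062 ktoe); irrigation loses its
  electricity-reliant share, `I_gcil = I_AC * (1 - I_RC)`.
* **Phase 2** (stocks depleted): fertilizer, pesticides and mechanization at
  zero. The only nitrogen left is manure from the draft cattle needed to work
  the land (`area / 5` ha per head at `39.77` kg N head⁻¹ yr⁻¹, i.e. ~7.95
  kg N ha⁻¹).

Per-cell relative change `RC = (Y_pred - Y_baseline)/Y_baseline` is clipped
at zero from above and aggregated as production-weighted means by crop,
phase and continent (yield itself is weighted by harvested area).

Because the real global source rasters (SPAM, GAEZ, PEST-CHEMGRIDS, ...) are
hundreds of megabytes, the package ships a synthetic-landscape generator
with known gamma-GLM ground truth — right-skewed input rates, blocky class
regions, missing cells, injected outliers — so every stage is testable
end-to-end offline. The pipeline accepts real data as CSV cell tables or
gridded layers if you have them.

## Worked example

```r
library(cropshock)
cfg <- synthetic_config(seed = 42, n_rows = 40, n_cols = 50,
                        crops = c("corn", "rice", "soybean", "wheat"))
res <- run_pipeline(cfg)
```

The run logs the cleaning ledger and per-crop fits:

    loaded 4817 rows, 4 crops
    cleaning ledger: 4817 -> 3504 rows
    corn: n = 677, shape = 3.92, validated rho2 = 0.061
    rice: n = 710, shape = 3.88, validated rho2 = 0.022
    ...

and the global production-weighted reductions come out of the summary table:

```r
s <- res$summary
glob <- s[s$region == "Global" & s$crop != "all",
          c("crop", "phase", "yield_mean_w", "rc_mean_w")]
glob$reduction_pct <- round(-100 * glob$rc_mean_w, 1)
```

        crop phase yield_mean_w rc_mean_w reduction_pct
        corn     1         4590   -0.4679          46.8
        rice     1         5518   -0.4498          45.0
     soybean     1         2587   -0.4116          41.2
       wheat     1         3856   -0.5243          52.4
        corn     2         3281   -0.6093          60.9
        rice     2         3863   -0.5952          59.5
     soybean     2         1766   -0.5806          58.1
       wheat     2         2870   -0.6308          63.1

`yield_mean_w` is the area-weighted mean predicted yield (kg ha⁻¹) for the
phase; `reduction_pct` is the production-weighted mean yield loss relative to
the baseline. On this synthetic landscape every crop loses roughly 40–50% of
yield in phase 1 and around 60% once stocks are gone; the numbers describe
the synthetic world, not the real one, but the phase-2 > phase-1 ordering
and the dominance of nitrogen/irrigation/machinery effects carry the same
structure as a real-data run would.

Multicollinearity screening for a fitted crop:

```r
res$gvif$corn
#        predictor df gvif gvif_scaled gvif_scaled_sq flag5 flag10
#          n_total  1 1.02        1.01           1.02 FALSE  FALSE
#        thz_class  6 1.76        1.05           1.10 FALSE  FALSE
#   ...
```

A thin CLI wrapper ships in `inst/cli/cropshock.R`
(`cropshock.R run-all --config cfg.yaml --out dir/`;
`cropshock.R simulate --seed 7 --out table.csv`).

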