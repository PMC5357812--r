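# tortmove

Movement analysis for GPS-telemetered tortoises (and other slow terrestrial
animals) in projected planar coordinates.

Bihourly GPS telemetry of leopard tortoises (*Stigmochelys pardalis*) in
semi-arid Karoo rangeland poses a specific statistical problem: the animals
move a few hundred metres per day, while the transmitters carry horizontal
fix errors averaging ~17 m with a heavy right tail, and roughly a tenth of
raw fixes are transmitter artifacts. Raw Euclidean step lengths therefore
overstate movement, and artifact fixes corrupt everything downstream.
`tortmove` implements the full analysis chain for this setting, for movement
ecologists who want each stage explicit, configurable and tested:

1. **Fix-error model** — per-fix Euclidean errors from stationary
   calibration data; empirical quantile function of the log10 errors,
   `Q_log10(p)`, at Hazen plotting positions.
2. **Step correction** — each step of raw length `d_est` gets the rank
   percentile `p` of its length among all steps and is corrected by
   deducting the matching error quantile on the log scale:

   `d_corr = max(0, d_est − 10^Q_log10(p))`

3. **Screening** — ordered discard rules: incomplete/dubious records,
   deployment-window violations, clock offsets > 120 s, extreme HDOP,
   z-coordinate error > 100 m against a DEM, impossible displacements
   (anchored on the previous retained fix).
4. **Spatial covariates** — habitat class per half-open raster cell,
   food/water/none resource regrouping, Euclidean distance to water
   features (points + polygons) and to resource pixel centres, inclusive
   250 m proximity flags.
5. **Aggregation** — bihourly records (weather from the 2 h before each
   fix) and daily records (cumulative distance, modal habitat, daily
   weather), both with log10 responses.
6. **Inference** — Gelman-standardized predictors (continuous divided by
   2 SD), Gaussian random-intercept LMMs fit by ML (`lme4`), all 2^m
   candidate subsets, AICc ranking (`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`),
   Akaike weights, ΔAICc < 2 top-set model averaging with unconditional
   SEs and relative importance, and nested likelihood-ratio interaction
   tests.
7. **Synthetic study system** — habitat mosaic + DEM + water features +
   weather + correlated-random-walk tracks whose log10 step lengths follow
   the same covariate model the inference stage fits, plus corrupted fixes
   with ground-truth artifact labels and calibration sets. Everything is
   deterministic under one root seed.

## Worked example

```r
library(tortmove)
cfg <- demo_config(out_dir = "demo_run", seed = 1)   # 4 animals, 3 months
rep <- run_pipeline(cfg)
print(rep)
```

```
tortmove pipeline run (seed 1)
  fixes_simulated        4320
  calibration_fixes      200
  fixes_retained         3778
  fixes_annotated        3778
  steps                  3774
  bihourly_records       3298
  daily_records          359
  candidates_bihourly    16
  candidates_daily       8
Fix screening: 4320 in, 542 removed, 3778 retained
  rule incomplete      removed 46
  rule window          removed 0
  rule time_offset     removed 119
  rule hdop            removed 199
  rule out_of_grid     removed 8
  rule z_error         removed 122
  rule impossible_move removed 48
```

The generator planted artifacts in 12.75% of fixes; screening removed 542
of 4,320 (12.5%): the planted artifacts plus a handful of clean fixes whose
error-displaced positions fell off the mapped grid (the `out_of_grid`
line). The model stage then ranks every candidate
subset and averages the top set:

```r
print(rep$model_bihourly, max_rows = 3)
```

```
Candidate set: 16 models; top set (delta AICc < 2): 1
                                        model df  logLik    AICc delta weight  top
         time_of_day + dist_water_m + temp_2h 16 -971.37 1974.90  0.00  0.631 TRUE
 month + time_of_day + dist_water_m + temp_2h 18 -970.68 1977.57  2.67  0.166 FALSE
                        time_of_day + temp_2h 15 -973.73 1977.61  2.71  0.163 FALSE

Model-averaged coefficients (top set):
          name         term   beta    se      z  lower  upper ri
   (Intercept)  (Intercept)  1.237 0.024 50.839  1.189  1.284 NA
  dist_water_m dist_water_m -0.031 0.014  2.181 -0.059 -0.003  1
       temp_2h      temp_2h  0.102 0.025  3.996  0.052  0.152  1
```

(coefficient rows abbreviated). Reading the output: the intercept 1.237 is
the expected log10 bihourly displacement at reference conditions
(10^1.237 ≈ 17 m per 2 h); movement increases with temperature
(β = +0.102 per 2 SD of temperature) and decreases with distance from
water (β = −0.031), recovering the structure the generator planted; month
drops out of the top set because the demo window spans only one season.
Every stage output is persisted under `out_dir` as plain text (fix CSVs,
Esri ASCII grids, GeoJSON water layers, model tables, a text report).

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tortmove.R", package = "tortmove"))')" \
    run-all --seed 1 --out-dir demo_run
```

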