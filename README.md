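# ecocorridor

Habitat suitability and ecological corridors for alpine wildlife, from a
coupled maximum-entropy / minimum-cumulative-resistance raster pipeline.

`ecocorridor` is aimed at ecologists modelling where a species (its
motivating case is the bharal, *Pseudois nayaur*, on the Tibetan Plateau)
can live today and under future climate/land-use scenarios, and how the
remaining habitat patches stay connected. It implements, as one coherent
R package:

- **Presence–background maximum-entropy SDM.** The fitted model is the
  Gibbs distribution over background cells
  `q_lambda(x) = e^{lambda . f(x)} / sum_bg e^{lambda . f}` that maximizes the
  L1-regularized gain
  `G(lambda) = mean_presence(lambda . f) - ln Z(lambda) - sum_j beta_j |lambda_j|`,
  fitted by cyclic coordinate ascent with exact 1-D Newton/bisection
  steps (linear, quadratic, product, hinge, and categorical-indicator
  features; stock default penalties). Outputs: raw and logistic
  suitability maps, replicate AUC, percent contribution, jackknife
  importance, response curves, Pearson collinearity screening.
- **Suitability classification and bookkeeping.** Logistic suitability is
  cut at 0.2 / 0.5 / 0.7 into unsuitable, marginal, moderate and most
  suitable classes; per-class areas, scenario deltas, and
  suitability-weighted habitat centroids (with elevation) follow.
- **MaxEnt → MCR coupling.** Each factor's marginal response curve is
  binned by suitability quintile into the 5-level resistance ladder
  {10, 20, 30, 40, 50}; percent contributions become the factor weights;
  the weighted overlay `R(x) = sum_f w_f r_f(x)` is the minimum cumulative
  resistance surface. Least-cost corridors
  (`MCR = min sum D_ij R_i`, Dijkstra over the 8-connected lattice with
  step cost `d * (R_a + R_b)/2`) connect the 8-connected patches of
  top-class habitat.
- **CA–Markov land-use projection.** `S(t+1) = S(t) P` with the transition
  matrix cross-tabulated from two calibration maps, an optional
  off-diagonal scenario multiplier, and a cellular-automata allocation
  that places the projected class totals by neighbourhood affinity; the
  distance-to-water/grassland predictors are then regenerated.
- **Landscape pattern metrics.** NP, PD, LSI, CONTAG, DIVISION and SHEI
  at the landscape level, following the standard FRAGSTATS definitions.
- **Synthetic landscapes.** A seeded generator of aligned raster stacks,
  land cover, and presence points with a known true response, so the
  whole pipeline is testable offline.

Rasters are plain ESRI ASCII grids held in a lightweight matrix-backed
`grid_layer` class; no GDAL dependency.

## Worked example

```r
library(ecocorridor)

# a synthetic study area with a known dominant driver (Bio16)
ws  <- make_synthetic_workspace(synthetic_spec(seed = 1))
cfg <- maxent_config(seed = 1)          # 10 reps, 25% test, tol 1e-5

ev <- evaluate_replicates(ws$presences, ws$stack, cfg)
round(c(auc_mean = ev$auc_mean, auc_sd = ev$auc_sd), 3)
#> auc_mean   auc_sd
#>    0.949    0.004

m  <- fit_maxent(ws$presences, ws$stack, cfg)
round(sort(percent_contribution(m), decreasing = TRUE), 1)
#> Bio16  Bio3 Bio19 Bio15    DW  LUCC   DEM    DH
#>  92.2   5.4   0.8   0.5   0.5   0.4   0.2   0.1

suit <- predict(m, ws$stack)            # logistic suitability in (0,1)
cl   <- classify_suitability(suit)      # classes 0-3 at 0.2/0.5/0.7
area_table(cl)                          # km2 per class and % of total

# resistance surface from the fitted responses, then corridors
sch  <- scheme_from_response(m)
surf <- resistance_surface(ws$stack, sch)
srcs <- identify_sources(cl, min_area_km2 = 5)
if (length(srcs) >= 2) least_cost_corridors(surf, srcs)
```

The replicate AUC (0.949 +/- 0.004 here) is the rank probability that a
held-out presence outscores a background cell; the contribution table
shows the generator's dominant variable (Bio16, the wet-quarter
precipitation analogue) correctly absorbing ~92% of the training gain.

Published bookkeeping can be fed straight through the same reporting
code:

```r
p <- system.file("extdata", "table3_areas.csv", package = "ecocorridor")
present <- load_area_table(p, "present")
attr(present, "total_km2")                                  # 4669
scenario_delta(present, load_area_table(p, "ssp245_2030"))  # -1199 km2, 25.68%
```

A full run (thin -> screen -> fit -> replicates -> predict -> classify ->
areas/centroid -> resistance/sources -> corridors -> metrics) with all
intermediates and a hashed manifest:

```r
cfg_path <- write_synthetic_workspace(synthetic_spec(seed = 1), "workspace")
run_pipeline(cfg_path, "run1")
```

or from the shell via `inst/cli/ecocorridor.R synth|run|thin|metrics`.

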