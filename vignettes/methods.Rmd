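---
title: "Methods: habitat suitability, resistance surfaces and corridors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat suitability, resistance surfaces and corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ecocorridor` chains four models that are usually run in separate GIS
tools into one auditable pipeline: a presence–background species
distribution model, a suitability classification with area bookkeeping,
a resistance-surface / least-cost corridor analysis, and a CA–Markov
land-use projection with landscape pattern metrics. This vignette states
each model, its assumptions, the tunable parameters with their defaults,
the numerical choices, and what the package's synthetic tests do and do
not establish.

## The raster data model

A `grid_layer` is a numeric matrix with square cells of `cellsize`
metres, a top-left `(x_min, y_max)` origin, and `NA` for nodata; row 1
is the northernmost row and the centre of cell `(r, c)` is
`(x_min + (c - 0.5) cellsize, y_max - (r - 0.5) cellsize)`. An
`env_stack` is a named, geometry-aligned set of layers; every model
operation works on the *joint* valid mask and propagates it — there are
no silent fill values. I/O is the ESRI ASCII grid dialect (values
written with 6 significant digits; a missing `nodata_value` header is an
error). GeoTIFF is deliberately not supported: the package carries no
GDAL dependency, and plain-text grids keep every artifact diffable.

Derived predictors follow the conventions of classified-land-cover
workflows:

* `slope_aspect()` uses Horn's 3×3 gradient. Aspect is the compass
  bearing of the *downslope* direction (east-dipping plane → 270°);
  flat cells get the sentinel −1 rather than a fabricated direction,
  and border cells are masked.
* `distance_to_class()` is centre-to-centre Euclidean distance to the
  nearest source cell (exact two-pass distance transform), which is how
  the distance-to-water (DW), distance-to-high-coverage-grassland (DH)
  and distance-to-road (DR) layers are built. One naming wrinkle is
  inherited from the source literature, which uses "DW" both for
  distance-to-water and once, evidently a typo, for distance-to-road:
  this package fixes DW = water, DH = high-coverage grassland,
  DR = road.

## Occurrence thinning

`thin()` implements greedy randomized thinning: points are visited in a
seeded random order and kept only if at least `min_dist` (default 100 m)
from every point already kept. The output is maximal, all pairwise
distances respect the floor, and the "one was kept randomly" behaviour
is reproducible through the seed. Coordinates must be projected metres;
the loader refuses lon/lat-looking input unless forced.

## The maximum-entropy model

The model is the Gibbs distribution over the background cells

$$q_\lambda(x) \propto e^{\lambda \cdot f(x)}$$

maximizing the regularized gain

$$G(\lambda) = \overline{\lambda \cdot f}_{\text{presence}} - \ln Z(\lambda)
  - \textstyle\sum_j \beta_j |\lambda_j|,$$

the standard presence–background formulation in which the fitted
distribution has maximum entropy subject to (soft) matching of presence
feature means. Assumptions: presences are an unbiased sample of use
within the study window; the background represents available
environment; features capture the response shape.

**Features.** Continuous variables are scaled to [0, 1] by background
min/max (prediction clamps to that range first, preventing hinge
extrapolation artifacts). Classes: linear, quadratic, pairwise products
(when ≥ 2 continuous variables), forward and reverse hinges at 30
background-quantile knots, and one indicator per observed category of a
categorical layer. All are config-overridable.

**Penalties.** $\beta_j$ = `reg_multiplier` × the published per-class
default (interpolated in the presence count) × the presence-sample
standard deviation of the feature / $\sqrt{m}$ — the stock behaviour of
the reference software, which the source study used with defaults.

**Optimization.** Cyclic coordinate ascent. Each coordinate step solves
its 1-D subproblem exactly: the tilted background expectation
$E_j(\delta)$ is increasing in $\delta$, so the stationarity condition
on each sign branch of the L1 term is found by safeguarded
Newton/bisection, and the candidate with the largest exact gain change
is accepted. Gain is therefore non-decreasing along the recorded path;
the run stops when a full cycle improves the gain by less than
`convergence_tol` (default 1e-5, the tolerance the source study states)
or after `max_iterations` (500) cycles. The background is a seeded
uniform sample of valid cells (default 10,000, or all if fewer) with the
presence cells always included.

**Outputs.** Raw output is $q_\lambda$ relative to the training
background (sums to 1 over it). Logistic output is
$e^H q / (1 + e^H q)$ with $H$ the entropy of the fitted background
distribution — the calibration for which an uninformative model scores
exactly 0.5 everywhere (that defining property pins the form of the
transform). Replicate evaluation refits on seeded 75/25
presence splits (defaults: 10 replicates, 25% test) and reports the
rank-based AUC of held-out presences against the model background.
Percent contribution credits each accepted coordinate-step gain
increment to the updated feature's source variable (products split
evenly); jackknife refits with-only and without each variable.

**Collinearity screen.** Pearson r over all joint-valid cells (not just
sample points — the denser estimate; documented choice). Pairs with
|r| ≥ 0.8 are resolved in descending |r| order by dropping the member
with the lower pre-model contribution; categorical layers are exempt;
constant layers are excluded with a warning.

## Suitability classes, areas, centroids

Logistic suitability is cut at 0.2 / 0.5 / 0.7 into four classes
(unsuitable, marginal, moderate, most suitable). The published interval
notation overlaps at the endpoints, so the half-open upward convention
is fixed here: [0, 0.2), [0.2, 0.5), [0.5, 0.7), [0.7, 1]. Areas are
cell counts × cellsize²; the "total suitable" area is classes 1–3;
percentages are rounded half-away-from-zero to the printed precision of
the tables they are compared against. One consequence is documented
honestly: the source table's "48.44%" for the SSP-585 2050 decrease is
a truncation of 2262/4669 = 48.447%, which this package reports as
48.45.

The habitat centroid is the suitability-weighted centre of mass of the
suitable cells (a binary-weights flag exists); its elevation is the
same weighted mean of the DEM. `centroid_shift()` returns displacement,
compass bearing (NaN for zero displacement), and elevation change.

## CA–Markov projection

`estimate_transition()` cross-tabulates two aligned calibration maps
into a row-stochastic per-step matrix (classes absent at t1 get an
identity row: no evidence, no invented change). `markov_project()`
advances areas by whole steps, $S_{t+n} = S_t P^n$, conserving total
area. The literature this follows speaks of a "modified" Markov
prediction without defining the modification; here it is an explicit,
minimal, default-off mechanism (`scenario_adjust()`): scale all
off-diagonal rates by one multiplier and let the diagonal re-absorb the
difference.

`ca_allocate()` turns projected totals into a map: a cell's affinity for
a class is the same-class fraction in its k×k neighbourhood (default
5×5), optionally blended 50/50 with a per-class suitability layer;
classes over target shed their lowest-affinity cells and classes under
target claim the highest-affinity released cells, with seeded
tie-breaking. Counts match the targets exactly and allocating to the
current counts is the identity. Neighbourhood size, blend and iteration
count (default 10) are conventional choices, not inferred ones, and are
configurable.

## Resistance surfaces and corridors

The coupling step reads resistance directly off the fitted model: each
factor's marginal response (100 points; other variables at background
mean/mode) is mapped to the 5-level ladder by suitability quintile —
most-suitable fifth → 10, least-suitable fifth → 50 — and consecutive
equal levels merge into intervals (non-contiguous interval sets are
legitimate, as published resistance tables show for elevation). Factor
weights are the percent contributions, normalized at build time, so the
surface $R(x) = \sum_f w_f r_f(x)$ lies in [10, 50] and is invariant to
uniform weight rescaling. A flat response yields an all-30 scheme with a
warning rather than fabricated structure. Published-table configs load
verbatim (including a "Bo7"→"Bio7" label repair) with a label→code
legend for categorical rows.

Source patches are 8-connected components of the top class with area ≥
`min_area_km2` (default 10; the criterion named in the source — "area
size" — without a number). Cost distance is Dijkstra on the 8-connected
lattice with step cost $d(a,b)\,(R_a + R_b)/2$ ($d$ = cellsize or
√2·cellsize): the standard discretization of accumulating
distance × resistance. Corridors are backlink traces from the cheapest
cell of the destination patch; patch-to-patch cost uses
nearest-member semantics, is symmetric, satisfies the triangle
inequality, and pairs severed by the mask are reported disconnected
rather than erroring.

## Landscape metrics

Six landscape-level FRAGSTATS definitions: NP (8-connected patches over
all classes), PD (patches per 100 ha), LSI (0.25·E/√A with the
landscape boundary counted as edge; toggleable), CONTAG (double-count
4-adjacency), DIVISION, SHEI; natural logarithms; 0·ln 0 = 0; CONTAG
and SHEI are NaN with a warning on single-class landscapes.

One property worth recording: for two classes of equal cover, *both* a
perfect checkerboard and the perfect-aggregation limit sit exactly at
CONTAG = 50 (all adjacency mass purely off-diagonal or purely
on-diagonal gives $\sum p \ln p = -\ln 2$ either way), and any finite
two-block map scores below 50. "More aggregation ⇒ higher CONTAG" is
therefore only testable with ≥ 3 classes, which is how the package's
property test is built.

## The synthetic world

`synthetic_spec()` defaults are the package's stated test world, chosen
once to mirror the kind of system the pipeline targets: an 80 × 80 km
window at 1 km resolution; four bioclimate-like predictors as
moving-average-smoothed Gaussian noise (correlation length 6 cells)
rescaled to plausible ranges; a smoother DEM at plateau elevations
(3500–5500 m); a five-class grassland-dominated land cover with small
water and construction fractions, from which DW and DH are true
distance rasters; and 200 presences (the order of a thinned field
campaign). The true suitability is logistic in z-scored layers with one
dominant negative driver (the wet-quarter precipitation analogue) and a
weak secondary one, with intercept −9 and slope −5 so that habitat is
rare (~5% of the landscape) and sharply defined — emulating
concentrated alpine habitat and the near-perfect discrimination real
studies of this system report. All randomness flows from one seed
through named substreams, so outputs do not depend on call order.

What a green synthetic test establishes: the estimator recovers a known
dominant driver, discriminates rare habitat (replicate AUC > 0.9), and
every geometric kernel agrees with brute-force oracles. What it does
not: spatial sampling bias, predictor collinearity structure of real
bioclimate suites, non-logistic true responses, or transferability
across climates — none of which the generator emulates.

## Numerical choices and edge cases

* Coordinate steps are capped at |λ| ≤ 30; root solves bisect to 1e-11
  on the expectation scale; the total gain is recomputed exactly each
  cycle to stop incremental drift.
* Class boundaries assign upward; percentage rounding is
  half-away-from-zero; centroid bearing of a zero shift is NaN.
* Distance transforms use a large finite sentinel (1e15) instead of
  infinity so the parabola arithmetic stays well-defined.
* Degenerate inputs error early and name the offender: empty rasters,
  all-masked DEMs, zero-variance feature sets, presences off the valid
  mask, non-covering resistance schemes, infeasible allocation targets,
  non-positive resistance.

## Known limitations

No reprojection between CRSs (alignment is affine resampling on a shared
projected grid); no GeoTIFF; no circuit-theory connectivity or corridor
widths; class- and patch-level metric suites are out of scope; the
CA–Markov allocation is a generic neighbourhood rule, not a calibrated
demand model.
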