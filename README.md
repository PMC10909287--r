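# dynaccess

Population accessibility to emergency departments (EDs), measured two ways:
against the **static** (residential register) population and against the
**dynamic** (mobile-network-derived, hourly) population — and tools to
quantify *where and when* the static picture over- or underestimates the
population actually present.

The package is aimed at health-geography and emergency-care researchers. It
implements, end to end:

* **Road-network travel times** — segment splitting at shared vertices,
  removal of walking roads (< 10 km/h), minute-weighted undirected graph,
  centroid snapping (5 km eligibility), exact closest-facility routing and
  ED catchment derivation.
* **Grid fusion** — merging a homogeneous residential grid with a
  variable-resolution, privacy-floored dynamic grid (nested cells, sides in
  powers of 2 down to quarter-cells; equal-split disaggregation, exact
  population conservation).
* **Accessibility bands** — population by travel-time band
  \[0–10), \[10–20), \[20–30), \[30–60), ≥60 minutes, stratified by
  urban / densely-populated / rural class.
* **Temporal share ratios** — the core statistic
  `R = static share / dynamic share` per band and stratum (hour × weekday /
  weekend, month); `R > 1` = static data overestimates the population
  present, `R < 1` = underestimates. Normalizing each dataset by its own
  total makes `R` invariant to the dynamic data's operator-extrapolation
  scale.
* **Catchment statistics** — per-ED percentage differences at midday,
  global Moran's I with inverse-distance weights (auto cut-off = max
  nearest-neighbour distance; permutation and analytic p), one-way ANOVA
  across hospital levels and Tukey HSD.
* **Synthetic scenarios** — a generator emulating the structure of the
  proprietary inputs (census grid, hourly operator counts with a minimum
  count of 5 per cell, road database): Gaussian urban core, weekday
  office-hour commuting, July coastal vacation outflow, Poisson noise.

## Worked example

```r
library(dynaccess)

# scaled-down country: 64 x 64 grid of 2 km cells, ~820k residents,
# 68 EDs (the national facility count), hourly counts for Jan + Jul
sc  <- scenario_config(n_eds = 68L, noise = TRUE)
res <- run_pipeline(pipeline_config(scenario = sc), out_dir = "out")

res$stats$july$moran$I        # 0.2589769
res$stats$july$moran$p_perm   # 0.001
res$stats$january$moran$I     # 0.01837476
res$stats$january$moran$p_perm  # 0.675
res$stats$july$anova$F        # 18.93686  with df (2, 65)
```

At 13:00 in July, catchment-level differences cluster spatially
(I = 0.26, permutation p = 0.001): city-centre catchments overestimate
(level-1 ED catchments by ~18% on average — the residents are on vacation),
coastal catchments underestimate. In January the surface is noise
(I = 0.02, p = 0.675). The ANOVA confirms the difference across hospital
levels in July, and Tukey HSD locates it between level 1 and level 3
(−27.2 ± 13.3 percentage points, adjusted p < 0.001):

```r
res$stats$july$tukey
#>   pair              diff half_width    lwr     upr     p_adj
#> 1 level2-level1    -6.45      13.90 -20.35    7.45  5.10e-01
#> 2 level3-level1   -27.16      13.29 -40.44  -13.87  1.96e-05
#> 3 level3-level2   -20.71       9.85 -30.55  -10.86  1.16e-05
```

The diurnal commuting signal shows up in the band ratios of the default
12-ED scenario (`run_pipeline(pipeline_config())$ratios`, or
`analysis/04_temporal_ratios.R`): weekday office-hour ratios in the
0–10 min band fall below 1 (mean 0.97 — residential data underestimates
the daytime population near EDs), while the 10–30 min bands rise above 1
(1.07–1.09).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → route → bands → ratios → catchment statistics) and
write their tables under `results/`.

## Layout

```
R/                  package code (generators, routing, fusion, bands,
                    ratios, spatial stats, GeoJSON/CSV IO, pipeline)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R   headline-quantity recomputation (JSON out)
tests/testthat/     unit, property and end-to-end tests with
                    independent oracles
vignettes/          methods vignette: model, assumptions, choices
```
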