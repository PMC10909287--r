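---
title: "Measuring ED accessibility with static and dynamic population data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ED accessibility with static and dynamic population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaccess)
```

## The problem

Accessibility to emergency departments (EDs) is conventionally measured
against residential ("static") population registers: count how many people
*live* within 10, 20, 30 or 60 minutes of the nearest ED. But people move.
During office hours they commute toward urban cores; in the vacation month
they leave the cities for the coast. A population snapshot derived from
mobile-network activity ("dynamic" population) captures where people
actually are, hour by hour. `dynaccess` implements the full comparison
pipeline: closest-facility travel times over a road network, fusion of a
homogeneous residential grid with a variable-resolution dynamic grid,
normalized share ratios across temporal strata, and spatial tests on
catchment-level over/underestimation.

## The core statistic

For a set of spatial units (travel-time bands or ED catchments) and a
temporal stratum $t$, each dataset is first normalized by its own total over
the same cells:

$$s_b = \frac{P^{static}_b}{\sum_{b'} P^{static}_{b'}}, \qquad
  d_b(t) = \frac{P^{dyn}_b(t)}{\sum_{b'} P^{dyn}_{b'}(t)}, \qquad
  R_b(t) = \frac{s_b}{d_b(t)}.$$

$R > 1$ means the residential register *overestimates* the share of the
population actually present in that unit at that time; $R < 1$ means it
underestimates. Normalizing by each dataset's own total is essential: the
dynamic data are extrapolated from one operator's market share, so absolute
totals are not comparable, and any global scale factor $c$ cancels from $R$
exactly. That identity (`ratio == 1` whenever dynamic $= c \times$ static) is
asserted by tests at $10^{-9}$.

At catchment level the same quantity is reported as a percentage difference
$(R - 1)\times 100$, mapped per ED, tested for spatial clustering with
global Moran's I under inverse-distance weights, and compared across
hospital levels 1–3 with one-way ANOVA and Tukey HSD.

## Pipeline stages and their conventions

**Road graph.** Segments are split wherever an interior vertex coincides
exactly with a vertex of another segment — connectivity by shared vertices,
as road databases encode it; geometric crossings are deliberately *not*
nodes, so bridges and overpasses do not create false junctions. Walking
roads (speed limit strictly below 10 km/h) are removed; a 10 km/h segment is
kept. Edge weight is travel time in minutes,
$\mathrm{length}_m / (\mathrm{speed}_{km/h} \times 1000/60)$; parallel edges
keep the fastest time. The graph is undirected — one-way streets and
turn restrictions are not modelled, and neither are weather, traffic or
ambulance-specific speeds.

**Snapping and routing.** Cell centroids within 5,000 m (Euclidean) of a
junction are snapped to their nearest junction; farther centroids are
marked unreachable and excluded from *both* datasets' totals — keeping the
cell set identical on both sides of the ratio, without which the identity
$R \equiv 1$ would fail. Each reachable cell gets the minimum-travel-time ED
by exact Dijkstra shortest paths; ties (equidistant nodes, equal travel
times) break toward the lower identifier, for determinism. Catchments are
the resulting partition of reachable cells.

**Grid fusion.** The dynamic grid is a nested, border-aligned refinement of
the static grid (sides scale by powers of 2, down to half a static cell).
Where dynamic cells are smaller, the static cell's population is split
equally among its quarters (uniform within-cell density, applied
recursively); where they are larger, covered static populations are summed.
Populations stay fractional reals so conservation is exact. Aggregated cells
take the urban class of their population-majority constituent, ties
resolved toward the more urban class; quarters inherit their parent's class.
Non-nested overlap is a hard error, not a warning.

**Bands.** Travel-time bands are half-open: $[0,10)$, $[10,20)$, $[20,30)$,
$[30,60)$, $[60,\infty)$ minutes — disjoint and exhaustive, with the
boundary value belonging to the upper band.

**Temporal strata.** A stratum is any combination of month, weekday/weekend
and hour; the dynamic population of a cell at a stratum is the arithmetic
mean of its counts over all matching observations. When all matching
observations are present the mean and the pooled sum give identical shares;
the mean is also robust to unequal numbers of observed days per stratum.

## Spatial statistics

Moran's I is computed as
$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$ on
catchment percentage differences, with $w_{ij} = 1/d_{ij}$ for
$0 < d_{ij} \le \tau$ and 0 beyond. The cut-off $\tau$ is chosen
automatically as the maximum nearest-neighbour distance — the smallest
value guaranteeing every catchment at least one neighbour, which keeps
neighbourhoods comparable between small urban catchments and large rural
ones. Catchment representative points are static-population-weighted
centroids of member cells, reflecting where the catchment population
actually sits. Weights are not row-standardized by default (a switch is
provided); because $I$ normalizes by $S_0$, the distance unit cancels.

Two p-values are reported: a two-sided permutation p,
$(1 + \#\{|I^*| \ge |I|\})/(1 + N_{perm})$ with $N_{perm} = 999$ under a
fixed seed, and the analytic z-test under the randomization assumption.
Constant surfaces (e.g. the identity scenario) leave $I$ undefined and are
reported as such, never as a number. ANOVA and Tukey HSD use the standard
`stats` machinery behind the module interface; degenerate inputs (zero
within-group variance) are resolved explicitly ($F = 0, p = 1$ for equal
means; $F = \infty, p = 0$ otherwise). The Tukey "± term" is the 95%
family-wise half-width from the studentized-range distribution
(Tukey–Kramer for unequal group sizes), so an interval excludes zero exactly
when the adjusted p is below 0.05.

## The synthetic scenario

Real inputs of this kind (operator-grade mobile-network counts, national
registers, national road databases) are proprietary, so the package ships a
generator that reproduces their statistical structure:

* **Static grid** — a square study area (default 64 × 64 cells of 2 km)
  with a Gaussian density surface: peak 2,000 persons/cell at the centre,
  $\sigma = $ extent/8, plus a rural base of 4 persons/cell. One dense
  metropolitan core over a sparse hinterland, ~820,000 residents. The 2 km
  cell (rather than the 1 km of real residential grids) keeps the study area
  large enough, at a tractable cell count, that travel-time bands out to
  >60 minutes are populated.
* **Roads** — a lattice over cell centroids with speeds drawn from
  {30, 50, 70, 90, 110} km/h, a 5% share of walking roads, and a fraction of
  collinear polylines sharing interior vertices so intersection splitting is
  exercised.
* **EDs** — default 12 facilities sampled proportionally to population
  (one forced to the core centre), levels 1–3 assigned by local population
  rank at proportions 0.15/0.35/0.50. For catchment-level statistics the
  analysis uses 68 EDs — the national facility count at which the published
  ANOVA degrees of freedom F(2, 65) operate — so the inferential setting is
  matched rather than miniaturized.
* **Dynamic grid** — a quadtree refined while every child would hold at
  least `privacy_floor = 5` persons at *every* emitted stratum, down to
  quarter-cells. This emulates privacy-preserving variable-resolution count
  grids: fine cells in cities, coarse cells in the countryside, never a
  count below the floor (asserted by test with noise off).
* **Movement** — baseline presence is `operator_scale` (default 1.2) times
  the residential count, emulating operator-share extrapolation. On
  weekdays 08–17 outside July, `commuting_fraction = 0.25` of each non-core
  cell's population is present in core cells instead. In July, at all hours,
  `vacation_fraction = 0.15` of core populations relocates to the vacation
  region — the outer ring of the eastern ("coastal") half. Commuting is
  deliberately switched off in July: the vacation month shows a flat
  diurnal profile, and industrial-style vacation absence removes the
  commuting signal rather than superimposing on it.
* **Noise** — optional independent Poisson draws per cell-stratum, off by
  default so the conservation and identity checks hold in closed form; on
  for the catchment statistics so the no-effect (January) comparison has a
  non-degenerate null.

The generator conserves `operator_scale × total static population` exactly
at every stratum, is fully reproducible from its seed, and emits long-format
hourly observations plus GeoJSON layers identical in shape to what the
readers validate.

What the generator does *not* emulate: agent-level mobility, real national
geography, border effects (cells reachable only by boat or helicopter),
device-ownership bias, or calibration of the operator extrapolation. Passing
tests therefore demonstrate that the pipeline arithmetic, the routing, and
the statistics are correct and that the method recovers implanted
commuting/vacation patterns of realistic magnitude — not that any particular
national result would be reproduced from real data.

## Numerical and design choices

* Exact shortest paths (Dijkstra via `igraph`) rather than any hierarchical
  approximation; verified against exhaustive simple-path enumeration on
  small random graphs.
* Snap eligibility measured to the nearest *junction* (not the nearest edge);
  both the threshold and the interpretation are configurable arguments.
* Ratios with a zero dynamic share are `NA`, never `Inf`; they propagate as
  missing.
* Fractional static populations are never rounded; conservation is asserted
  at $10^{-9}$ over random nested grids.
* Problem sizes used in the shipped analyses: 4,096 static cells, ~8,700
  dynamic cells, 96 temporal strata (24 h × weekday/weekend × January/July),
  999 Moran permutations. One full pipeline run takes well under a minute on
  a single CPU.

## Known limitations

The movement model is a two-flow caricature (commuting + vacation); real
mobile-network data shows richer structure (events, weather, tourism,
borders). The road lattice has uniform topology, so travel-time variation
comes from speeds and ED placement rather than network shape. Urban classes
are generated by distance bands, standing in for the official
commuting-based municipal classification, which is treated as input data
throughout. The one-sided ("coastal") vacation region is a deliberate
geographic asymmetry: a symmetric ring would cancel much of the spatial
autocorrelation signal that the catchment-level clustering test is designed
to detect, and real vacation geography is asymmetric in the same way.
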