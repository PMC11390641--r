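---
title: "Potential-model accessibility and equity for aged-care institutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-model accessibility and equity for aged-care institutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careaccess)
```

## The problem

Institutional aged care is a capacity-constrained service: a bed
occupied by one resident is unavailable to another, and an older adult's
willingness to enter a home falls off with travel time, with the home's
size, and with its quality grade. A city can have a bed total that looks
proportional to its older population district by district while the
*effective* supply an older adult can reach varies several-fold across
neighbourhoods. This package separates those two questions — aggregate
proportionality (equity) and local reachability (accessibility) — and
computes both at grid resolution.

## The accessibility models

All three models act on the same data: demand cells `k` (or `i`) with
60+ population `P_k`, facilities `j` with beds `M_j`, and a travel-time
matrix `D_ij` in hours.

**Basic potential.** `A_i = Σ_j M_j / D_ij^β`. Pure gravity: useful as a
baseline and as an oracle anchor, but it double-counts beds (every cell
"receives" every bed) and has no per-capita interpretation.

**Competition adjustment.** Dividing each facility's contribution by its
demand potential `V_j = Σ_k P_k / D_kj^β` shares its beds over the
demand it serves. The resulting `A_i` is a per-capita allocation rate:
summing `P_i · A_i` over cells returns exactly the system's bed total.
This conservation identity is algebraic, not approximate, and the test
suite asserts it at 1e-9 relative tolerance on randomly generated
cities.

**Improved model.** Two facts about aged care motivate the final form:
bigger institutions (≥ 500 beds) draw from farther away, and
higher-graded institutions are attractive over longer travel times. Both
enter through the influence coefficient

    S_ij = 1 − (D_ij / (d + D_j))^β,   clamped to [0, 1],

where `d` is the bed-scale service radius (1 h under 500 beds, 2 h at or
above) and `D_j` the tier travel limit (0.25 h below Level 3, 0.5 h for
Level 3, 1 h for Level 4, 2 h for Level 5). `S` multiplies both the
supply a cell sees and the demand a facility counts in `V_j`, and the
result is scaled to beds per 1,000 older adults:

    A_i = 1000 · Σ_j S_ij M_j / (D_ij^β V_j),
    V_j = Σ_k S_kj P_k / D_kj^β.

Three design points deserve emphasis, because the design here was
genuinely open:

- **`V_j` sits in the denominator.** A formulation without the
  competition term cannot produce a per-capita quantity — "beds per
  1,000 older adults" is dimensionally a supply share, which only the
  normalised form yields (and only it conserves beds). The
  non-normalised gravity form remains available as
  `accessibility_basic()` for comparison.
- **The catchment is soft.** `S` is clamped at zero for
  `D_ij ≥ d + D_j`, so the scale radius and tier limit jointly define a
  reach beyond which a facility exerts no pull, rather than acting as
  two separate hard cut-offs. One could instead read the tier limit as a
  hard constraint and the radius as the decay scale; the summed-
  denominator form was chosen because it follows the coefficient's
  definition literally (one formula, one reach `d + D_j`) and yields
  anchor values such as `S(0.5; d = 1, D_j = 0.5) = 2/3` directly.
- **Boundary and ungraded cases.** The scale rule as stated covers
  `M_j > 500` and `M_j < 500`; exactly 500 beds is assigned the large
  radius (a facility at the threshold is, for planning purposes, a large
  facility). Ungraded institutions are treated as "below Level 3"
  (0.25 h): the grading system gives no other place to put them, and
  about 40% of institutions in the motivating registry are ungraded, so
  silently dropping them would distort every result.

`β` defaults to 1 — appropriate for a service used far less frequently
than, say, hospitals, where 2 is common — and warns outside `[1, 2]`.
Facilities whose catchment contains no population (`V_j = 0`) are
excluded from the sum rather than dividing by zero, and are surfaced as
"unused capacity" in the run report, since a facility nobody can reach
is itself a planning finding.

## Travel impedance

No routing engine is bundled. The default impedance is straight-line
distance (planar euclidean, or haversine on lon/lat) inflated by a
detour factor of 1.3 — a common planning approximation of network
vs crow-flies distance — divided by 30 km/h. Both are configurable, and
a precomputed matrix (long CSV `cell_id,facility_id,hours`) can replace
the whole computation, which is the recommended route when network
travel times are available. All impedances are floored at one minute so
`1 / D^β` stays finite when a facility sits inside a demand cell; the
floor only binds for co-located pairs and its value is irrelevant to any
conservation property.

## Equity: Lorenz and Gini

Districts are sorted **ascending by beds per capita** before
accumulating shares. Sorting by any other key (e.g. raw bed counts) can
produce a non-convex "Lorenz" polyline whose Gini is not an inequality
measure; per-capita ordering is the only concave-consistent choice.
Ties break by unit id for determinism; zero-demand units sort first and
contribute zero-width segments, so adding an empty unit provably leaves
`G` unchanged. The trapezoid formula
`G = 1 − Σ (P_k − P_{k−1})(T_k + T_{k−1})` is checked in the tests
against two independent oracles: numeric integration of the polyline
(1e-12) and the O(n²) demand-weighted mean-absolute-difference Gini
(1e-9), plus the transfer principle and scale invariance as property
tests. Band edges (0.2 / 0.3 / 0.4 / 0.5) are half-open on the right;
the verbal convention does not specify edge ownership, so `G = 0.2` is
"relatively-average".

The shipped 16-district fixture contains the published bed and
institution counts. The corresponding 60+ populations are only
partially published (the top five districts); the packaged completion
(`shanghai_pop60_synthetic()`) keeps those five exactly and splits the
remaining citywide total equally over the other eleven districts — the
least-informative completion, flagged `synthetic` row by row. Any Gini
computed from it is a demonstration, not a reproduction of the original
case study.

## Kernel density

`kernel_density()` uses an isotropic Gaussian kernel in which each point
integrates to its weight (1 for institution counts, beds for bed
density), so the area-weighted grid sum recovers total weight — the
invariant the tests assert within 1% whenever the bandwidth is at least
two grid spacings (below that, a grid cannot resolve the kernel, and
above it edge truncation is negligible at four-bandwidth padding). The
default bandwidth is Silverman's rule on the mean per-axis spread; the
kernel and bandwidth behind any particular published map are typically
unstated, so density values are treated as descriptive, never as
quantities to match.

## The synthetic-city generator

`generate_city()` exists so every pipeline stage is testable without
external downloads. Its defaults are the study conditions of the
motivating case: an 80 km square at 500 m grid resolution, 16 districts,
5,536,600 older adults, 658 facilities, log-normal bed counts
(`meanlog = log(150)`, matching the ~150-bed median scale of central-city
institutions, `sdlog = 0.8`, putting the mean near the observed ~208
beds/institution), roughly 60% of facilities graded (the registry's
396/658), and facilities placed with 0.7 bias toward population. The
population surface decays exponentially from the centre(s);
`center_concentration = 2` reproduces a strongly monocentric profile,
`0` a uniform one, and multiple weighted centres give polycentric or
two-blob cities for tests. Cell populations are rounded by largest
remainder so they sum *exactly* to the target; districts come from a
k-means tessellation of cell centroids; all randomness flows from one
integer seed through a local RNG stream that leaves the caller's
`.Random.seed` untouched.

What the generator does **not** emulate: road networks (impedance is
straight-line-based), age structure within the 60+ population,
correlation between facility tier and location, water bodies or other
barriers, and temporal dynamics. Passing tests on synthetic cities
therefore demonstrates the *mathematics* — conservation, monotonicity,
oracle agreement, the central-vs-peripheral ordering — not calibrated
agreement with any real city's accessibility surface, which additionally
requires real travel times and population rasters.

## Numerical choices and problem sizes

- Impedance floor 1/60 h; `S` clamped to `[0, 1]`; `G` clamped against
  floating-point dust at 0 and 1.
- Property tests run on cities of ~2,500 cells × 50 facilities (20
  seeds) for conservation, ≤ 5 × 3 micro-instances against the naive
  double-loop oracle at 1e-12, and 100 random 16-unit instances for the
  Gini oracle at 1e-9 — sizes chosen to exercise every code path while
  keeping the full suite around five seconds.
- `lorenz_curve()` errors on all-zero demand or supply rather than
  returning NaN shares; `surface_to_district()` reports zero-population
  districts as `NA` rather than 0, since "no residents" and "no access"
  are different findings.

## Known limitations

Accessibility values from the default impedance are sensitive to the
detour factor and speed, which are conventions, not estimates; use a
real travel-time matrix for substantive conclusions. The improved
model's catchment interaction (`d + D_j` summed inside `S`) is one
defensible reading of scale-plus-tier attraction; alternatives (hard
tier cut-offs, multiplicative attenuation) would change peripheral
values. GeoTIFF rasters are not read — convert to ESRI ASCII grid, whose
header and geotransform round-trip exactly. District polygons are
supported as GeoJSON with even-odd point-in-polygon assignment of cell
centroids; cells straddling boundaries are assigned by centroid alone.
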