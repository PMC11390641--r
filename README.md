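# careaccess

Spatial accessibility and equity assessment for institutional aged care.

As populations age, whether older adults can actually reach an aged-care
bed depends not just on how many beds a city has, but on where they are,
how good the institutions are, and who else is competing for them.
`careaccess` is for health-services researchers and urban planners who
have (or can simulate) three things: a gridded surface of the 60+
population, a registry of aged-care institutions (location, beds,
quality tier), and some notion of travel time between them. It answers
two questions: *how many beds per 1,000 older adults are effectively
reachable from each grid cell?* and *is the allocation of beds across
districts equitable relative to where the older population lives?*

## The models

Three gravity-style potential models, from simplest to the headline one:

- **Basic potential**: `A_i = Σ_j M_j / D_ij^β` — facility bed counts
  `M_j` discounted by travel time `D_ij` raised to a friction exponent
  `β` (default 1). No competition: units are raw potential.
- **Competition-adjusted** (population-size factor):
  `A_i = Σ_j M_j / (D_ij^β · V_j)` with `V_j = Σ_k P_k / D_kj^β`. Each
  facility's beds are shared over all demand `P_k` it can reach, making
  `A_i` a per-capita rate.
- **Improved** (the package's centrepiece): an influence coefficient
  `S_ij = 1 − (D_ij / (d + D_j))^β`, clamped to `[0, 1]`, attenuates both
  supply and demand sides:

  ```
  A_i = 1000 · Σ_j S_ij · M_j / (D_ij^β · V_j),
  V_j = Σ_k S_kj · P_k / D_kj^β
  ```

  Here `d` is a bed-scale service radius (1 h for facilities under 500
  beds, 2 h at or above) and `D_j` a quality-tier travel limit (15 min
  below Level 3, 0.5 h / 1 h / 2 h for Levels 3/4/5). `S` reaches zero at
  `D_ij = d + D_j`, a soft catchment boundary: small, low-tier homes only
  pull nearby demand, large high-tier ones pull from far. Output is in
  **beds per 1,000 older adults**, and within reach of any demand the
  allocation conserves beds exactly:
  `Σ_i P_i · A_i / 1000 = Σ_j M_j` over facilities with `V_j > 0`.

Equity across districts is assessed with the **Lorenz curve** (units
sorted by beds per capita, cumulative bed share against cumulative 60+
population share) and the **Gini coefficient**
`G = 1 − Σ_k (P_k − P_{k−1})(T_k + T_{k−1})`, with the conventional bands
(below 0.2 "absolute average" … 0.5+ "wide gap"). Facility point
patterns are summarised with weighted Gaussian **kernel density**
surfaces and per-district tables.

Travel times default to straight-line distance × a detour factor (1.3) ÷
speed (30 km/h), floored at one minute; a precomputed travel-time matrix
(long CSV `cell_id,facility_id,hours`) can be plugged in instead.

## Worked example

A synthetic monocentric city — 20 km square, 500 m grid, 400,000 older
adults decaying from the centre, 80 facilities placed with a bias toward
population:

```r
library(careaccess)
city <- generate_city(city_spec(seed = 42, extent_km = 20, grid_m = 500,
                                n_districts = 9, total_older_pop = 400000,
                                n_facilities = 80))
imp <- impedance_from_coords(city$cells, city$facilities)
A <- accessibility_improved(city$cells, city$facilities, imp)
A
#> Accessibility surface (improved model, beta = 1): 1600 cells
#>   A in [14.72, 78.09] beds per 1000 older adults

agg <- surface_to_district(A, city$cells)
head(agg[order(-agg$accessibility), ], 3)
#>  district_id older_pop accessibility
#>          D08    105041         47.52
#>          D05     50995         43.43
#>          D04     49203         41.81

sum(city$cells$older_pop * A$accessibility) / 1000   # bed conservation
#> [1] 15960    # == sum(city$facilities$beds)
```

Cells near the centre see ~50–78 beds per 1,000 older adults; the
periphery drops below 30 — the central-vs-suburban imbalance the
improved model is designed to expose, even though district-level bed
totals look equitable: running `equity_summary()` on the district
beds/population table of the same city gives `G = 0.166`
("absolute-average").

The published 16-district Shanghai table ships as a fixture:

```r
s <- district_summary(table1_fixture())
sum(s$n_institutions)                 # 658
round(s$share_institutions_pct[1], 1) # 20.2  (Pudong, 133 institutions)
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/careaccess.R synth  --seed 42 --extent-km 20 --out-prefix city
Rscript inst/cli/careaccess.R access --demand city_cells.csv \
    --facilities city_facilities.csv --model improved --out-prefix run
Rscript inst/cli/careaccess.R equity --units districts.csv --out-prefix eq
```

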