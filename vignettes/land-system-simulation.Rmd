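---
title: "Demand-driven land system simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demand-driven land system simulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipland)
```

tipland simulates changes in *land systems*: mixed land-use/cover classes
that combine a dominant cover type with a within-cell density level. This
vignette is the package's account of the science it implements — the models,
their assumptions, the tunable parameters, the numerical choices, and what the
synthetic test scenes do and do not establish about behaviour on real data.

## From land cover to land systems

The raw input is a categorical land cover raster with ten basic types
(cropland, forest, grassland, shrubland, wetland, water body, tundra,
artificial surfaces, bare land, snow/ice; integer codes 0–9). Building the
land system map takes three steps:

1. **Majority upscaling** (`upscale_dominant_type()`). The fine raster is
   traversed in non-overlapping `window × window` blocks (default 33, so
   30 m cells aggregate to 990 m cells). Each coarse cell records the modal
   cover type of its block and the *dominant fraction* — the modal type's
   share of the block's valid cells.
2. **Natural-breaks density classing** (`compute_density_breaks()`,
   `classify_density()`). For each cover type, the dominant fractions of all
   its coarse cells are split into three classes (low / medium / high
   density) at the two breakpoints that minimize the within-class sum of
   squared deviations — the Jenks natural-breaks criterion. The package
   implements the exact weighted Fisher dynamic program over the unique
   fraction values (block fractions have denominator `window²`, so the number
   of unique values is bounded and the exact solution is cheap); the test
   suite checks it against exhaustive enumeration of all two-breakpoint
   partitions.
3. **Coding** (`classify_density()`). The land system code is
   `3 · type + density`, type-major with density 0/1/2 = L/M/H, giving up to
   30 classes. `merge_density()` (integer division by 3) recovers the
   ten-type thematic resolution used for coarse validation, and
   `resample_nearest()` supports the value-preserving 990 m → 1 km step.

Design points the upscaling spec leaves open, fixed here once:

* **Edge blocks** are processed when at least 50 % of the block area lies
  inside the raster, and dropped otherwise — partial blocks carry enough
  cells to estimate a dominant fraction, while slivers would bias it.
* **Modal ties** go to the lowest class code; all orderings in the package
  are deterministic so runs are exactly reproducible.
* **Degenerate types** with fewer than three distinct fraction values cannot
  support two breakpoints; all their cells are classed high density and the
  condition is reported. In practice this affects rare types whose few cells
  are near-pure blocks, for which "high density" is the faithful label.
* **Breakpoint boundaries** are inclusive on the left: density is low for
  `fraction ≤ b1`, medium for `b1 < fraction ≤ b2`, else high.
* **Breaks are global** over the study region, not per basin, so one legend
  describes the whole map.

## Service demand and supply capacity

Demand and supply meet through four *land system services*: cropland,
forest, grassland and shrubland area (km²).

**Demand** comes from integrated-assessment-model (IAM) land tables — per
basin, land type and year. `reclassify_iam_types()` maps the IAM's land-type
vocabulary onto the four services through an editable dictionary (shipped as
YAML); types treated as non-changing (tundra, urban, rocky, snow or ice,
desert) are excluded with a log message, and unknown strings are an error
rather than silently dropped. `aggregate_service_demand()` sums areas per
basin–year–service. Because IAMs conventionally report thousand km² and the
convention is not universal, the reader takes an explicit unit declaration
(`thous_km2`, the default, or `km2`) and converts on ingest. For historical
validation runs, `demand_from_landcover()` instead derives demand from an
observed cover map: the total area of each service's backing cover type.
IAM tables arrive at coarse time steps; `interpolate_demand()` fills
intermediate years linearly, one external iteration per simulation step.

**Supply capacity** `CA[j, d]` (`compute_supply_capacity()`) is the average
area of service *d*'s backing cover type among the fine cells nested inside
coarse cells of land system class *j*. A Cropland_H cell whose 33 × 33 block
is pure cropland supplies 1089 × 900 m² ≈ 0.9801 km² of cropland; a
Forest_M cell typically supplies mostly forest plus smaller amounts of the
other services. This is the many-to-many structure: one class supplies
several services, one service is supplied by several classes.

A design choice worth stating explicitly: capacity rows are **data-driven
for all 30 classes**, including classes dominated by non-service types
(wetland, water, ...). The alternative — zeroing those rows so non-service
classes only participate through the conversion matrix — is available as
`service_classes_only = TRUE`, but it is not the default because it breaks
the books: service area located inside, say, wetland-dominated cells counts
toward demand derived from the fine map yet could never be booked as supply,
leaving a structural under-supply no allocation can close. With data-driven
rows, the supply implied by a map is consistent (up to class-mean
quantization) with the fine-cell areas that define historical demand.

## Location suitability

The probability that a cell converts to class *j* (`P_loc`) is estimated
with a probability random forest (`fit_suitability_model()`, via ranger):
200 trees, each grown on a 25 % subsample drawn without replacement, a
single seed governing subsampling and tree construction, single-threaded so
results are bit-reproducible. Drivers are co-registered raster layers; the
cover-density layers (`compute_density_drivers()` — the within-cell area
proportion of each basic type) join whatever soil/climate/socioeconomic
surrogates are supplied.

The sample-labelling rule deserves care. The literal rule labels set A the
cells *of class j at y1 but not at y2* — i.e. it trains on **losses** of
class j — while the quantity consumed by the allocator is suitability for
conversion *to* j. Both readings are implemented
(`target = "loss"`, the default, and `target = "presence_at_y2"`), the choice
is recorded in the fitted model and run metadata, and the default follows
the literal rule. Additional bounds: class B is optionally downsampled to at
most 10× class A (seeded) to bound memory; a single-label sample set is an
error that names the remedy (augment or skip the class) rather than a silent
degenerate fit.

## The allocation engine

`allocate()` converts cells one at a time until the supply of the four
services meets demand. A candidate conversion of cell *c* to class *j* is
scored by the conversion potential

    P_pot(c, j) = P_loc(c, j) + P_res(T(c)) + P_nei(c, j) + P_comp(c, j)

* `P_loc` — the suitability surface for class *j*.
* `P_res` — conversion resistance of the cell's class at the start of the
  external iteration (`T(c)`): the observed persistence proportion of that
  class between the two calibration dates (`estimate_resistance()`). Classes
  unseen at y1 default to 0.5 (logged). Within a cell the term is constant
  across candidate classes, so — added literally as above — it only affects
  the ordering *across* cells, which is the documented behaviour.
* `P_nei` — neighbourhood effects, weight 0 by default. The hook exists but
  no kernel library is built; comprehensive land-system simulations (unlike
  urban-growth models) have been found to validate better without it.
* `P_comp` — the adaptive competitive advantage,
  `Σ_d inertia_d · (CA[j,d] − CA[u,d]) / Σ_j CA[j,d]`, where *u* is the
  cell's current class. Three readings fixed here: the inertia line is read
  as *accumulation* over internal iterations
  (`inertia_d ← inertia_d + (Demand_d − Supply_d) / speed_i`, with
  `speed_i = seed + (i−1)·step`, defaults seed 1, step 0.001); the stray
  class subscript on the printed inertia symbol is read as a typo for the
  service index; and the reference capacity `CA[u,d]` is the cell's current
  class, which makes `P_comp` the *marginal* service gain of switching —
  the only reading under which the mechanism adapts per cell. The
  normalizing sum runs over all classes with nonzero capacity.

Mechanically, each internal iteration: (1) checks convergence —
`|Supply_d − Demand_d| ≤ max(0.001 · Demand_d, floor)` per service, with the
absolute floor one cell-equivalent of the largest capacity entry
(configurable); (2) updates speed and inertia from the previous supply;
(3) selects, among conversions permitted by the binary conversion matrix
(`derive_conversion_matrix()`: a→b allowed iff observed between the
calibration maps, diagonal forced), the highest-potential candidate that
*strictly reduces the total out-of-tolerance excess*
`Σ_d max(0, |gap_d| − tol_d)`; (4) applies it and logs
(iteration, row, col, from, to). The admission rule is the package's own
closure of an under-specified point: demand-driven conversion must not
wander, and measuring progress as excess-beyond-tolerance (rather than raw
deviation) keeps rebalancing moves admissible — a conversion may shuffle
within-tolerance services freely while closing an out-of-tolerance gap.
Because a nonnegative quantity decreases by a bounded-away-from-zero step
each iteration, termination is guaranteed. Ties in potential are broken by
(row-major cell index, class code), so identical inputs give byte-identical
change logs.

One cell converts per internal iteration — the finest-grained reading of
the iteration scheme, chosen because it makes the engine exactly
reproducible by an independent greedy oracle, which the test suite exploits
on grids up to 15 × 15. After 20 000 coarse iterations without convergence,
a **fine phase** visits each cell at most once in descending best-candidate
potential, applying the best admissible conversion under the then-current
state; if demand still cannot be met the result carries an explicit
non-convergence report (never a silent partial answer). Infeasible demand —
exceeding the best attainable supply when every cell switches to its
highest-capacity class reachable through *chains* of allowed conversions
(transitive closure of the conversion matrix) — is detected before any
iteration.

## Validation

`validate_maps()` scores a simulated map against the observed one at 30- or
10-class thematic resolution (the latter by merging densities first):

* **Cohen's kappa** — chance-corrected overall agreement, with the expected
  agreement under independent marginals (the product-of-marginals
  convention; the verbal definition "correct in the random case" admits
  others, e.g. uniform 1/K, and the convention used is stated rather than
  asserted to be the original authors').
* **Figure of merit** — `B / (A + B + C + D)` over the change components:
  A observed-only change, B change correct in both, C change in both but to
  the wrong class, D simulated-only change. FoM scores *change* prediction
  and is far harsher than kappa when change is rare.

Degenerate cases (single-class tables, no change anywhere) return a typed
`NA` with a reason attribute, never a silent 0.

## The synthetic scene generator

`generate_landscape()` produces the study conditions for every test:
thresholded smoothed Gaussian noise, rank-transformed so quantile cuts
reproduce the target class shares while cells stay spatially autocorrelated
at the requested correlation length (0 gives i.i.d. cells; the suite checks
multinomial shares by chi-square at length 0 and positive Moran's I at
length 4). `generate_drivers()` adds smooth fields plus class-linked signals
of stated effect size, recording the generative links so recovery tests know
ground truth. `generate_transition_pair()` applies explicit rules (from, to,
ranking driver, cell count) and records realized per-class persistence,
closing the loop for the resistance and conversion-matrix estimators.
`generate_demand_trajectory()` emits geometric demand paths in the same CSV
schema the demand reader consumes.

What the generator emulates: multi-class autocorrelated composition,
driver–transition coupling, demand expressed in the same capacity units the
allocator books supply in. What it does not: coastlines and basin geometry,
classification noise in the cover product, non-stationary drivers, and the
scale of real continental runs. Green tests therefore establish the
correctness of the mechanics (counting, classing, scoring, convergence,
determinism) — not the empirical accuracy the method attains on real land
cover, which depends on data that are out of scope here.

## Problem sizes and numerical choices

The shipped test and acceptance runs use deliberately modest scenes — toy
pipelines on 80 × 80 fine cells (window 4 → 20 × 20 land system cells) and a
convergence demonstration on a 100 × 100 land-system grid (300 × 300 fine
cells, window 3, all ten types, four services) — sizes at which every
quantity can be cross-checked against brute-force oracles and the full suite
runs in well under a minute per scene. The convergence scene derives demand
from a target composition reached through known transitions, stated in
capacity units (class counts × CA); this isolates the allocator's
convergence behaviour from the fine-vs-class-mean quantization that any
historical-mode run inherits from its inputs. Numerical details fixed
package-wide: admission and feasibility comparisons use a 10⁻⁹ slack;
fractions and capacities are plain doubles; all areas are km² internally;
rasters interchange as Esri ASCII grids (a plain-text header-plus-matrix
format that round-trips integer rasters exactly), written and read by the
package itself.

## Known limitations

* Georeferencing is passed through, not processed: no reprojection, no CRS
  arithmetic; co-registration is the caller's responsibility and is checked
  only as dimensions + cell size + origin.
* The neighbourhood hook accepts a weight but no kernels are implemented.
* Spatial constraints are a single binary frozen-cell mask.
* The conversion matrix is binary; no per-transition costs or lags.
* Historical-mode runs (demand from fine-cell counts, supply booked through
  class-mean capacities) converge only up to the quantization gap between
  the two accountings; the result object reports the residual per service.
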