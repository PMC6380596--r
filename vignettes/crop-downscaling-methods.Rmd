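---
title: "Methods: spatial downscaling of crop statistics and its robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial downscaling of crop statistics and its robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropalloc)
```

## The problem

Crop production statistics are reported for administrative units —
countries (ADM0), provinces (ADM1), districts (ADM2) — yet most
ecological, economic and climate applications need them on a regular
pixel grid.  Downscaling models bridge the gap by spreading each
reporting unit's harvested area, production and yield over the unit's
pixels.  Every such surface, however, is a *model* of where crops grow,
and its geography depends on the modelling choices made.  `cropalloc`
implements the downscaling machinery together with the apparatus needed
to quantify that dependence: paired allocation runs under controlled
methodological variations, scored for spatial concordance.

Because real source data (subnational statistics, cropland and
suitability rasters) are large and externally hosted, the package ships
a synthetic-landscape generator.  It produces a world whose pixel-level
"truth" is known, aggregates that truth into reporting-unit tables, and
lets every experiment run end to end from a seed.

## The two allocation methods

**Simple method.**  Each unit's harvested area for a crop is spread over
the unit's pixels in proportion to their share of the unit's cropland;
every pixel inherits the unit-average yield; production is their
product.  Crops are allocated independently and no capacity cap is
enforced, so summed crop area may exceed a pixel's cropland — read as
multi-cropping, documented rather than forbidden.  There is no
production-system split: the method operates on pixel-by-crop totals.

**Cross-entropy method.**  Allocation is posed per reporting unit as a
convex program over shares $s_{ijl}$ of crop $j$, production system $l$
(irrigated, rainfed high-input, rainfed low-input, subsistence) in pixel
$i$:

$$\min_s \sum_{j,l}\sum_i s_{ijl}\,\ln\frac{s_{ijl}}{\pi_{ijl}}
\quad\text{s.t.}\quad
\sum_i s_{ijl}=1,\;\;
\sum_{j,l} T_{jl}\,s_{ijl}\le C_i,\;\;
T_{jl}\,s_{ijl}\le U_{ijl},$$

where $T_{jl}$ is the unit's physical-area target (harvested area split
across systems, divided by the cropping intensity), $C_i$ the pixel's
(possibly adjusted) cropland capacity, and $U_{ijl}$ the per-pixel caps:
the suitable area (when the suitability constraint is on) and the
irrigated area for the irrigated system.  The prior
$\pi_{ijl}\propto \text{suitable}_{ijl}\times\text{revenue}_{ijl}
\times\text{access}_{il}$ encodes suitability, potential revenue
(potential yield times price when prices are used) and market access (a
bounded increasing transform of rural population density,
$d/(d+\mathrm{median}\,d)$, inverted for the subsistence system, whose
production tracks rural population rather than market proximity).
Every prior ingredient and constraint is an independent toggle so each
robustness scenario is a one-flag change.

The solver is deterministic block-coordinate ascent on the dual: the
per-(crop, system) mass constraints are restored by exact capped
waterfilling (a sorted breakpoint scan), the per-pixel capacity
multipliers by monotone bisection, iterated to a relative tolerance of
`1e-9` (configurable, `entropy_config()`).  At the optimum
$A_{ijl}=\min\{U_{ijl},\ \beta_{jl}\,\pi_{ijl}T_{jl}\,e^{-\lambda_i
T_{jl}}\}$, which is the KKT form of the program; ties in degenerate
priors cannot arise because the map is single-valued in the duals.  The
test suite checks the solver against `stats::constrOptim` (a generic
adaptive-barrier convex solver) on random small instances.

**Back-conversion.**  Allocated physical area becomes harvested area
via cropping intensities, production via the per-system potential
yields rescaled so each unit/crop production total matches the
statistics exactly, and yield as their ratio.  Conservation per
(unit, crop) is an invariant asserted by tests at `1e-6` relative.

**Cropland adjustment.**  A unit whose reported crops require more
physical area than its cropland would make the program infeasible.  The
adjustment raises capacity minimally: the deficit is first assigned to
spare (non-cropland) land within the unit proportional to spare area,
and only a remainder is spread by uniform scaling; a fully cropped unit
therefore reduces to exact uniform scaling by `required/cropland`.  The
adjustment is flagged per unit, and it is the only mechanism by which a
crop's *presence share* (percent of cropland pixels where the crop
occurs) can exceed 100% — allocation lands on pixels that are not
cropland pixels.  Expansion beyond the configurable `cropland_slack`
(default 2) is a hard error.

## The robustness scenarios

Nine runs: a baseline (cross-entropy, all ingredients on, statistics at
their reported level) and eight variants —

| scenario | change |
|---|---|
| `allocation_method` | simple method instead of cross-entropy |
| `crop_choice` | crops merged into aggregates (areas/production summed, price and cropping intensity area-weighted) |
| `remainder_allocation` | rest-of-crops assigned passively to residual cropland |
| `crop_suitability` | suitability caps removed |
| `market_access` | access weight held constant |
| `crop_price` | prices removed from the prior (all 1 I$/mt) |
| `adm0_only` | statistics degraded to country level |
| `adm1_only` | statistics degraded to (at most) ADM1 |

Two of these are exact fixed points, asserted bitwise in the tests:
`crop_price` when all prices are already 1.0, and `adm1_only` when the
statistics were reported at ADM1.

The passive remainder sets the rest-of-crops physical area *equal to*
each pixel's residual cropland (clipped at zero) — not rescaled to the
reported rest-of-crops area.  Its production is distributed over the
residual so unit production totals stay conserved, but its harvested
area is deliberately not conserved: passivity, not adding-up, is the
phenomenon being modelled.  Negative residuals cannot occur because the
named-crop allocation respects capacity.

## Concordance scoring

Two allocation surfaces $a$ and $b$ are compared per crop and variable
(harvested area, production, yield) in four steps.

1. **Focal smoothing.**  Both rasters are smoothed with Gaussian focal
   weights, by default a 1-pixel radius and 0.33-pixel standard
   deviation.  The radius is three standard deviations because 99.7% of
   an infinite Gaussian's mass lies within 3 sd, so the truncation
   barely distorts the kernel; a larger radius-to-sd ratio would.  The
   smoothing absorbs one-pixel misregistrations that would otherwise
   read as total disagreement.  Edge and mask handling renormalizes the
   kernel over valid in-window pixels (no zero padding), so borders are
   not artificially attenuated.  We smooth all three variables,
   including yields; smoothing only area/production is a defensible
   alternative the config accommodates (`gaussian_kernel(0, 1)` skips
   smoothing entirely).
2. **Pixel similarity.**  $SSI_i = 1 - |a_i - b_i| / \max(a_i, b_i)$,
   bounded in $[0,1]$, symmetric and scale invariant.  Pixels where
   both values are zero (below `1e-6` ha, the package-wide floating
   point guard) carry no information and are excluded; the compared-
   pixel count $n$ is reported.
3. **Crop level.**  The arithmetic mean of $SSI_i$ over the $n$
   compared pixels.
4. **Country level.**  The harvested-area-weighted mean of the crop
   SSIs, weights taken from the *baseline* allocation (the second
   argument of `compare_allocations()`), so that a scenario cannot
   shift its own weighting.

An RMSE-of-regression similarity is provided as `rmse_similarity()` but
deliberately not used in any aggregate: it is unbounded and outlier
dominated.  Moran's I (queen contiguity, row-standardized weights) is
reported per crop and variable as a clustering diagnostic on both
surfaces.

## The synthetic world

`generate_landscape()` grows nested, contiguous administrative units by
seeded multi-source region growing (each unassigned cell attaches to a
random assigned 4-neighbour), and produces a cropland fraction surface
from Gaussian-smoothed noise rescaled to a target mean (default 0.45 of
a 100-ha pixel).  Admin-unit size — the dominant driver of downscaling
sensitivity — is directly scriptable through the unit counts.

`generate_ancillary()` gives each crop its own autocorrelated
suitability field (`exp(sharpness * z)`, normalized), potential yields
positively tied to suitability with per-system multipliers (irrigated
1.5 > rainfed high 1.2 > rainfed low 0.8 > subsistence 0.6), a smooth
rural population surface, and irrigated area bounded by cropland
(mean fraction 0.25).  The normalized suitability has a floor
(default 0.25): a positive floor guarantees that every unit's suitable
area can host any target its own cropland can generate, so the
suitability-constrained baseline is feasible by construction rather
than by luck.  That is a property of the stated world, chosen once from
the capacity arithmetic, not a tuning knob.

`generate_true_allocation()` draws pixel-level physical area
proportional to `cropland * suitability^concentration` (default
concentration 2; 0 reduces to the simple method's geometry), squeezed
iteratively to respect per-pixel cropland exactly, with total demand
0.7 of total cropland split across crops by a seeded Dirichlet draw.
`aggregate_to_sru()` then manufactures the statistics tables the
allocators consume, so allocator-vs-truth recovery is scoreable at any
reporting level.

What the generator does *not* emulate: latitude-dependent pixel areas,
real boundary polygons, reporting gaps and suppressed cells, measurement
error in the statistics, and inter-annual variation.  A green test
therefore establishes internal correctness of the machinery — not that
any real country's surfaces are accurate.

## Numerical choices

* All areas hectares, production metric tons, yields mt/ha; pixels
  column-major, 1-based.
* Presence and non-zero tests use a `1e-6` ha threshold.
* Solver: relative tolerance `1e-9`, 2000-iteration cap,
  non-convergence is an error carrying residuals, never a silent
  result.
* Cropping intensities default to 1.0 everywhere and are configurable
  per crop and system; no country-specific values are assumed.
* System split of harvested area: the unit's irrigated fraction of
  cropland, remainder split 0.35/0.45/0.20 over the rainfed systems
  (configurable in `entropy_config()`).
* Degenerate (all-zero) priors for a crop-system with positive area are
  an error by default; an explicit `degenerate_prior = "cropland"`
  fall-back is available.

## Known limitations

* The prior is a documented, faithful-in-spirit construction
  (suitability x revenue x access); it does not reproduce any specific
  operational model's coefficients, and the entropy objective is per
  (crop, system) rather than joint over crops — the scenario toggles
  are insensitive to that choice.
* The simple method's composite system occupies the first system slot
  of the physical-area array; per-system comparisons against it are not
  meaningful.
* `adm0_only`/`adm1_only` assume statistics tables at a single
  reporting level per run (what `aggregate_to_sru()` produces); mixed
  levels within one table are supported by the allocators but not by
  the degradation fixed-point guarantee.
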