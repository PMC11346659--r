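---
title: "A biogeomorphic slab-lattice model of barrier island evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biogeomorphic slab-lattice model of barrier island evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(barriersim)
```

## The model

`barriersim` simulates the decadal evolution of a barrier island as the
interaction of four processes on a regular lattice of sediment slabs. The
landscape is a grid of cells, each `L = 4` m square, whose surface height is a
count `H(i, j)` of slabs of thickness `delta = 0.1` m. Rows index the
alongshore direction (row 1 north), columns the cross-shore direction with the
ocean on the east (high-column) side; landward migration moves material
toward low columns. Sea level is carried as a continuous offset in meters
above the datum (sea level when the state was created) rather than by
re-quantising `H` — annual rise is one to two orders of magnitude below the
slab thickness — and every elevation comparison goes through
`effective_elevation()`. A cell is *subaerial* when its surface is strictly
above current sea level; cells at exactly sea level count as water, which
removes a zero-area ambiguity from the windowed cover average below.

Four plant species live on the grid as fractional cover fields
`P_k in [0, 1]`: the dune-building grass *Ammophila breviligulata* (viable
1–5 m above sea level), the moderate dune grass *Spartina patens*
(0.75–3 m), the marsh grass *Spartina alterniflora* (−0.5–1 m), and the woody
shrub *Morella cerifera* (above 1.5 m). Vegetation feeds back on every
sediment process through the *effective cover*
`PC = sum_k alpha_k P_k` (clipped to 1), with erosion-inhibition weights
`alpha = (0.667, 0.333, 1, 1)`.

### Annual vegetation dynamics

Once a year each species grows and immigrates:
`P_k <- P_k + gamma_k * (3x3-neighbourhood sum of P_k)`, with `gamma_k` drawn
uniformly from −2% to +8% per year, independently per cell and year and
shared across the nine neighbourhood terms of a cell. The update is clipped
to the per-species cap `eta = (0.8, 0.8, 0.6, 0.6)`. Where total cover
exceeds the global cap `M = 0.8`, the excess is removed in even shares from
the grass species only — the shrub outcompetes the grasses — with any grass
driven below zero floored and its deficit re-spread. Cells whose elevation
leaves a species' viable band lose half of that species' cover per year
(`d_viab = 0.5`; the decay rate is a package choice — the literature states
only that out-of-range cover declines — and is exposed in the
configuration), and covers below `1e-4` are zeroed. Finally the shrub's
bird-carried seeds may found new patches: each subaerial, empty cell at or
above the shrub's minimum elevation gains cover `0.01` with probability
`1e-3` per year, provided any source population exists. Both dispersal
numbers are package defaults (none are published) and are configurable.

### Aeolian transport (every two weeks)

One wind record (speed, direction-of-origin) represents each two-week
period. Every subaerial cell holding sediment loses its top slab with
probability `rho = (1 - PC) * (omega - 6) / (16 - 6)` — zero below the 6 m/s
transport threshold; events above the 16 m/s storm threshold are outside the
model's regime and are skipped with a notice. A moving slab is carried 1, 2,
or 3 cells for winds in [6, 9), [9, 13), [13, 16] m/s, downwind with
probability 0.5 or along either 45-degree off-direction with probability
0.25 each. Pickups are decided synchronously on the pre-event surface;
diagonal distance is counted in cells along the diagonal; slabs may land on
water (building subaqueous relief) and slabs carried off the grid leave the
system (open boundary).

### Avalanching

After any process that moves sediment, slopes steeper than the critical
angle of repose `theta_o = pi/6` relax. The inter-cell angle is computed as
`atan(delta * (H - H') / L)` — the dimensionally consistent slope; the
printed form of the source relation divides a raw slab count by `L * delta`,
which would make a single-slab step a 14-degree slope at the default
geometry, so the package uses the physical form throughout. A violating cell
avalanches one slab onto its steepest von Neumann neighbour with probability
`min(1, (theta/theta_o) * (1 - PC))`. Relaxation passes are evaluated
synchronously on the pass-start surface (the same convention as the aeolian
step; an earlier sequential-visit implementation produced statistically
indistinguishable surfaces at several times the cost) and repeat until no
violation remains or `max_passes = 100` is reached; with vegetation present
termination is only probabilistic, hence the cap. Mass is conserved exactly
and the grid maximum never increases.

### Sea-level rise and landward migration (annual)

Sea level follows a quadratic curve anchored in 1992:
`L(t) = a (t - 1992) + b (t - 1992)^2 + c` cm above the 1984 datum, with
`a = 0.45` cm/yr, `c = 3.6` cm, and `b` equal to 0, 0.0043, 0.0105, or
0.0157 cm/yr² for the historic, low, high, and highest scenarios; growth is
linear before 1992. The annual increment is `S(t) = L(t) - L(t-1)`.

Recession follows a whole-island generalisation of the Bruun rule,
`R = B * S`. By default `B` is calibrated from historical movement,
`B = R_o / S_hist = 15 m/yr / 0.45 cm/yr ≈ 3333`; a profile-geometry mode
(`bruun_coefficient()`) is available when shore-zone lengths, closure depths
and berm heights are known. Vegetation throttles migration through the
windowed migration factor `M_f`: for each row, the mean effective cover over
the subaerial cells of a window spanning `w` rows either side (the
full-scale window half-width is 250 rows; for other grids the package scales
it proportionally to the row count). The per-row landward migration is
`R_i = (1 - alpha_f M_f) B S` with `alpha_f = 1/M_f` at `M_f >= 0.5` — so
migration ceases exactly from half cover upward (the boundary value is
assigned to the ceasing branch, consistent with "0.5 or greater") — and
`alpha_f = 2` below. The rate is realised as rigid landward translation of
each row's height and cover profiles (rollover, consistent with an abundant
sediment supply and the constant simulated width); the whole-cell part of
the accumulated distance is shifted, the fractional remainder carries over
to the next year so nothing is lost to rounding, vacated ocean-side cells
become water, and columns pushed off the landward edge are lost. Plants ride
with the substrate and are subsequently pruned by the viability decay.

### Scheduling

Each simulated year runs, in order: 26 aeolian events (each followed by
relaxation), the annual vegetation update, and the annual marine step
(sea-level increment, windowed migration, relaxation). The within-year order
is a package decision — the source describes the cadences but not the
ordering — chosen so the annual processes act on the wind-worked surface.
All randomness flows from the single configured seed; identical seed,
configuration and initial state give bit-identical trajectories.

## The synthetic island

No real elevation/cover rasters or wind records are distributed, so the
package generates an island with the structure the model assumes
(`island_template()`, `make_island()`, `make_vegetation()`): an elongated
north-south bar with, from ocean to lagoon, a bare beach ramp (0.3-1.2 m
over 8 cells), a 3 m dune ridge, a bare interior platform at 1.2 m, and a
low marsh fringe at 0.4 m; the upper half is narrower (100 cells) with
grasses confined to the dune, while the lower half is wide (180 cells) and
carries a woody shrub terrace at 1.7 m over most of its interior (135
cells) — the classic pairing of a disturbance-reinforcing upper island with
a disturbance-resisting lower island. Elevations are quantised to slabs
with +/-2 slabs of seeded noise; width and relief taper gently at the tips
(relief floor 0.85, so tip rows keep their vegetation bands and stay
subaerial throughout the scenarios).

Several generator choices matter, and each was fixed from an explicit
design condition rather than from simulation output:

* **Cover zonation.** Initial covers (dune grasses 0.35/0.15 on the ridge,
  shrub 0.5 plus grass 0.15 on the terrace, marsh grass 0.35 on the
  fringe) saturate to their caps within a few years under the growth law;
  the zonation is sized so the windowed migration factors sit near the
  values that observed regression rates imply through the migration law —
  a nearly bare upper window and a woody lower window at roughly 0.3-0.45.
* **Terrace at 1.7 m.** The shrub's viability margin above its 1.5 m
  minimum is 0.2 m: the accelerated sea-level curves cross it early
  (highest around 2031, high around 2035, low only in the mid-2040s) while
  the historic curve (0.135 m of rise by 2050) never does. Shrub die-off
  and the consequent release of the lower half is the mechanism that
  amplifies the accelerated scenarios beyond a pure sea-level-rate
  rescaling.
* **Platform at 1.2 m.** The bare interior must neither drown (it keeps
  about half a metre of freeboard under the highest curve, so wind
  deflation does not fragment it into water) nor sit inside the marsh
  grass band (which would let the fringe blanket it over the run: band
  fronts advance roughly one cell per year regardless of island size).
* **Island width.** Vegetation fronts and slab-scale deflation are
  fringe-scale processes with fixed speeds; the island must be wide enough
  that thirty years of them stay fringe effects, as they are on a
  kilometres-wide island. Widths below ~50 cells let the marsh front
  blanket the interior and distort the windowed cover averages.
* **Wind climate.** Weibull speeds (shape 2, scale 8 m/s) put slightly
  over half the draws inside the 6-16 m/s transport window and exercise
  every distance bin. The direction rose is near-balanced cross-shore with
  a slight easterly (onshore) prevalence, so the net wind-driven shoreline
  drift is near zero (about -0.1 m/yr on the default island): the
  recession calibration attributes historical retreat to sea-level rise,
  so the generated climate must not impose a large aeolian drift of its
  own.

The default grid is 200 x 500 cells (alongshore x cross-shore); the
cross-shore extent leaves room for three decades of landward migration
under the highest curve (`B*S` approaches 60 m/yr, 15 cells/yr). The
island occupies rows 9-192; the migration window half-width scales to
`w = 69` rows. Real wind records can substitute for the synthetic climate
via `read_wind_table()`.

What the generator does *not* emulate: storm winds and overwash, tides,
shoreface profile evolution, sediment supply limits, beach moisture and
grain size, groundwater, and the irregular planform of a real island.
Passing tests on the synthetic island therefore validate the process
algebra, conservation laws, and scenario response of the model — not a
hindcast of any real island.

## Scenario experiment

```{r}
ex <- scenario_experiment(island_template(), wind_seeds = 1:3)
ex
```

`scenario_experiment()` builds the default island once, then runs 2020–2050
under the four sea-level scenarios with identical wind seeds, so runs differ
only in the sea-level curve. It reports per-scenario mean annual shoreline
regression (all transects, and the upper/lower halves split at the midpoint
between the island tips, a transect entering an average only if subaerial at
both epochs) and the ratios of each scenario to historic. Under the default
conditions the accelerated-to-historic ratios fall near the sea-level-rise
rate ratios amplified by woody die-off, and the grass-dominated upper half
migrates more than twice as fast as the shrub-protected lower half.

## Numerical choices and degenerate inputs

* Violation threshold: with the defaults, a slope violates from a 24-slab
  (2.4 m) difference between adjacent cells upward.
* `M_f` is 0 when a window contains no subaerial cells; rows with no
  subaerial cells report an absent shoreline (`NA`) and drop out of
  regression averages.
* The migration law is continuous at `M_f = 0.5` (both branches vanish) and
  never negative; the branch point itself ceases migration.
* Fractional-cell migration carries across years exactly; a zero-rate year
  is the identity.
* Covers below `1e-4` after out-of-range decay are zeroed to keep fields
  sparse; in-range cells are preserved bit-exactly.
* Shoreline contours are traced at half a slab (0.05 m) above sea level so
  the 0-level does not degenerate on water cells at exactly sea level.
* Storm-regime winds (> 16 m/s) skip the aeolian event with a notice rather
  than erroring: they are out of the model's scope, not invalid data.

## Problem sizes

The package's own experiments use the 200 × 480 default island: a 30-year
single-scenario run takes on the order of a minute; the four-scenario,
three-seed experiment runs in roughly ten minutes on one core. The
full-scale 728 × 678 lattice is available through `grid_spec()` for users
with real rasters.

## Known limitations

The recession coefficient treats the whole island with one calibrated `B`;
real profiles vary alongshore. Rollover conserves island width by
construction, so width changes observed in nature (driven by overwash and
shoreface erosion, both out of scope) cannot emerge. The marsh grass band
extends to −0.5 m, so submerged marsh retains cover until viability decay
removes it, and newly flooded flats can be colonised from the fringe —
encroachment is slow (one cell per year at the growth defaults) but present
in all scenarios. Wind is sampled i.i.d. per two-week step with no
seasonality or storms.
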