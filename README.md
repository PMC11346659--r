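# barriersim

Cellular biogeomorphic simulation of barrier island evolution under
sea-level rise.

Barrier islands migrate landward ("roll over") as sea level rises, and the
plants that colonise them — dune grasses, marsh grass, woody shrub — slow
every process that moves sand. `barriersim` implements a slab-lattice model
of this interaction for coastal geomorphologists and ecologists who want
whole-island, multi-decade scenario projections: wind moves discrete
sediment slabs (aeolian transport), gravity relaxes over-steep slopes
(angle-of-repose avalanching), and sea-level rise drives Bruun-type
shoreline recession, with each process attenuated by local vegetation
cover.

## The model

The landscape is a lattice `H(i, j)` of slab counts (slab = 0.1 m x 4 m x
4 m); four species covers `P_k(i, j)` in `[0, 1]` grow by
`P_k <- P_k + gamma_k * sum_{3x3} P_k` (`gamma_k ~ U(-0.02, 0.08)` per
year), compete under a global cap that favours the woody species, and
decay outside species-specific elevation bands. Sediment processes see the
effective cover `PC = sum_k alpha_k P_k`:

* aeolian: a subaerial cell's top slab moves with probability
  `rho = (1 - PC) (omega - omega_L) / (omega_H - omega_L)`, carried 1-3
  cells downwind by wind-speed class (6-16 m/s), 50% downwind / 25% each
  off-diagonal, every two weeks;
* avalanche: slopes with `atan(delta dH / L) >= pi/6` shed slabs with
  probability `min(1, (theta/theta_o)(1 - PC))` until stable;
* marine (annual): sea level follows
  `L(t) = a (t-1992) + b (t-1992)^2 + c` (four scenarios: historic, low,
  high, highest), and each alongshore row migrates landward at
  `R_i = (1 - alpha_f M_f) B S(t)`, where `M_f` is the mean cover over the
  subaerial cells of a 2w+1-row moving window, `alpha_f` makes migration
  cease at `M_f >= 0.5`, and `B` is calibrated from a 15 m/yr historical
  retreat rate.

A synthetic-island generator produces a dune-ridge barrier island with a
grass-dominated upper half, a woody (shrub) lower half, and a back-barrier
marsh fringe, plus a Weibull wind climate, so everything is testable
without external data. See the methods vignette
(`vignettes/barrier-island-model.Rmd`) for assumptions, parameter tables,
and design rationale.

## Worked example

```r
library(barriersim)

tpl    <- island_template()                 # 200 x 500 desk-scale island
island <- make_vegetation(make_island(tpl), tpl)
island
#> island_state: 200 x 500 cells, year 0.00, sea level offset 0.000 m
#>   subaerial cells: 24507 (24.5%); max elevation 3.20 m; total slabs 348824

ex <- scenario_experiment(tpl, wind_seeds = c(101, 202, 303))
ex
#> Scenario experiment, 2020-2050, 3 wind seed(s)
#> Mean annual shoreline regression (m/yr):
#>  scenario   all upper lower
#>  historic  7.62  10.3  4.99
#>       low 13.74  18.7  8.81
#>      high 22.15  30.5 13.80
#>   highest 28.76  39.8 17.71
#> Ratios:
#>    historic_to_historic         low_to_historic        high_to_historic
#>                   1.000                   1.802                   2.905
#>     highest_to_historic upper_to_lower_historic
#>                   3.772                   2.055
```

Reading the table: under the historic (non-accelerating) sea-level curve
the eastern shoreline retreats 7.6 m/yr on average over 2020-2050; the
grass-dominated upper half (10.3 m/yr) moves about twice as fast as the
shrub-protected lower half (5.0 m/yr). Accelerating sea-level rise roughly
doubles the retreat under the low scenario and amplifies it nearly
four-fold under the highest, where rising water also pushes the woody
terrace below its viability band and releases the lower half. Single runs
are available through `run_simulation()`, whose result has `print`,
`summary`, and `plot` (shoreline contour overlay) methods; rasters and
wind tables read/write through `read_ascii_grid()`/`write_state()` and
`read_wind_table()`. A thin command-line front end lives at
`inst/cli/barriersim.R` (subcommands `simulate`, `make-island`,
`scenarios`, `report`).

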