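#' Simulation configuration
#'
#' Bundles every tunable of a run. Defaults follow the standard
#' parameterisation: global cover cap 0.8, transport window 6-16 m/s,
#' critical repose angle pi/6, recession coefficient calibrated from a 15 m/yr
#' initial retreat against the 0.45 cm/yr historic rise, 26 two-week aeolian
#' events per year, and an alongshore migration window of half-width `w` rows
#' (the full-scale value is 250; pass `w = NULL` to scale it proportionally
#' to the island's row count).
#'
#' @param species list of four [species_params()].
#' @param M global cover cap in `(0, 1]`.
#' @param wind a [wind_climate()] or a data frame of records with columns
#'   `speed` and `direction` sampled per event.
#' @param scenario an [slr_scenario()].
#' @param B recession coefficient; `NULL` calibrates `R_o / S_ref`.
#' @param R_o,S_ref calibration pair (m/yr observed retreat, m/yr reference
#'   rise).
#' @param w migration-window half-width in rows; `NULL` scales 250 rows by
#'   `n_rows / 728` at run time.
#' @param start_year,end_year simulated span (`end_year > start_year`).
#' @param seed RNG seed governing all randomness of the run.
#' @param snapshot_years years at which full states are kept (default start,
#'   midpoint, end).
#' @param events_per_year aeolian events per year (two-week cadence).
#' @param omega_L,omega_H transport and storm wind thresholds (m/s).
#' @param repose a [repose_params()].
#' @param d_viab,p_disp,p_seed_cover vegetation parameters, see
#'   [viability_update()] and [distant_dispersal()].
#' @param processes named logical vector enabling the `aeolian`,
#'   `vegetation`, and `marine` process groups (the scheduler alone is a
#'   fixed point when all are off).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(species = default_species(), M = 0.8,
                              wind = wind_climate(),
                              scenario = slr_scenario("historic"),
                              B = NULL, R_o = 15, S_ref = 0.0045,
                              w = NULL,
                              start_year = 2020, end_year = 2050,
                              seed = 1L,
                              snapshot_years = NULL,
                              events_per_year = 26L,
                              omega_L = 6, omega_H = 16,
                              repose = repose_params(),
                              d_viab = 0.5, p_disp = 1e-3,
                              p_seed_cover = 0.01,
                              processes = c(aeolian = TRUE, vegetation = TRUE,
                                            marine = TRUE)) {
  stopifnot(M > 0, M <= 1, end_year >= start_year, is.null(w) || w >= 0)
  if (is.null(B)) B <- calibrate_bruun(R_o, S_ref)
  structure(list(species = species, M = M, wind = wind, scenario = scenario,
                 B = B, w = w, start_year = start_year, end_year = end_year,
                 seed = as.integer(seed), snapshot_years = snapshot_years,
                 events_per_year = as.integer(events_per_year),
                 omega_L = omega_L, omega_H = omega_H, repose = repose,
                 d_viab = d_viab, p_disp = p_disp,
                 p_seed_cover = p_seed_cover, processes = processes),
            class = "simulation_config")
}

.draw_winds <- function(wind, n_events) {
  ws <- if (inherits(wind, "wind_climate")) {
    wind_series(wind, n_events)
  } else {
    wind[sample.int(nrow(wind), n_events, replace = TRUE), ]
  }
  lapply(seq_len(n_events),
         function(e) wind_record(ws$speed[e], as.character(ws$direction[e])))
}

#' Run a multi-year simulation
#'
#' The master scheduler. Each simulated year executes, in order: the
#' configured number of two-week aeolian events (each followed by avalanche
#' relaxation), one annual vegetation update (growth, dispersal, crowding,
#' viability), and one annual marine step (sea-level increment, windowed
#' migration, relaxation). State invariants are checked after every process;
#' a violation aborts with a diagnostic naming the step. Identical seed,
#' configuration, and initial state give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param initial the initial `island_state`.
#' @param verbose print a one-line log per simulated year (slabs moved by
#'   avalanching, cells shifted by migration, mean shoreline).
#' @return an object of class `island_sim` with elements `config`, `initial`,
#'   `final`, `snapshots` (list by year), `years`, `positions` (transect x
#'   year shoreline matrix), `split`, and `report` (a [migration_report()]).
#' @export
run_simulation <- function(config, initial, verbose = FALSE) {
  validate_island_state(initial, config$species, config$M, step = "input")
  set.seed(config$seed)
  state <- initial
  state$t <- config$start_year
  n <- state$grid$n_rows
  w <- if (is.null(config$w)) as.integer(round(250 * n / 728)) else config$w
  years <- config$start_year:config$end_year
  snap_years <- config$snapshot_years
  if (is.null(snap_years)) {
    snap_years <- unique(round(c(config$start_year,
                                 (config$start_year + config$end_year) / 2,
                                 config$end_year)))
  }
  positions <- matrix(NA_real_, n, length(years),
                      dimnames = list(NULL, years))
  positions[, 1] <- shoreline_position(state)
  split <- tryCatch(split_rows(state), error = function(e) NULL)
  snapshots <- list()
  if (config$start_year %in% snap_years)
    snapshots[[as.character(config$start_year)]] <- state
  carry <- numeric(n)
  on <- config$processes

  if (config$end_year > config$start_year) {
    for (year in (config$start_year + 1):config$end_year) {
      slabs_av <- 0L
      if (isTRUE(on[["aeolian"]])) {
        # covers change only at the annual vegetation update: cache PC
        PC <- effective_cover(state$P, species_alphas(config$species))
        winds <- .draw_winds(config$wind, config$events_per_year)
        for (e in seq_len(config$events_per_year)) {
          state <- aeolian_event(state, winds[[e]], config$species,
                                 config$omega_L, config$omega_H, PC = PC)
          state <- relax(state, config$repose, config$species, PC = PC)
          slabs_av <- slabs_av + attr(state, "slabs_moved")
        }
        validate_island_state(state, step = paste0("aeolian year ", year))
      }
      if (isTRUE(on[["vegetation"]])) {
        state <- vegetation_annual_step(state, config$species, config$M,
                                        config$d_viab, config$p_disp,
                                        config$p_seed_cover)
        validate_island_state(state, config$species, config$M,
                              step = paste0("vegetation year ", year))
      }
      if (isTRUE(on[["marine"]])) {
        res <- annual_marine_step(state, year, config$scenario,
                                  config$species, config$B, w, carry,
                                  config$repose)
        state <- res$state
        carry <- res$carry
        validate_island_state(state, step = paste0("marine year ", year))
      }
      state$t <- year
      positions[, year - config$start_year + 1] <- shoreline_position(state)
      if (verbose)
        message(sprintf(
          "year %d: avalanched %d slabs, sea level %+0.3f m, mean shoreline %.0f m",
          year, slabs_av, state$sea_level_offset,
          mean(positions[, year - config$start_year + 1], na.rm = TRUE)))
      if (year %in% snap_years) snapshots[[as.character(year)]] <- state
    }
  }

  report <- if (!is.null(split) && length(years) > 1) {
    snap_idx <- match(intersect(snap_years, years), years)
    migration_report(positions[, snap_idx, drop = FALSE],
                     years[snap_idx], split, state$grid$L)
  } else NULL
  structure(list(config = config, initial = initial, final = state,
                 snapshots = snapshots, years = years, positions = positions,
                 split = split, report = report, w = w),
            class = "island_sim")
}

#' @export
print.island_sim <- function(x, ...) {
  cat(sprintf("island_sim: %d-year run (%d-%d), scenario '%s', seed %d\n",
              x$config$end_year - x$config$start_year,
              x$config$start_year, x$config$end_year,
              x$config$scenario$name, x$config$seed))
  print(x$final)
  invisible(x)
}

#' @export
summary.island_sim <- function(object, ...) {
  if (!is.null(object$report)) print(object$report)
  else cat("no migration report (zero-length run or empty island)\n")
  invisible(object$report)
}

#' @export
plot.island_sim <- function(x, levels = NULL, ...) {
  export_contours(x$snapshots, levels = levels, plot = TRUE)
  invisible(x)
}

#' Scenario comparison experiment
#'
#' Runs the same initial island under several sea-level-rise scenarios with
#' identical wind seeds and summarises per-scenario all-transect mean annual
#' regression, the upper/lower split, and ratios against the historic
#' scenario. With several wind seeds the reported rates are seed means.
#'
#' @param template an [island_template()] used to build the island (once).
#' @param scenarios scenario names to run.
#' @param start_year,end_year simulated span.
#' @param wind_seeds integer vector of RNG seeds; each seed is shared across
#'   scenarios so runs differ only in the sea-level curve.
#' @param ... further arguments passed to [simulation_config()].
#' @return an object of class `scenario_experiment`: list with `table`
#'   (scenario x {all, upper, lower} mean regression in m/yr), `ratios`
#'   (each scenario's all-transect rate over historic, plus historic
#'   upper/lower), and `runs` (per-seed rates).
#' @export
scenario_experiment <- function(template = island_template(),
                                scenarios = c("historic", "low", "high", "highest"),
                                start_year = 2020, end_year = 2050,
                                wind_seeds = 1L, ...) {
  island <- make_vegetation(make_island(template), template)
  span <- end_year - start_year
  runs <- expand.grid(seed = wind_seeds, scenario = scenarios,
                      stringsAsFactors = FALSE)
  rates <- lapply(seq_len(nrow(runs)), function(r) {
    cfg <- simulation_config(scenario = slr_scenario(runs$scenario[r]),
                             start_year = start_year, end_year = end_year,
                             seed = runs$seed[r], ...)
    sim <- run_simulation(cfg, island)
    p0 <- sim$positions[, 1]
    p1 <- sim$positions[, ncol(sim$positions)]
    c(all = mean_annual_regression(p0, p1, 0, span),
      upper = mean_annual_regression(p0, p1, 0, span, sim$split$upper),
      lower = mean_annual_regression(p0, p1, 0, span, sim$split$lower))
  })
  runs <- cbind(runs, do.call(rbind, rates))
  tab <- do.call(rbind, lapply(scenarios, function(sc) {
    m <- colMeans(runs[runs$scenario == sc, c("all", "upper", "lower")])
    data.frame(scenario = sc, all = m["all"], upper = m["upper"],
               lower = m["lower"], row.names = NULL)
  }))
  hist_all <- tab$all[tab$scenario == "historic"]
  if (!length(hist_all)) hist_all <- NA_real_
  ratios <- c(stats::setNames(tab$all / hist_all, paste0(tab$scenario, "_to_historic")),
              upper_to_lower_historic =
                tab$upper[tab$scenario == "historic"] /
                tab$lower[tab$scenario == "historic"])
  structure(list(table = tab, ratios = ratios, runs = runs,
                 start_year = start_year, end_year = end_year),
            class = "scenario_experiment")
}

#' @export
print.scenario_experiment <- function(x, ...) {
  cat(sprintf("Scenario experiment, %d-%d, %d wind seed(s)\n",
              x$start_year, x$end_year, length(unique(x$runs$seed))))
  cat("Mean annual shoreline regression (m/yr):\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("Ratios:\n")
  print(round(x$ratios, 3))
  invisible(x)
}
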