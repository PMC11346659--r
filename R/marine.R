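#' Sea-level-rise scenario
#'
#' Quadratic sea-level curve relative to the 1984 datum:
#' `L(t) = a (t - 1992) + b (t - 1992)^2 + c` for `t >= 1992`, with linear
#' growth at rate `a` through the same 1992 anchor before the acceleration
#' start. `a = 0.45` cm/yr is the historic rate, `c = 3.6` cm the 1992
#' intercept; the quadratic coefficient distinguishes the four named
#' scenarios: historic (`b = 0`), low (0.0043), high (0.0105), and highest
#' (0.0157) cm/yr^2.
#'
#' @param name one of `"historic"`, `"low"`, `"high"`, `"highest"`, or
#'   `"custom"`.
#' @param a linear rate (cm/yr).
#' @param b quadratic coefficient (cm/yr^2); overrides the named value.
#' @param c intercept at the acceleration start (cm).
#' @param accel_start_year year the quadratic term switches on.
#' @param reference_year datum year (sea level zero).
#' @return an object of class `slr_scenario`.
#' @export
slr_scenario <- function(name = c("historic", "low", "high", "highest", "custom"),
                         a = 0.45, b = NULL, c = 3.6,
                         accel_start_year = 1992, reference_year = 1984) {
  name <- match.arg(name)
  if (is.null(b))
    b <- switch(name, historic = 0, low = 0.0043, high = 0.0105,
                highest = 0.0157, custom = 0)
  stopifnot(a >= 0, b >= 0)
  structure(list(name = name, a = a, b = b, c = c,
                 accel_start_year = accel_start_year,
                 reference_year = reference_year),
            class = "slr_scenario")
}

#' Sea level above the datum
#'
#' Evaluates the scenario curve at year `t`, in centimeters above the
#' reference-year (1984) sea level. Before the acceleration start the curve is
#' linear at rate `a` through the same anchor, so `L(1984) = 0` with the
#' default coefficients.
#'
#' @param scenario an [slr_scenario()].
#' @param year calendar year (vectorised); must be at or after the reference
#'   year.
#' @return sea level in cm.
#' @examples
#' sea_level(slr_scenario("highest"), 2050)  # 82.51 cm
#' @export
sea_level <- function(scenario, year) {
  if (any(year < scenario$reference_year))
    stop("year before the ", scenario$reference_year, " datum")
  dt <- year - scenario$accel_start_year
  b <- ifelse(year >= scenario$accel_start_year, scenario$b, 0)
  scenario$a * dt + b * dt^2 + scenario$c
}

#' Annual sea-level increment
#'
#' `S(t) = L(t) - L(t - 1)`, in cm/yr.
#'
#' @param scenario an [slr_scenario()].
#' @param year calendar year (vectorised), at least one year after the datum.
#' @return increment in cm/yr.
#' @export
slr_increment <- function(scenario, year) {
  sea_level(scenario, year) - sea_level(scenario, year - 1)
}

#' Whole-island recession coefficient from profile geometry
#'
#' The generalised Bruun proportionality between recession rate and sea-level
#' rise, `R = B * S`, with
#' `B = (L_0 + W + L_L) / ((B_0 + hb_0) - (B_L + hb_L))`: total active profile
#' length over the net elevation drop between the ocean-side and lagoon-side
#' active zones.
#'
#' @param W island width (m).
#' @param L0,LL active shore-zone lengths on the ocean and lagoon sides (m).
#' @param hb0,hbL closure depths at the ends of the active zones (m).
#' @param B0,BL berm heights on the ocean and lagoon sides (m).
#' @return the dimensionless coefficient `B`.
#' @export
bruun_coefficient <- function(W, L0, LL, hb0, hbL, B0, BL) {
  stopifnot(W >= 0, L0 >= 0, LL >= 0, hb0 >= 0, hbL >= 0, B0 >= 0, BL >= 0)
  den <- (B0 + hb0) - (BL + hbL)
  if (den == 0) stop("degenerate profile: zero net elevation drop")
  (L0 + W + LL) / den
}

#' Calibrate the recession coefficient from an observed retreat rate
#'
#' `B = R_o / S_ref`: the historically observed initial retreat rate divided
#' by the contemporaneous rate of sea-level rise. With the defaults (15 m/yr
#' retreat against the 0.45 cm/yr historic rise) `B ~= 3333`.
#'
#' @param R_o observed shoreline retreat rate (m/yr).
#' @param S_ref reference sea-level-rise rate (m/yr).
#' @return the dimensionless coefficient `B`.
#' @export
calibrate_bruun <- function(R_o = 15, S_ref = 0.0045) {
  stopifnot(S_ref > 0)
  R_o / S_ref
}

#' Windowed migration factor
#'
#' For each alongshore row, the mean effective plant cover over the subaerial
#' cells of a moving window spanning `w` rows above and below (truncated at
#' the grid edges) and the full cross-shore extent. Rows whose window holds no
#' subaerial cells get 0. This is the vegetation term that throttles
#' sea-level-driven migration.
#'
#' @param state an `island_state`.
#' @param species list of four [species_params()] (erosion coefficients).
#' @param w window half-width in rows.
#' @param rows rows to evaluate (default all).
#' @return numeric vector of `M_f` values in `[0, 1]`.
#' @export
migration_factor <- function(state, species, w, rows = NULL) {
  n <- state$grid$n_rows
  if (is.null(rows)) rows <- seq_len(n)
  sub <- subaerial_mask(state)
  PC <- effective_cover(state$P, species_alphas(species))
  num_r <- rowSums(PC * sub)
  den_r <- rowSums(sub)
  cs_num <- c(0, cumsum(num_r))
  cs_den <- c(0, cumsum(den_r))
  lo <- pmax(rows - w, 1L)
  hi <- pmin(rows + w, n)
  num <- cs_num[hi + 1L] - cs_num[lo]
  den <- cs_den[hi + 1L] - cs_den[lo]
  ifelse(den > 0, num / den, 0)
}

#' Per-row landward migration rate
#'
#' `R_i = (1 - alpha_f * M_f) * B * S`, where the adjustment factor
#' `alpha_f` is `1 / M_f` for `M_f >= 0.5` (migration ceases exactly) and 2
#' below; the rate falls linearly with windowed cover and is zero from half
#' cover upward, never negative.
#'
#' @param M_f windowed migration factor(s) in `[0, 1]`.
#' @param B recession coefficient (see [calibrate_bruun()]).
#' @param S sea-level-rise rate in m/yr (consistent with `B`'s calibration).
#' @return migration rate(s) in m/yr.
#' @examples
#' row_migration(0.25, 3333.33, 0.0045)  # half the unvegetated rate
#' @export
row_migration <- function(M_f, B, S) {
  stopifnot(all(M_f >= 0), all(M_f <= 1), B >= 0)
  ifelse(M_f >= 0.5, 0, (1 - 2 * M_f) * B * S)
}

#' Apply landward migration to the lattice
#'
#' Realises each row's migration rate as rigid landward translation
#' (rollover): the row's slab and cover profiles shift toward low columns by
#' the whole-cell part of the accumulated distance, the fractional remainder
#' carries over to the next year, vacated ocean-side cells become water, and
#' columns pushed off the landward edge are lost. The caller runs avalanche
#' [relax()] afterwards.
#'
#' @param state an `island_state`.
#' @param R per-row migration rates (m/yr), all >= 0.
#' @param carry per-row carried-over distance from previous years (m).
#' @return `list(state = updated state, carry = updated carry)`.
#' @export
apply_migration <- function(state, R, carry = NULL) {
  n <- state$grid$n_rows; m <- state$grid$n_cols
  if (is.null(carry)) carry <- numeric(n)
  stopifnot(length(R) == n, length(carry) == n, all(R >= 0))
  total <- R + carry
  shift <- floor(total / state$grid$L)
  carry <- total - shift * state$grid$L
  for (i in which(shift > 0)) {
    s <- shift[i]
    if (s >= m) {
      state$H[i, ] <- 0L
      for (k in 1:4) state$P[[k]][i, ] <- 0
    } else {
      keep <- (s + 1):m
      state$H[i, ] <- c(state$H[i, keep], rep(0L, s))
      for (k in 1:4) state$P[[k]][i, ] <- c(state$P[[k]][i, keep], rep(0, s))
    }
  }
  list(state = state, carry = carry)
}

#' One annual marine step
#'
#' Raises the sea-level offset by this year's scenario increment, evaluates
#' the windowed migration factor and per-row migration rates, translates the
#' lattice landward accordingly, and relaxes slopes.
#'
#' @param state an `island_state`.
#' @param year calendar year being completed.
#' @param scenario an [slr_scenario()].
#' @param species list of four [species_params()].
#' @param B recession coefficient (calibrated in m/yr per m/yr of rise).
#' @param w window half-width in rows.
#' @param carry per-row carry-over distances (m).
#' @param repose a [repose_params()].
#' @return `list(state, carry)` as in [apply_migration()].
#' @export
annual_marine_step <- function(state, year, scenario, species, B, w,
                               carry = NULL, repose = repose_params()) {
  S_m <- slr_increment(scenario, year) / 100
  state$sea_level_offset <- state$sea_level_offset + S_m
  M_f <- migration_factor(state, species, w)
  R <- row_migration(M_f, B, S_m)
  res <- apply_migration(state, R, carry)
  res$state <- relax(res$state, repose, species)
  res
}
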