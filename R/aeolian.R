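#' Eight compass points
#'
#' Direction labels used throughout: `"N"`, `"NE"`, `"E"`, `"SE"`, `"S"`,
#' `"SW"`, `"W"`, `"NW"`. On the lattice, row 1 is the northern edge and high
#' columns are the eastern (ocean) side.
#' @export
COMPASS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

# (row, col) unit steps for each compass point; row 1 is north, high columns
# are east. Diagonal distance is counted in cells along the diagonal.
.dir_dr <- c(N = -1L, NE = -1L, E = 0L, SE = 1L, S = 1L, SW = 1L, W = 0L, NW = -1L)
.dir_dc <- c(N =  0L, NE =  1L, E = 1L, SE = 1L, S = 0L, SW = -1L, W = -1L, NW = -1L)

opposite_direction <- function(dir) COMPASS[(match(dir, COMPASS) + 3L) %% 8L + 1L]

#' Wind record
#'
#' One sampled wind event: speed in m/s and the compass direction the wind
#' blows *from* (meteorological convention), one of the eight points in
#' `COMPASS`. Transport is directed downwind, i.e. toward the opposite point.
#'
#' @param speed wind speed in m/s (>= 0).
#' @param direction one of `"N"`, `"NE"`, ..., `"NW"` (direction of origin).
#' @return an object of class `wind_record`.
#' @export
wind_record <- function(speed, direction) {
  stopifnot(speed >= 0, direction %in% COMPASS)
  structure(list(speed = speed, direction = direction), class = "wind_record")
}

#' Downwind transport distance
#'
#' Number of cells a moving slab is carried, binned by wind speed: 0 below
#' 6 m/s, 1 for 6-9, 2 for 9-13, 3 for 13-16 m/s. Winds above 16 m/s belong to
#' the storm regime and are not handled by the aeolian process.
#'
#' @param omega wind speed in m/s.
#' @param omega_H storm threshold (m/s); speeds above it return `NA` so the
#'   caller can skip the event.
#' @return integer cell count (or `NA` for storm winds).
#' @export
transport_distance <- function(omega, omega_H = 16) {
  stopifnot(omega >= 0)
  if (omega > omega_H) return(NA_integer_)
  if (omega < 6) 0L else if (omega < 9) 1L else if (omega < 13) 2L else 3L
}

#' Probability that a surface slab moves
#'
#' Linear in wind speed between the transport threshold and the storm
#' threshold, attenuated by effective plant cover:
#' `rho = (1 - PC) * (omega - omega_L) / (omega_H - omega_L)`, clipped to
#' `[0, 1]` (zero below `omega_L`).
#'
#' @param PC effective plant cover in `[0, 1]` (scalar or matrix).
#' @param omega wind speed (m/s).
#' @param omega_L minimum transporting wind speed (m/s).
#' @param omega_H storm threshold (m/s).
#' @return movement probability, same shape as `PC`.
#' @examples
#' move_probability(0.5, 11)  # 0.25
#' @export
move_probability <- function(PC, omega, omega_L = 6, omega_H = 16) {
  stopifnot(omega_L < omega_H)
  rho <- (1 - PC) * (omega - omega_L) / (omega_H - omega_L)
  pmin(pmax(rho, 0), 1)
}

#' Sample the destination direction of a moving slab
#'
#' A moving slab travels downwind with probability 0.5, or toward either of
#' the two 45-degree off-directions with probability 0.25 each (e.g. wind from
#' the west sends slabs east, northeast, or southeast).
#'
#' @param wind_direction compass point the wind blows from.
#' @param n number of independent draws.
#' @return character vector of destination compass points.
#' @export
sample_destination_direction <- function(wind_direction, n = 1) {
  down <- opposite_direction(wind_direction)
  i <- match(down, COMPASS)
  lobes <- COMPASS[c(i, (i %% 8L) + 1L, ((i - 2L) %% 8L) + 1L)]
  lobes[sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))]
}

#' One two-week aeolian transport event
#'
#' Every subaerial cell holding at least one slab loses its top slab with
#' probability [move_probability()] evaluated on the pre-event surface; the
#' slab is carried [transport_distance()] cells along a direction drawn by the
#' 50/25/25 rule and deposited there (also onto water cells, building
#' subaqueous relief). Pickups are decided synchronously on the pre-event
#' state; slabs carried off the grid leave the system (open boundary). Storm
#' winds (speed above `omega_H`) skip the event with a message. The caller is
#' expected to run avalanche [relax()] afterwards.
#'
#' @param state an `island_state`.
#' @param wind a [wind_record()].
#' @param species list of four [species_params()] (for erosion coefficients).
#' @param omega_L,omega_H transport and storm wind-speed thresholds (m/s).
#' @param PC optional precomputed effective-cover matrix (covers change only
#'   at the annual vegetation update, so callers may cache it).
#' @return the updated state.
#' @export
aeolian_event <- function(state, wind, species, omega_L = 6, omega_H = 16,
                          PC = NULL) {
  if (wind$speed > omega_H) {
    message(sprintf("aeolian event skipped: wind %.1f m/s exceeds storm threshold %.1f m/s",
                    wind$speed, omega_H))
    return(state)
  }
  d <- transport_distance(wind$speed, omega_H)
  if (d == 0L) return(state)
  H <- state$H
  n <- nrow(H); m <- ncol(H)
  hmin <- max(1L, as.integer(floor(state$sea_level_offset / state$grid$delta)) + 1L)
  cand <- which(H >= hmin)
  if (!length(cand)) return(state)
  if (is.null(PC)) PC <- effective_cover(state$P, species_alphas(species))
  rho <- move_probability(PC[cand], wind$speed, omega_L, omega_H)
  moving <- cand[stats::runif(length(cand)) < rho]
  if (!length(moving)) return(state)
  down <- opposite_direction(wind$direction)
  i <- match(down, COMPASS)
  lobes <- COMPASS[c(i, (i %% 8L) + 1L, ((i - 2L) %% 8L) + 1L)]
  pick <- sample.int(3L, length(moving), replace = TRUE, prob = c(0.5, 0.25, 0.25))
  dest_dir <- lobes[pick]

  r <- ((moving - 1L) %% n) + 1L
  c <- ((moving - 1L) %/% n) + 1L
  dr <- .dir_dr[dest_dir] * d
  dc <- .dir_dc[dest_dir] * d
  rr <- r + dr; cc <- c + dc
  inside <- rr >= 1L & rr <= n & cc >= 1L & cc <= m

  H[moving] <- H[moving] - 1L
  if (any(inside)) {
    dest <- (cc[inside] - 1L) * n + rr[inside]
    H <- H + tabulate(dest, nbins = n * m)
  }
  storage.mode(H) <- "integer"
  state$H <- H
  state
}
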