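#' Synthetic island template
#'
#' Parameters of the generated barrier island: an elongated north-south bar
#' with, from ocean (east) to lagoon (west), a bare beach ramp, a dune ridge,
#' an interior platform (carrying an elevated woody-shrub terrace in the lower
#' half by default), and a low back-barrier marsh fringe. The upper half is
#' narrower and grass-dominated, the lower half wider with woody vegetation --
#' the configuration of a disturbance-reinforcing upper island over a
#' disturbance-resisting lower island. All lengths in cells unless noted.
#'
#' @param grid a [grid_spec()]; default is a desk-scale 200 x 500 lattice
#'   (the cross-shore extent leaves room for three decades of landward
#'   migration under the accelerated sea-level scenarios).
#' @param row_margin water rows at the northern and southern edges (>= 2).
#' @param shore_margin water columns east of the shoreline (>= 2).
#' @param width_upper,width_lower island width in the upper / lower half
#'   (blended linearly over the ten rows around the split).
#' @param beach_width,ridge_width widths of the beach ramp and dune ridge.
#' @param marsh_width_upper,marsh_width_lower marsh fringe width per half
#'   (blended like the island width).
#' @param beach_top elevation at the top of the beach ramp (m).
#' @param ridge_height dune ridge crest elevation (m, > 0).
#' @param platform_elev interior platform elevation (m).
#' @param terrace_elev elevated interior terrace elevation (m).
#' @param terrace_width_upper,terrace_width_lower terrace width per half
#'   (0 disables the terrace in that half).
#' @param marsh_elev marsh fringe elevation (m).
#' @param taper_rows rows over which width and height taper at the island
#'   tips.
#' @param noise_amp amplitude of integer elevation noise (slabs).
#' @param seed RNG seed for the noise.
#' @return an object of class `island_template`.
#' @export
island_template <- function(grid = grid_spec(200, 500),
                            row_margin = 8, shore_margin = 22,
                            width_upper = 100, width_lower = 180,
                            beach_width = 8, ridge_width = 5,
                            marsh_width_upper = 2, marsh_width_lower = 6,
                            beach_top = 1.2, ridge_height = 3,
                            platform_elev = 1.2, terrace_elev = 1.7,
                            terrace_width_upper = 0, terrace_width_lower = 135,
                            marsh_elev = 0.4,
                            taper_rows = 8, noise_amp = 2, seed = 42) {
  stopifnot(row_margin >= 2, shore_margin >= 2, ridge_height > 0,
            max(width_upper, width_lower) + shore_margin + 2 <= grid$n_cols,
            2 * row_margin + 4 <= grid$n_rows)
  structure(as.list(environment()), class = "island_template")
}

# Deterministic geometry shared by make_island and make_vegetation:
# continuous elevation surface plus a zone code per cell
# (0 water, 1 beach, 2 dune, 3 terrace, 4 platform, 5 marsh).
.island_geometry <- function(tpl) {
  g <- tpl$grid
  n <- g$n_rows; m <- g$n_cols
  first <- tpl$row_margin + 1L
  last <- n - tpl$row_margin
  split_row <- (first + last) %/% 2L
  shore_col <- m - tpl$shore_margin

  elev <- matrix(0, n, m)
  zone <- matrix(0L, n, m)
  for (i in first:last) {
    # blend half parameters over the ten rows around the split
    lam <- min(max((i - split_row + 5) / 10, 0), 1)
    W <- tpl$width_upper + lam * (tpl$width_lower - tpl$width_upper)
    tw <- tpl$terrace_width_upper +
      lam * (tpl$terrace_width_lower - tpl$terrace_width_upper)
    mw_t <- as.integer(round(tpl$marsh_width_upper +
      lam * (tpl$marsh_width_lower - tpl$marsh_width_upper)))
    # taper width and relief toward the nearest tip
    tip_dist <- min(i - first, last - i)
    f <- if (tip_dist < tpl$taper_rows) (tip_dist + 1) / (tpl$taper_rows + 1) else 1
    W <- max(6L, as.integer(round(W * f)))
    # relief tapers only gently so tip rows keep their vegetation bands
    relief <- max(0.85, f)
    bw <- min(tpl$beach_width, W)
    tw <- as.integer(round(tw * f))
    rw <- min(tpl$ridge_width, max(W - bw, 0))
    mw <- min(mw_t, max(W - bw - rw, 0))
    interior <- max(W - bw - rw - mw, 0)
    tw <- min(tw, interior)
    pw <- interior - tw
    # offsets o = 0 at the shoreline column, increasing landward (west)
    prof <- c(
      seq(0.3, tpl$beach_top, length.out = max(bw, 1)),
      if (rw > 0) {
        half <- ceiling(rw / 2)
        back <- if (tw > 0) tpl$terrace_elev else tpl$platform_elev
        c(seq(tpl$beach_top, tpl$ridge_height, length.out = half + 1)[-1],
          seq(tpl$ridge_height, back, length.out = rw - half + 1)[-1])
      },
      rep(tpl$terrace_elev, tw),
      rep(tpl$platform_elev, pw),
      if (mw > 0) seq(tpl$marsh_elev, 0.05, length.out = mw)
    )
    zcode <- c(rep(1L, bw), rep(2L, rw), rep(3L, tw), rep(4L, pw), rep(5L, mw))
    prof <- prof * relief
    cols <- shore_col - seq_along(prof) + 1L
    keep <- cols >= 1L
    elev[i, cols[keep]] <- prof[keep]
    zone[i, cols[keep]] <- zcode[keep]
  }
  list(elev = elev, zone = zone, first = first, last = last,
       split_row = split_row, shore_col = shore_col)
}

#' Generate a synthetic island
#'
#' Quantises the template's continuous elevation surface to slab counts and
#' adds small seeded integer noise on island cells. The result satisfies all
#' `island_state` invariants; the water margin is bare seabed (`H = 0`).
#'
#' @param template an [island_template()].
#' @return an `island_state` with bare (unvegetated) cover grids.
#' @seealso [make_vegetation()] to populate the cover grids.
#' @export
make_island <- function(template) {
  geo <- .island_geometry(template)
  g <- template$grid
  H <- matrix(as.integer(round(geo$elev / g$delta)), g$n_rows, g$n_cols)
  if (template$noise_amp > 0) {
    set.seed(template$seed)
    land <- which(geo$zone > 0L)
    H[land] <- H[land] + sample.int(2L * template$noise_amp + 1L, length(land),
                                    replace = TRUE) - template$noise_amp - 1L
    H[H < 0L] <- 0L
  }
  storage.mode(H) <- "integer"
  island_state(g, H = H)
}

#' Generate zoned vegetation cover
#'
#' Populates the four cover grids according to the template's zonation and the
#' species' viable elevation bands: dune-building grasses on the dune ridge,
#' the moderate dune grass additionally on the interior terrace, the woody
#' shrub on the lower-half terrace only (the upper half carries no woody
#' cover), and marsh grass on the low back-barrier fringe; the wide beach ramp
#' and interior platform start bare. Every species is assigned only inside its
#' elevation band, and a crowding pass enforces the global cover cap.
#'
#' @param state the `island_state` from [make_island()].
#' @param template the same [island_template()].
#' @param species list of four [species_params()].
#' @param M global cover cap.
#' @return the state with cover grids filled in.
#' @export
make_vegetation <- function(state, template, species = default_species(),
                            M = 0.8) {
  geo <- .island_geometry(template)
  ee <- effective_elevation(state)
  upper <- matrix(FALSE, state$grid$n_rows, state$grid$n_cols)
  upper[geo$first:geo$split_row, ] <- TRUE
  land <- geo$zone > 0L
  in_band <- function(k) land & ee >= species[[k]]$lambda_L & ee <= species[[k]]$lambda_H

  P <- replicate(4, matrix(0, state$grid$n_rows, state$grid$n_cols),
                 simplify = FALSE)
  P[[1]][in_band(1) & geo$zone == 2L] <- 0.35
  P[[2]][in_band(2) & geo$zone %in% c(2L, 3L)] <- 0.15
  P[[3]][in_band(3) & geo$zone == 5L] <- 0.35
  P[[4]][in_band(4) & !upper & geo$zone == 3L] <- 0.5
  P <- crowding_adjust(P, M)
  for (k in 1:4) P[[k]] <- pmin(P[[k]], species[[k]]$eta)
  state$P <- P
  state
}

#' Synthetic wind climate
#'
#' Weibull-distributed wind speeds and a categorical direction law over the
#' eight compass points. The defaults (shape 2, scale 8 m/s) put a little
#' over half of the draws inside the 6-16 m/s transport window and exercise
#' every transport-distance bin; the rose is near-balanced cross-shore with a
#' slight easterly (onshore) prevalence, so the net wind-driven shoreline
#' drift stays small against Bruun recession.
#'
#' @param shape,scale Weibull parameters for speed (m/s); `shape = Inf` gives
#'   a point mass at `scale`.
#' @param dir_probs named probability vector over [COMPASS] (directions the
#'   wind blows from), summing to 1.
#' @return an object of class `wind_climate`.
#' @export
wind_climate <- function(shape = 2, scale = 8,
                         dir_probs = c(N = 0.10, NE = 0.14, E = 0.17,
                                       SE = 0.14, S = 0.11, SW = 0.11,
                                       W = 0.12, NW = 0.11)) {
  stopifnot(scale > 0, length(dir_probs) == 8,
            all(names(dir_probs) == COMPASS),
            abs(sum(dir_probs) - 1) < 1e-8)
  structure(list(shape = shape, scale = scale, dir_probs = dir_probs),
            class = "wind_climate")
}

#' Draw a wind series
#'
#' Independent two-week wind records from a [wind_climate()]: speeds from the
#' Weibull law, directions from the categorical law. Uses the current RNG
#' stream unless `seed` is given.
#'
#' @param climate a [wind_climate()].
#' @param n_steps number of records (>= 0).
#' @param seed optional RNG seed.
#' @return data frame with columns `speed` (m/s) and `direction` (compass
#'   point the wind blows from).
#' @export
wind_series <- function(climate, n_steps, seed = NULL) {
  stopifnot(n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps)
  speed <- if (is.finite(climate$shape))
    stats::rweibull(n_steps, climate$shape, climate$scale)
  else rep(climate$scale, n_steps)
  direction <- COMPASS[sample.int(8L, n_steps, replace = TRUE,
                                  prob = climate$dir_probs)]
  data.frame(speed = speed, direction = direction,
             stringsAsFactors = FALSE)
}
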