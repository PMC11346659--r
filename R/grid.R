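#' Grid geometry of the slab lattice
#'
#' Defines the regular lattice on which the island evolves. Rows index the
#' alongshore direction (row 1 is the northern edge), columns the cross-shore
#' direction with the ocean on the high-column (eastern) side; landward
#' migration therefore moves material toward low column indices. Elevation is
#' discretised into slabs of thickness `delta` and footprint `L` x `L`.
#'
#' @param n_rows number of alongshore rows (>= 3).
#' @param n_cols number of cross-shore columns (>= 3).
#' @param L cell edge length in meters (> 0).
#' @param delta slab thickness in meters (> 0).
#' @return an object of class `grid_spec`.
#' @examples
#' grid_spec(200, 120)
#' @export
grid_spec <- function(n_rows = 728L, n_cols = 678L, L = 4, delta = 0.1) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 3L, n_cols >= 3L, L > 0, delta > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, L = L, delta = delta),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Slab lattice: %d rows (alongshore) x %d cols (cross-shore), cell %g m, slab %g m\n",
              x$n_rows, x$n_cols, x$L, x$delta))
  invisible(x)
}

#' Island state container
#'
#' Bundles the mutable world: the integer slab-count grid `H` (relative to the
#' datum sea level at state creation), four per-species fractional cover grids,
#' the continuous sea-level offset above that datum (meters), and the current
#' simulation year. Sea level is tracked as a continuous offset rather than by
#' re-quantising `H`: annual rise (~0.5-2 cm) is far below the slab thickness
#' (10 cm), so elevation comparisons always go through [effective_elevation()].
#'
#' @param grid a [grid_spec()].
#' @param H integer matrix of slab counts (`n_rows` x `n_cols`, all >= 0).
#' @param P list of four cover matrices in `[0, 1]` (defaults to bare sand).
#' @param sea_level_offset meters of sea level above the datum.
#' @param t current simulation year (possibly fractional).
#' @return an object of class `island_state`.
#' @export
island_state <- function(grid, H = NULL, P = NULL, sea_level_offset = 0, t = 0) {
  if (is.null(H)) H <- matrix(0L, grid$n_rows, grid$n_cols)
  storage.mode(H) <- "integer"
  if (is.null(P)) P <- replicate(4, matrix(0, grid$n_rows, grid$n_cols), simplify = FALSE)
  stopifnot(nrow(H) == grid$n_rows, ncol(H) == grid$n_cols, length(P) == 4)
  st <- structure(list(grid = grid, H = H, P = P,
                       sea_level_offset = sea_level_offset, t = t),
                  class = "island_state")
  validate_island_state(st)
  st
}

#' Validate island state invariants
#'
#' Checks that `H` is a non-negative integer grid and every cover grid lies in
#' `[0, 1]`. Called by the scheduler after each process step; the error message
#' names the offending step.
#'
#' @param state an `island_state`.
#' @param species optional list of four [species_params()]; when given, also
#'   enforces per-species caps `P_k <= eta_k` (with a small numeric slack).
#' @param M optional global cover cap; when given, enforces `sum_k P_k <= M`.
#' @param step label used in the abort diagnostic.
#' @return the state, invisibly.
#' @export
validate_island_state <- function(state, species = NULL, M = NULL, step = "input") {
  H <- state$H
  if (any(H < 0L)) stop("island_state invariant violated after step '", step,
                        "': negative slab count")
  if (!is.integer(H)) stop("island_state invariant violated after step '", step,
                           "': H is not integer")
  tol <- 1e-9
  tot <- 0
  for (k in 1:4) {
    Pk <- state$P[[k]]
    if (any(Pk < -tol) || any(Pk > 1 + tol))
      stop("island_state invariant violated after step '", step,
           "': cover P", k, " outside [0, 1]")
    if (!is.null(species) && any(Pk > species[[k]]$eta + tol))
      stop("island_state invariant violated after step '", step,
           "': cover P", k, " exceeds its cap")
    tot <- tot + Pk
  }
  if (!is.null(M) && any(tot > M + tol))
    stop("island_state invariant violated after step '", step,
         "': total cover exceeds global cap M")
  invisible(state)
}

#' @export
print.island_state <- function(x, ...) {
  ee <- effective_elevation(x)
  sub <- sum(ee > 0)
  cat(sprintf("island_state: %d x %d cells, year %.2f, sea level offset %.3f m\n",
              x$grid$n_rows, x$grid$n_cols, x$t, x$sea_level_offset))
  cat(sprintf("  subaerial cells: %d (%.1f%%); max elevation %.2f m; total slabs %.0f\n",
              sub, 100 * sub / length(ee), max(ee), sum(as.numeric(x$H))))
  invisible(x)
}

#' Elevation above current sea level
#'
#' `H * delta - sea_level_offset`, the physical elevation of the sediment
#' surface relative to the instantaneous sea level.
#'
#' @param state an `island_state`.
#' @param cell optional `c(row, col)`; when omitted the full matrix is
#'   returned.
#' @return meters above current sea level (matrix, or scalar when `cell` is
#'   given).
#' @examples
#' g <- grid_spec(3, 3)
#' st <- island_state(g, H = matrix(10L, 3, 3))
#' effective_elevation(st, c(2, 2))  # 1.0 m
#' @export
effective_elevation <- function(state, cell = NULL) {
  if (is.null(cell))
    return(state$H * state$grid$delta - state$sea_level_offset)
  r <- cell[1]; c <- cell[2]
  if (r < 1 || r > state$grid$n_rows || c < 1 || c > state$grid$n_cols)
    stop("cell (", r, ", ", c, ") outside grid")
  state$H[r, c] * state$grid$delta - state$sea_level_offset
}

#' Subaerial mask
#'
#' TRUE exactly where the surface is strictly above current sea level; cells at
#' exactly sea level count as water, which removes zero-area ambiguity from the
#' subaerial-area term of the migration factor.
#'
#' @param state an `island_state`.
#' @return logical matrix.
#' @export
subaerial_mask <- function(state) {
  effective_elevation(state) > 0
}
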