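#' Angle-of-repose parameters
#'
#' `theta_o` is the shallowest inter-cell slope angle that triggers
#' avalanching (default pi/6). With vegetation present, termination of the
#' stochastic relaxation is only probabilistic, so a pass cap is required.
#'
#' @param theta_o critical angle of repose in radians, in `(0, pi/2)`.
#' @param max_passes iteration cap for [relax()].
#' @return an object of class `repose_params`.
#' @export
repose_params <- function(theta_o = pi / 6, max_passes = 100L) {
  stopifnot(theta_o > 0, theta_o < pi / 2, max_passes >= 1)
  structure(list(theta_o = theta_o, max_passes = as.integer(max_passes)),
            class = "repose_params")
}

#' Inter-cell repose angle
#'
#' The physical slope angle between two adjacent cells,
#' `atan(delta * (H_center - H_neighbor) / L)`: the slab-count difference is
#' converted to meters by the slab thickness and divided by one cell width.
#' Note this is the dimensionally consistent form of the slope; the ratio of a
#' raw slab count to `L * delta` would make a single-slab step a ~14 degree
#' slope at the default geometry. Evaluated over the von Neumann (4-cell)
#' neighbourhood.
#'
#' @param H_center,H_neighbor slab counts.
#' @param grid a [grid_spec()] (supplies `delta` and `L`).
#' @return angle in radians (negative when the neighbour is higher).
#' @examples
#' repose_angle(10, 0, grid_spec(3, 3))  # atan(0.25)
#' @export
repose_angle <- function(H_center, H_neighbor, grid) {
  atan(grid$delta * (H_center - H_neighbor) / grid$L)
}

#' Probability of an avalanche move
#'
#' For a slope violating the critical angle,
#' `rho_av = min(1, (theta / theta_o) * (1 - PC))`: steeper violations
#' avalanche more readily, and vegetation on the source cell pins sediment.
#'
#' @param theta repose angle of the violating pair (radians).
#' @param theta_o critical angle of repose (radians).
#' @param PC effective plant cover of the source cell.
#' @return probability in `[0, 1]`.
#' @export
avalanche_probability <- function(theta, theta_o, PC) {
  pmin(1, (theta / theta_o) * (1 - PC))
}

# cells violating the repose threshold: the higher member of any adjacent
# pair whose slab-count difference reaches crit; found from the two first
# difference matrices, so cost stays linear with small constants
.violating_cells <- function(H, crit) {
  n <- nrow(H); m <- ncol(H)
  dv <- H[-1, , drop = FALSE] - H[-n, , drop = FALSE]    # (n-1) x m
  dh <- H[, -1, drop = FALSE] - H[, -m, drop = FALSE]    # n x (m-1)
  out <- integer(0)
  k <- which(dv >= crit)          # lower row higher than upper: source (i+1, j)
  if (length(k)) out <- c(out, ((k - 1L) %/% (n - 1L)) * n + ((k - 1L) %% (n - 1L)) + 2L)
  k <- which(dv <= -crit)         # source (i, j)
  if (length(k)) out <- c(out, ((k - 1L) %/% (n - 1L)) * n + ((k - 1L) %% (n - 1L)) + 1L)
  k <- which(dh >= crit)          # source (i, j+1)
  if (length(k)) out <- c(out, ((k - 1L) %/% n) * n + n + ((k - 1L) %% n) + 1L)
  k <- which(dh <= -crit)         # source (i, j)
  if (length(k)) out <- c(out, ((k - 1L) %/% n) * n + ((k - 1L) %% n) + 1L)
  unique(out)
}

# max over the four von Neumann neighbours of H - H_nb (off-grid neighbours
# ignored); 0 floor is harmless since only positive drops can violate
.steepest_drops <- function(H) {
  n <- nrow(H); m <- ncol(H)
  drop <- matrix(0L, n, m)
  dv <- H[-1, , drop = FALSE] - H[-n, , drop = FALSE]
  drop[-1, ] <- pmax(drop[-1, , drop = FALSE], dv)
  drop[-n, ] <- pmax(drop[-n, , drop = FALSE], -dv)
  dh <- H[, -1, drop = FALSE] - H[, -m, drop = FALSE]
  drop[, -1] <- pmax(drop[, -1, drop = FALSE], dh)
  drop[, -m] <- pmax(drop[, -m, drop = FALSE], -dh)
  drop
}

#' Avalanche relaxation
#'
#' Relaxes over-steep slopes after any sediment-moving process. Each pass
#' evaluates all currently violating cells synchronously on the pass-start
#' surface (the same convention the aeolian step uses): every violating cell
#' moves one slab, with probability [avalanche_probability()], onto its
#' steepest von Neumann neighbour (ties broken uniformly at random), and all
#' moves are applied together. Passes repeat until no pair violates `theta_o`
#' or the pass cap is reached (then a warning is logged). Total slab count is
#' conserved exactly; the grid maximum never increases (a receiving cell sits
#' at least the violation threshold below its sources); with bare sand
#' (`PC = 0`) every violating cell moves, so termination is deterministic.
#'
#' @param state an `island_state`.
#' @param params a [repose_params()].
#' @param species list of four [species_params()]; `NULL` treats the surface
#'   as bare.
#' @param PC optional precomputed effective-cover matrix (covers change only
#'   at the annual vegetation update, so callers may cache it).
#' @return the updated state, with attributes `passes` and `slabs_moved`
#'   describing the relaxation.
#' @export
relax <- function(state, params = repose_params(), species = NULL, PC = NULL) {
  H <- state$H
  grid <- state$grid
  n <- nrow(H); m <- ncol(H)
  crit <- tan(params$theta_o) * grid$L / grid$delta  # slab-count threshold
  passes <- 0L; moved <- 0L
  repeat {
    viol <- .violating_cells(H, crit)
    if (!length(viol) || passes >= params$max_passes) break
    if (is.null(PC)) {
      PC <- if (is.null(species)) matrix(0, n, m)
            else effective_cover(state$P, species_alphas(species))
    }
    passes <- passes + 1L
    k <- length(viol)
    r <- ((viol - 1L) %% n) + 1L
    c <- ((viol - 1L) %/% n) + 1L
    # neighbour heights (N, S, W, E); off-grid neighbours never targeted
    nbi <- cbind(viol - 1L, viol + 1L, viol - n, viol + n)
    ok <- cbind(r > 1L, r < n, c > 1L, c < m)
    nbH <- matrix(Inf, k, 4)
    nbH[ok] <- H[nbi[ok]]
    diffs <- H[viol] - nbH
    maxd <- pmax(diffs[, 1], diffs[, 2], diffs[, 3], diffs[, 4])
    theta <- atan(grid$delta * maxd / grid$L)
    mv <- stats::runif(k) < avalanche_probability(theta, params$theta_o, PC[viol])
    if (any(mv)) {
      # steepest neighbour, ties broken uniformly via random scores
      score <- matrix(stats::runif(4L * k), k, 4)
      score[diffs < maxd] <- -1
      tgt <- nbi[cbind(seq_len(k), max.col(score))]
      src <- viol[mv]; tgt <- tgt[mv]
      H[src] <- H[src] - 1L
      H <- H + tabulate(tgt, nbins = n * m)
      storage.mode(H) <- "integer"
      dim(H) <- c(n, m)
      moved <- moved + sum(mv)
    }
  }
  if (passes >= params$max_passes && length(.violating_cells(H, crit)))
    warning("avalanche relaxation hit max_passes with violations remaining")
  state$H <- H
  attr(state, "passes") <- passes
  attr(state, "slabs_moved") <- moved
  state
}
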