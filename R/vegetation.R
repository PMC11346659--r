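# 3x3 Moore-neighbourhood sum (including the centre), truncated at edges.
moore_sum <- function(P) {
  n <- nrow(P); m <- ncol(P)
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- P
  out <- matrix(0, n, m)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + pad[(1 + dr):(n + dr), (1 + dc):(m + dc)]
  out
}

#' Annual growth and immigration
#'
#' One year of logistic-free neighbourhood growth: each cell gains
#' `gamma(i,j) * sum of P over its 3x3 Moore neighbourhood` (the sum includes
#' the cell itself, so the update covers both in-cell growth and immigration
#' from neighbours). The rate `gamma` is drawn uniformly from `[g, G]`
#' independently per cell per year and shared across the nine neighbourhood
#' terms of that cell. The result is clipped to `[0, eta]`.
#'
#' @param P cover matrix for one species.
#' @param species the [species_params()] supplying `g`, `G`, `eta`.
#' @param gamma optional rate matrix overriding the random draw (used for
#'   analytic checks).
#' @return updated cover matrix.
#' @export
grow_step <- function(P, species, gamma = NULL) {
  if (is.null(gamma))
    gamma <- matrix(stats::runif(length(P), species$g, species$G), nrow(P), ncol(P))
  out <- P + gamma * moore_sum(P)
  out[out < 0] <- 0
  out[out > species$eta] <- species$eta
  out
}

#' Overcrowding adjustment
#'
#' Where total cover exceeds the global cap `M`, the excess is removed from the
#' grass species (1-3) in even shares; the woody species (4) is never reduced
#' here, reflecting its competitive dominance. A grass driven below zero is
#' floored at zero and its residual deficit re-spread over the remaining
#' positive grasses until consistent. Operates on whole grids at once.
#'
#' @param P list of four cover matrices (or a numeric vector of four covers
#'   for a single cell).
#' @param M global cover cap (fraction).
#' @return adjusted covers, same shape as input; total cover at most `M`
#'   wherever it exceeded it.
#' @examples
#' crowding_adjust(c(0.5, 0.5, 0, 0.3), M = 0.8)  # grasses each lose 0.25
#' @export
crowding_adjust <- function(P, M = 0.8) {
  vec <- is.numeric(P)
  if (vec) P <- lapply(P, function(x) matrix(x, 1, 1))
  total <- P[[1]] + P[[2]] + P[[3]] + P[[4]]
  deficit <- pmax(total - M, 0)
  # grasses absorb the deficit; up to three redistribution rounds suffice
  for (round in 1:3) {
    if (all(deficit <= 1e-12)) break
    pos <- lapply(1:3, function(k) P[[k]] > 0)
    l <- pos[[1]] + pos[[2]] + pos[[3]]
    share <- ifelse(l > 0, deficit / pmax(l, 1), 0)
    deficit <- matrix(0, nrow(share), ncol(share))
    for (k in 1:3) {
      red <- ifelse(pos[[k]], share, 0)
      newP <- P[[k]] - red
      deficit <- deficit + pmax(-newP, 0)   # overshoot re-spread next round
      P[[k]] <- pmax(newP, 0)
    }
  }
  if (vec) vapply(P, function(x) x[1, 1], numeric(1)) else P
}

#' Elevation-range viability decay
#'
#' Once a year, cover of a species on cells whose effective elevation lies
#' outside its viable band `[lambda_L, lambda_H]` is multiplied by the decay
#' factor `d_viab`; cells inside the band are untouched exactly. Decayed covers
#' below `1e-4` are zeroed to keep grids sparse.
#'
#' @param state an `island_state` (supplies elevations).
#' @param P cover matrix for the species.
#' @param species its [species_params()].
#' @param d_viab annual decay multiplier for out-of-range cover.
#' @return updated cover matrix.
#' @export
viability_update <- function(state, P, species, d_viab = 0.5) {
  ee <- effective_elevation(state)
  out_of_range <- ee < species$lambda_L | ee > species$lambda_H
  P[out_of_range] <- P[out_of_range] * d_viab
  P[out_of_range & P < 1e-4] <- 0
  P
}

#' Long-distance (bird) dispersal of the woody species
#'
#' Woody-plant seeds are carried island-wide by birds: once a year, provided
#' any source cell carries woody cover, every subaerial, currently empty cell
#' whose elevation is at or above the woody species' minimum independently
#' gains a small founding cover with probability `p_disp`.
#'
#' @param P4 woody-species cover matrix.
#' @param state an `island_state`.
#' @param species the woody [species_params()] (supplies `lambda_L`).
#' @param p_disp per-cell annual establishment probability.
#' @param p_seed_cover founding cover assigned to a seeded cell.
#' @return updated woody cover matrix.
#' @export
distant_dispersal <- function(P4, state, species, p_disp = 1e-3,
                              p_seed_cover = 0.01) {
  if (!any(P4 > 0)) return(P4)
  ee <- effective_elevation(state)
  eligible <- which(ee > 0 & ee >= species$lambda_L & P4 == 0)
  if (!length(eligible)) return(P4)
  hit <- eligible[stats::runif(length(eligible)) < p_disp]
  P4[hit] <- p_seed_cover
  P4
}

#' Full annual vegetation update
#'
#' Growth and immigration for each species, then long-distance dispersal of
#' the woody species, then the overcrowding adjustment (woody cover capped at
#' its own `eta` first, grasses bear the excess over `M`), then the
#' elevation-range viability decay. After this update every cell satisfies
#' `P_k <= eta_k` and `sum_k P_k <= M`.
#'
#' @param state an `island_state`.
#' @param species list of four [species_params()].
#' @param M global cover cap.
#' @param d_viab out-of-range decay multiplier.
#' @param p_disp,p_seed_cover dispersal parameters, see [distant_dispersal()].
#' @return the state with updated cover grids.
#' @export
vegetation_annual_step <- function(state, species, M = 0.8, d_viab = 0.5,
                                   p_disp = 1e-3, p_seed_cover = 0.01) {
  P <- state$P
  for (k in 1:4) P[[k]] <- grow_step(P[[k]], species[[k]])
  P[[4]] <- distant_dispersal(P[[4]], state, species[[4]], p_disp, p_seed_cover)
  P[[4]] <- pmin(P[[4]], species[[4]]$eta)
  P <- crowding_adjust(P, M)
  for (k in 1:3) P[[k]] <- pmin(P[[k]], species[[k]]$eta)
  state$P <- P
  for (k in 1:4)
    state$P[[k]] <- viability_update(state, state$P[[k]], species[[k]], d_viab)
  state
}
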