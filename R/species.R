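#' Species parameters
#'
#' Per-species traits controlling viability, erosion inhibition, and growth.
#' The viable elevation band `[lambda_L, lambda_H]` is the range (meters above
#' current sea level) where the species persists; outside it cover decays. The
#' erosion coefficient `alpha` in `[0, 1]` weights how strongly the species'
#' cover inhibits sediment movement; `eta` caps the species' own fractional
#' cover; annual per-cell growth rates are drawn uniformly from `[g, G]`.
#'
#' @param name species label.
#' @param lambda_L minimum viable elevation (m).
#' @param lambda_H maximum viable elevation (m); `Inf` for unbounded.
#' @param alpha erosion coefficient in `[0, 1]`.
#' @param eta per-species cover cap in `(0, 1]`.
#' @param g,G minimum / maximum annual growth rate (fractions per year).
#' @return an object of class `species_params`.
#' @export
species_params <- function(name, lambda_L, lambda_H, alpha, eta,
                           g = -0.02, G = 0.08) {
  stopifnot(lambda_L < lambda_H, alpha >= 0, alpha <= 1,
            eta > 0, eta <= 1, g <= G)
  structure(list(name = name, lambda_L = lambda_L, lambda_H = lambda_H,
                 alpha = alpha, eta = eta, g = g, G = G),
            class = "species_params")
}

#' Default species set
#'
#' The four mid-Atlantic barrier-island species of the model with their
#' standard elevation bands, erosion coefficients, cover caps, and growth-rate
#' range: the dune-building grass *Ammophila breviligulata* (1-5 m, alpha
#' 0.667, cap 0.8), the moderate dune grass *Spartina patens* (0.75-3 m, alpha
#' 0.333, cap 0.8), the marsh grass *Spartina alterniflora* (-0.5-1 m, alpha 1,
#' cap 0.6), and the woody shrub *Morella cerifera* (above 1.5 m, alpha 1, cap
#' 0.6, favoured in crowding). Growth rates are drawn from -2% to +8% per
#' year.
#'
#' @return list of four [species_params()]; species 1-3 are grasses, species 4
#'   is the woody shrub.
#' @export
default_species <- function() {
  list(
    species_params("Ammophila breviligulata", 1,    5,   0.667, 0.8),
    species_params("Spartina patens",         0.75, 3,   0.333, 0.8),
    species_params("Spartina alterniflora",  -0.5,  1,   1,     0.6),
    species_params("Morella cerifera",        1.5,  Inf, 1,     0.6)
  )
}

#' Effective erosion-inhibiting plant cover
#'
#' The alpha-weighted sum of species covers, `PC = sum_k alpha_k P_k`, clipped
#' to at most 1 so downstream probabilities receive a valid fraction (with the
#' default caps the raw sum can reach 1.4).
#'
#' @param P list of four cover matrices (or a numeric vector of four covers).
#' @param alpha numeric vector of four erosion coefficients.
#' @return effective cover `PC` in `[0, 1]`, same shape as the covers.
#' @examples
#' effective_cover(c(0.3, 0, 0, 0), c(0.667, 0.333, 1, 1))  # 0.2001
#' @export
effective_cover <- function(P, alpha) {
  if (is.numeric(P)) {
    pc <- sum(alpha * P)
  } else {
    pc <- alpha[1] * P[[1]] + alpha[2] * P[[2]] + alpha[3] * P[[3]] + alpha[4] * P[[4]]
  }
  pmin(pc, 1)
}

species_alphas <- function(species) vapply(species, `[[`, numeric(1), "alpha")
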