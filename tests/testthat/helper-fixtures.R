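# Small in-code fixtures shared across tests.

# a flat slab of constant height occupying cols `land_cols`, bare cover
flat_state <- function(n = 20, m = 30, h = 5L, land_cols = 5:25,
                       offset = 0, L = 4, delta = 0.1) {
  g <- grid_spec(n, m, L = L, delta = delta)
  H <- matrix(0L, n, m)
  H[, land_cols] <- h
  island_state(g, H = H, sea_level_offset = offset)
}

# set one species' cover uniformly on all land (H > 0) cells
with_cover <- function(state, k, value) {
  state$P[[k]][state$H > 0] <- value
  state
}

tiny_template <- function(...) {
  defaults <- list(grid = grid_spec(60, 120), row_margin = 6,
                   width_upper = 30, width_lower = 40,
                   beach_width = 10, terrace_width_lower = 16,
                   taper_rows = 6)
  do.call(island_template, utils::modifyList(defaults, list(...)))
}
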