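sp <- default_species()

test_that("growth adds the rate times the Moore-neighbourhood population", {
  P <- matrix(0.1, 7, 7)
  gam <- matrix(0.08, 7, 7)
  out <- grow_step(P, sp[[1]], gamma = gam)
  # interior: 0.1 + 0.08 * (9 * 0.1) = 0.172; edges see truncated neighbourhoods
  expect_equal(out[4, 4], 0.172)
  expect_equal(out[1, 1], 0.1 + 0.08 * (4 * 0.1))  # corner: 4 cells
  expect_equal(out[1, 4], 0.1 + 0.08 * (6 * 0.1))  # edge: 6 cells

  expect_equal(grow_step(matrix(0, 5, 5), sp[[1]]), matrix(0, 5, 5))
  expect_equal(grow_step(P, sp[[1]], gamma = matrix(0, 7, 7)), P)
})

test_that("growth clips to the species cap and never goes negative", {
  P <- matrix(0.7, 5, 5)
  out <- grow_step(P, sp[[1]], gamma = matrix(0.08, 5, 5))
  expect_true(all(out <= sp[[1]]$eta))
  out2 <- grow_step(matrix(0.01, 5, 5), sp[[1]], gamma = matrix(-1, 5, 5))
  expect_true(all(out2 >= 0))
})

test_that("growth is monotone in the input for non-negative shared rates", {
  set.seed(5)
  for (rep in 1:5) {
    P <- matrix(runif(36, 0, 0.5), 6, 6)
    Q <- pmin(P + matrix(runif(36, 0, 0.2), 6, 6), 1)
    gam <- matrix(runif(36, 0, 0.08), 6, 6)
    expect_true(all(grow_step(Q, sp[[1]], gamma = gam) >=
                    grow_step(P, sp[[1]], gamma = gam)))
  }
})

test_that("sustained positive growth saturates a seeded cell at its cap", {
  P <- matrix(0, 5, 5); P[3, 3] <- 0.05
  gam <- matrix(sp[[1]]$G, 5, 5)
  for (i in 1:60) P <- grow_step(P, sp[[1]], gamma = gam)
  expect_equal(P[3, 3], sp[[1]]$eta)
  expect_true(all(P > 0))  # immigration spread to the whole grid
})

test_that("crowding removes the excess evenly from the grasses, never the shrub", {
  expect_equal(crowding_adjust(c(0.5, 0.5, 0, 0.3), M = 0.8),
               c(0.25, 0.25, 0, 0.3))
  expect_equal(crowding_adjust(c(0.2, 0.1, 0, 0.4), M = 0.8),
               c(0.2, 0.1, 0, 0.4))
  # a grass driven negative is floored and its deficit re-spread
  expect_equal(crowding_adjust(c(0.05, 0.6, 0, 0.4), M = 0.8),
               c(0, 0.4, 0, 0.4))
})

test_that("crowding caps the total at M on whole grids", {
  set.seed(11)
  P <- replicate(4, matrix(runif(100, 0, 0.6), 10, 10), simplify = FALSE)
  P[[4]] <- pmin(P[[4]], sp[[4]]$eta)
  out <- crowding_adjust(P, M = 0.8)
  tot <- Reduce(`+`, out)
  expect_true(all(tot <= 0.8 + 1e-9))
  expect_identical(out[[4]], P[[4]])
  for (k in 1:3) expect_true(all(out[[k]] >= 0))
})

test_that("effective cover is the alpha-weighted sum clipped to one", {
  al <- c(0.667, 0.333, 1, 1)
  expect_equal(effective_cover(c(0, 0, 0, 0), al), 0)
  expect_equal(effective_cover(c(0.3, 0, 0, 0), al), 0.2001)
  expect_equal(effective_cover(c(0, 0, 0.6, 0.6), al), 1)  # raw 1.2 clipped
})

test_that("cover decays only outside the species' elevation band", {
  g <- grid_spec(3, 3)
  st <- island_state(g, H = matrix(20L, 3, 3))  # 2.0 m everywhere
  P <- matrix(0.4, 3, 3)
  expect_equal(viability_update(st, P, sp[[3]])[2, 2], 0.2)  # marsh grass out
  expect_equal(viability_update(st, P, sp[[1]]), P)          # dune grass in
  tiny <- matrix(5e-5, 3, 3)
  expect_equal(viability_update(st, tiny, sp[[3]]), matrix(0, 3, 3))
  expect_equal(viability_update(st, tiny, sp[[1]]), tiny)    # in range: exact
})

test_that("bird dispersal seeds eligible empty cells at the configured rate", {
  g <- grid_spec(25, 40)
  st <- island_state(g, H = matrix(20L, 25, 40))  # all eligible (2 m)
  P4 <- matrix(0, 25, 40)
  expect_equal(distant_dispersal(P4, st, sp[[4]]), P4)  # no seed source

  P4[1, 1] <- 0.5
  set.seed(3)
  forced <- distant_dispersal(P4, st, sp[[4]], p_disp = 1, p_seed_cover = 0.01)
  expect_true(all(forced[-1] == 0.01 | forced[-1] == 0))
  expect_equal(sum(forced == 0.01), 25 * 40 - 1)

  # Monte-Carlo seeding count vs the binomial law (999 eligible cells)
  set.seed(42)
  n_rep <- 200
  total <- sum(vapply(seq_len(n_rep), function(i) {
    sum(distant_dispersal(P4, st, sp[[4]], p_disp = 1e-3) == 0.01)
  }, numeric(1)))
  expn <- n_rep * 999 * 1e-3
  sd3 <- 3 * sqrt(n_rep * 999 * 1e-3 * (1 - 1e-3))
  expect_gt(total, expn - sd3)
  expect_lt(total, expn + sd3)
})

test_that("the full annual update restores every cover invariant", {
  tpl <- tiny_template()
  st <- make_vegetation(make_island(tpl), tpl)
  set.seed(8)
  for (yr in 1:3) {
    st <- vegetation_annual_step(st, sp, M = 0.8)
    expect_silent(validate_island_state(st, sp, M = 0.8, step = "veg"))
  }
  tot <- Reduce(`+`, st$P)
  expect_true(all(tot <= 0.8 + 1e-9))
})
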