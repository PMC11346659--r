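test_that("effective elevation combines slab count and sea-level offset", {
  g <- grid_spec(5, 5)
  st <- island_state(g, H = matrix(10L, 5, 5))
  expect_equal(effective_elevation(st, c(3, 3)), 1.0)

  st0 <- island_state(g, sea_level_offset = 0.25)
  expect_equal(effective_elevation(st0, c(1, 1)), -0.25)

  st92 <- island_state(g, H = matrix(10L, 5, 5), sea_level_offset = 0.036)
  expect_equal(effective_elevation(st92, c(2, 4)), 0.964)

  expect_error(effective_elevation(st, c(6, 1)), "outside grid")
})

test_that("subaerial mask is strict: cells at sea level are water", {
  g <- grid_spec(4, 4)
  expect_false(any(subaerial_mask(island_state(g))))

  H <- matrix(0L, 4, 4); H[2, 3] <- 1L
  st <- island_state(g, H = H, sea_level_offset = 0.05)
  expect_identical(which(subaerial_mask(st)), which(H == 1L))

  st_boundary <- island_state(g, H = H, sea_level_offset = 0.1)
  expect_false(any(subaerial_mask(st_boundary)))
})

test_that("state invariant checks name the offending step", {
  g <- grid_spec(4, 4)
  st <- island_state(g)
  st$H[1, 1] <- -1L
  expect_error(validate_island_state(st, step = "aeolian"),
               "aeolian.*negative")
  st2 <- island_state(g)
  st2$P[[2]][2, 2] <- 1.4
  expect_error(validate_island_state(st2, step = "vegetation"),
               "outside \\[0, 1\\]")
})

test_that("zero-length run returns the input unchanged", {
  tpl <- tiny_template()
  st <- make_vegetation(make_island(tpl), tpl)
  cfg <- simulation_config(start_year = 2020, end_year = 2020, seed = 7)
  sim <- run_simulation(cfg, st)
  expect_identical(sim$final$H, st$H)
  expect_identical(sim$final$P, st$P)
  expect_null(sim$report)
})

test_that("identical seed, config, and initial state reproduce bit-identical output", {
  tpl <- tiny_template()
  st <- make_vegetation(make_island(tpl), tpl)
  cfg <- simulation_config(start_year = 2020, end_year = 2022, seed = 99, w = 20)
  s1 <- suppressMessages(run_simulation(cfg, st))
  s2 <- suppressMessages(run_simulation(cfg, st))
  expect_identical(s1$final$H, s2$final$H)
  expect_identical(s1$final$P, s2$final$P)
  expect_identical(s1$positions, s2$positions)
})

test_that("with all processes disabled the state is a fixed point of the scheduler", {
  tpl <- tiny_template()
  st <- make_vegetation(make_island(tpl), tpl)
  cfg <- simulation_config(start_year = 2020, end_year = 2023, seed = 1,
                           processes = c(aeolian = FALSE, vegetation = FALSE,
                                         marine = FALSE))
  sim <- run_simulation(cfg, st)
  expect_identical(sim$final$H, st$H)
  expect_identical(sim$final$P, st$P)
  expect_equal(sim$final$sea_level_offset, st$sea_level_offset)
})

test_that("a flat unvegetated island recedes by the floor-accumulated Bruun distance", {
  st <- flat_state(n = 20, m = 40, h = 5L, land_cols = 5:30)
  cfg <- simulation_config(start_year = 2020, end_year = 2021, seed = 1,
                           w = 5,
                           processes = c(aeolian = FALSE, vegetation = FALSE,
                                         marine = TRUE))
  sim <- run_simulation(cfg, st)
  # historic increment 0.45 cm -> R = 3333.33 * 0.0045 = 15 m/yr -> 3 whole
  # cells of 4 m, 3 m carried over
  expect_equal(unname(sim$positions[, "2021"]), rep(27 * 4, 20))
  expect_equal(unname(sim$positions[, "2020"] - sim$positions[, "2021"]),
               rep(12, 20))
})
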