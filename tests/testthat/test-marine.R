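sp <- default_species()

test_that("the sea-level curve anchors at 3.6 cm in 1992 and grows quadratically", {
  for (nm in c("historic", "low", "high", "highest"))
    expect_equal(sea_level(slr_scenario(nm), 1992), 3.6)
  expect_equal(sea_level(slr_scenario("historic"), 2050), 29.7)
  expect_equal(sea_level(slr_scenario("highest"), 2050), 0.45 * 58 + 0.0157 * 58^2 + 3.6)
  expect_equal(sea_level(slr_scenario("historic"), 1984), 0)
  expect_error(sea_level(slr_scenario("historic"), 1983), "datum")
})

test_that("the curve is non-decreasing and the scenarios are ordered", {
  yrs <- 1984:2050
  curves <- lapply(c("historic", "low", "high", "highest"),
                   function(nm) sea_level(slr_scenario(nm), yrs))
  for (cv in curves) expect_true(all(diff(cv) >= 0))
  for (i in 1:3) expect_true(all(curves[[i]] <= curves[[i + 1]]))
})

test_that("annual increments difference the curve", {
  expect_equal(slr_increment(slr_scenario("historic"), 2000), 0.45)
  expect_equal(slr_increment(slr_scenario("historic"), 1990), 0.45)
  expect_equal(slr_increment(slr_scenario("highest"), 2021),
               0.45 + 0.0157 * (29^2 - 28^2))
  expect_equal(slr_increment(slr_scenario("custom", a = 0, c = 5), 2030), 0)
})

test_that("the recession coefficient comes from geometry or calibration", {
  expect_equal(bruun_coefficient(W = 100, L0 = 100, LL = 100,
                                 hb0 = 3, hbL = 0.5, B0 = 1, BL = 0.5), 100)
  expect_equal(bruun_coefficient(W = 0, L0 = 0, LL = 0,
                                 hb0 = 3, hbL = 0, B0 = 1, BL = 0), 0)
  expect_error(bruun_coefficient(W = 100, L0 = 0, LL = 0,
                                 hb0 = 1, hbL = 1, B0 = 1, BL = 1),
               "degenerate")
  expect_equal(calibrate_bruun(15, 0.0045), 10000 / 3)
  expect_equal(calibrate_bruun(), 3333.3, tolerance = 1e-4)
})

test_that("the migration factor averages cover over subaerial window cells", {
  st <- flat_state(n = 10, m = 12, h = 5L, land_cols = 3:10)
  expect_equal(migration_factor(st, sp, w = 3), rep(0, 10))

  st04 <- with_cover(st, 3, 0.4)  # alpha_3 = 1 -> PC = 0.4 on land
  expect_equal(migration_factor(st04, sp, w = 3), rep(0.4, 10))

  # toy window: 3 x 4 grid, six subaerial cells, PC values averaging 0.5
  g <- grid_spec(3, 4)
  H <- matrix(0L, 3, 4)
  H[cbind(c(1, 1, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2))] <- 1L
  st3 <- island_state(g, H = H)
  st3$P[[3]][cbind(c(1, 1, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2))] <-
    c(0.2, 0.2, 0.8, 0.8, 0.5, 0.5)
  expect_equal(migration_factor(st3, sp, w = 1, rows = 2), 0.5)
})

test_that("migration ceases exactly from half cover upward and is continuous there", {
  B <- 10000 / 3
  S <- 0.0045
  expect_equal(row_migration(0.6, B, S), 0)
  expect_equal(row_migration(0.5, B, S), 0)
  expect_equal(row_migration(0, B, S), B * S)
  expect_equal(row_migration(0.25, B, 0.0045), 7.5)
  # continuity at the branch point and monotonicity below it
  expect_lt(row_migration(0.4999, B, S), 0.005)
  mfs <- seq(0, 0.5, 0.05)
  expect_true(all(diff(row_migration(mfs, B, S)) <= 0))
})

test_that("landward translation uses whole cells and carries the remainder", {
  st <- flat_state(n = 6, m = 20, h = 4L, land_cols = 8:16)
  r0 <- apply_migration(st, rep(0, 6))
  expect_identical(r0$state$H, st$H)
  expect_equal(r0$carry, rep(0, 6))

  r1 <- apply_migration(st, rep(6, 6))           # 6 m = 1 cell + 2 m carry
  expect_equal(unname(shoreline_position(r1$state)), rep(15 * 4, 6))
  expect_equal(r1$carry, rep(2, 6))

  r2 <- apply_migration(r1$state, rep(6, 6), r1$carry)  # cumulative 12 m = 3 cells
  expect_equal(unname(shoreline_position(r2$state)), rep(13 * 4, 6))
  expect_equal(r2$carry, rep(0, 6))
})

test_that("the annual marine step raises the sea and shifts only sparse rows", {
  still <- slr_scenario("custom", a = 0, c = 0)
  st <- flat_state()
  out <- annual_marine_step(st, 2030, still, sp, B = 10000 / 3, w = 3)
  expect_identical(out$state$H, st$H)
  expect_equal(out$state$sea_level_offset, 0)

  # fully vegetated: sea rises but nothing shifts
  veg <- with_cover(flat_state(), 3, 0.6)
  outv <- annual_marine_step(veg, 2030, slr_scenario("historic"), sp,
                             B = 10000 / 3, w = 3)
  expect_identical(outv$state$H, veg$H)
  expect_equal(outv$state$sea_level_offset, 0.0045)

  # unvegetated: every row shifts by the same amount
  bare <- flat_state()
  outb <- annual_marine_step(bare, 2030, slr_scenario("historic"), sp,
                             B = 10000 / 3, w = 3)
  pos <- shoreline_position(outb$state)
  expect_equal(unname(pos), rep(pos[1], 20))
  expect_equal(unname(shoreline_position(bare) - pos), rep(12, 20))
})
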