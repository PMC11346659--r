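sp <- default_species()

test_that("transport distance follows the wind-speed bins", {
  expect_identical(transport_distance(5), 0L)
  expect_identical(transport_distance(6), 1L)
  expect_identical(transport_distance(8.99), 1L)
  expect_identical(transport_distance(9), 2L)
  expect_identical(transport_distance(10), 2L)
  expect_identical(transport_distance(12.99), 2L)
  expect_identical(transport_distance(13), 3L)
  expect_identical(transport_distance(16), 3L)
  expect_true(is.na(transport_distance(16.1)))  # storm regime
})

test_that("movement probability is linear in wind and attenuated by cover", {
  expect_equal(move_probability(1, 12), 0)
  expect_equal(move_probability(0, 16), 1)
  expect_equal(move_probability(0.5, 11), 0.25)
  expect_equal(move_probability(0, 5), 0)  # below the transport threshold
  # monotone: non-increasing in PC, non-decreasing in omega
  pcs <- seq(0, 1, 0.1)
  expect_true(all(diff(move_probability(pcs, 12)) <= 0))
  oms <- seq(6, 16, 0.5)
  expect_true(all(diff(vapply(oms, function(o) move_probability(0.3, o),
                              numeric(1))) >= 0))
})

test_that("destination direction follows the 50/25/25 downwind rule", {
  expect_true(all(sample_destination_direction("W", 50) %in% c("E", "NE", "SE")))
  expect_true(all(sample_destination_direction("N", 50) %in% c("S", "SE", "SW")))
  set.seed(1)
  draws <- sample_destination_direction("W", 1e5)
  p_hat <- table(factor(draws, levels = c("E", "NE", "SE"))) / 1e5
  for (pair in list(c("E", 0.5), c("NE", 0.25), c("SE", 0.25))) {
    p <- as.numeric(pair[2])
    expect_lt(abs(p_hat[[pair[1]]] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("slow winds and storm winds leave the state untouched", {
  st <- flat_state()
  expect_identical(aeolian_event(st, wind_record(5, "W"), sp)$H, st$H)
  expect_message(out <- aeolian_event(st, wind_record(17, "W"), sp),
                 "storm threshold")
  expect_identical(out$H, st$H)
})

test_that("a bare single slab is carried the full distance downwind", {
  g <- grid_spec(15, 15)
  H <- matrix(0L, 15, 15); H[8, 8] <- 1L
  st <- island_state(g, H = H)
  set.seed(2)
  out <- aeolian_event(st, wind_record(16, "W"), sp)  # distance 3, rho = 1
  landed <- which(out$H == 1L, arr.ind = TRUE)
  expect_equal(nrow(landed), 1)
  expect_equal(unname(landed[1, "col"]), 11)             # 3 cells east
  expect_true(unname(landed[1, "row"]) %in% c(5, 8, 11)) # E, NE, or SE lobe
  expect_equal(sum(out$H), 1L)
})

test_that("slab count is conserved when no slab can reach the boundary", {
  # the maximum carry is 3 cells, so a block with a >= 4-cell water margin
  # conserves mass over a single event; repeat over fresh random basins
  set.seed(9)
  g <- grid_spec(20, 20)
  for (i in 1:20) {
    H <- matrix(0L, 20, 20)
    H[5:16, 5:16] <- matrix(sample(0:6, 144, TRUE), 12, 12)
    st <- island_state(g, H = H)
    out <- aeolian_event(st, wind_record(runif(1, 6, 16), sample(COMPASS, 1)), sp)
    expect_equal(sum(out$H), sum(H))
  }
})

test_that("single-slab displacement matches the enumerated transport kernel", {
  # oracle: enumerate the event outcome law for omega = 10 m/s, bare sand,
  # wind from the west: rho = (1-0)*(10-6)/10 = 0.4, distance 2 cells;
  # P(stay) = 0.6, P(E+2) = 0.4*0.5, P(NE+2) = P(SE+2) = 0.4*0.25
  g <- grid_spec(9, 9)
  H0 <- matrix(0L, 9, 9); H0[5, 5] <- 1L
  base <- island_state(g, H = H0)
  expected <- c(stay = 0.6, E = 0.2, NE = 0.1, SE = 0.1)
  outcome_of <- function(out) {
    pos <- which(out$H == 1L, arr.ind = TRUE)
    if (pos[1, "col"] == 5) "stay"
    else if (pos[1, "row"] == 5) "E" else if (pos[1, "row"] == 3) "NE" else "SE"
  }
  set.seed(123)
  n <- 1e5
  got <- character(n)
  for (i in seq_len(n))
    got[i] <- outcome_of(aeolian_event(base, wind_record(10, "W"), sp))
  p_hat <- table(factor(got, levels = names(expected))) / n
  for (k in names(expected)) {
    p <- expected[[k]]
    expect_lt(abs(p_hat[[k]] - p), 3 * sqrt(p * (1 - p) / n))
  }
})
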