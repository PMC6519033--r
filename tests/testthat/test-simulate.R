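test_that("scenario grids have factorial cardinality in deterministic order", {
  g <- scenario_grid(c(10, 16, 20), c(1000, 2000, 3000),
                     seq(0, 0.1, length.out = 111), 0.01)
  expect_equal(nrow(g), 999)
  expect_equal(nrow(constant_rate_grid()), 999)
  expect_equal(nrow(scenario_grid(5, 1000, 0.01, 0.01)), 1)
  expect_equal(nrow(scenario_grid(c(10, 16), 1000, seq(0.01, 0.05, length.out = 5),
                                  0.01, replicates = 2)), 20)
  # deterministic order: n, then length, then rho ascending
  expect_true(!is.unsorted(g$n))
  expect_equal(g$rho[1:111], seq(0, 0.1, length.out = 111))
  expect_error(scenario_grid(numeric(0), 1000, 0.01, 0.01), "non-empty")
  expect_error(scenario_grid(10, 1000, -0.01, 0.01), ">= 0")
  expect_error(scenario_grid(10, 1000, 0.01, 0), "theta")
})

test_that("hotspot maps reproduce their design", {
  m <- hotspot_map(30000, 0.001,
                   data.frame(start = c(10000, 20000), length = 1000,
                              intensity = c(20, 35)))
  expect_equal(n_blocks(m), 5)
  expect_equal(m$rates, c(0.001, 0.02, 0.001, 0.035, 0.001))
  expect_equal(m$breakpoints, c(10000, 11000, 20000, 21000))
  expect_equal(rho_at(m, c(0, 10500, 15000, 20999, 29999)),
               c(0.001, 0.02, 0.001, 0.035, 0.001))

  # no hotspots: a single background block
  flat <- hotspot_map(5000, 0.01, data.frame(start = numeric(0),
                                             length = numeric(0),
                                             intensity = numeric(0)))
  expect_equal(n_blocks(flat), 1)
  expect_equal(flat$rates, 0.01)

  # a 1 Mb map with 15 interior hotspots has 31 blocks
  nat <- natural_hotspot_map(1e6, 0.005)
  expect_equal(n_blocks(nat), 31)
  expect_equal(sum(nat$rates == 0.005), 16)

  expect_error(hotspot_map(1000, 0.01,
                           data.frame(start = c(100, 150), length = 100,
                                      intensity = 5)), "overlap")
  expect_error(hotspot_map(1000, 0.01,
                           data.frame(start = 950, length = 100,
                                      intensity = 5)), "outside")
  expect_error(hotspot_map(1000, 0.01,
                           data.frame(start = 100, length = 100,
                                      intensity = 0.5)), "intensity")
})

test_that("simple-setup design constants are as specified", {
  # background grid, intensity and length menus of the single-hotspot setups
  bgs <- seq(0.001, 0.03, length.out = 15)
  expect_equal(length(bgs), 15)
  expect_equal(range(bgs), c(0.001, 0.03))
  ints <- c(5, 10, 15, 20, 40)
  lens <- 1 / c(5, 10, 20, 35, 50)
  m <- hotspot_map(10000, 0.001, data.frame(start = 1000,
                                            length = 10000 * lens[1],
                                            intensity = ints[5]))
  expect_equal(max(m$rates), 0.04)
})

test_that("bottleneck-growth demography encodes the three epochs", {
  dem <- bottleneck_growth_demography()
  expect_equal(demography_eta(dem, -0.25), 100)
  expect_equal(demography_eta(dem, 0), 100)
  expect_equal(demography_eta(dem, -0.55), 0.1)
  expect_equal(demography_eta(dem, -0.5), 0.1)   # boundary: -0.5 < t excluded
  expect_equal(demography_eta(dem, -1.0), 1)
  expect_equal(demography_eta(dem, -0.58), 1)
  expect_equal(dem$relative_sizes, c(100, 0.1, 1))
})

test_that("simulation is seed-deterministic and respects theta", {
  m <- recomb_map(1000, numeric(0), 0.01)
  a1 <- simulate_alignment(m, 10, 0.01, seed = 5)
  a2 <- simulate_alignment(m, 10, 0.01, seed = 5)
  expect_identical(a1, a2)
  a3 <- simulate_alignment(m, 10, 0.01, seed = 6)
  expect_false(identical(a1, a3))
  expect_equal(a1$n, 10)
  expect_equal(a1$length_bp, 1000)
  # theta -> 0: no segregating sites with overwhelming probability
  a0 <- simulate_alignment(m, 6, 1e-9, seed = 7)
  expect_equal(a0$S, 0)
})

test_that("segregating sites match Watterson's expectation for n = 2", {
  # E[S] = theta * L * a_2 = 10 for theta = 0.01, L = 1000
  m <- recomb_map(1000, numeric(0), 0)
  alns <- simulate_alignments(rep(list(m), 400), n = 2, theta = 0.01,
                              seed = 9)
  S <- vapply(alns, function(a) a$S, numeric(1))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 10), 3 * se)
})

test_that("simulation under demography changes the data distribution", {
  m <- recomb_map(2000, numeric(0), 0.005)
  dem <- bottleneck_growth_demography()
  neut <- simulate_alignments(rep(list(m), 40), 10, 0.01, NULL, seed = 31)
  bot <- simulate_alignments(rep(list(m), 40), 10, 0.01, dem, seed = 31)
  s_n <- mean(vapply(neut, function(a) a$S, numeric(1)))
  s_b <- mean(vapply(bot, function(a) a$S, numeric(1)))
  # the long large-size recent epoch inflates tree length
  expect_gt(s_b, s_n)
})
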