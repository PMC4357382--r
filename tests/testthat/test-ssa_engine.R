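test_that("an absorbing state yields the absorbed signal and no state change", {
  net <- decay_network(0.5)
  ev <- draw_next_event(c(X = 0L), net)
  expect_true(ev$absorbed)
  expect_identical(ev$wait, Inf)
  tr <- simulate_network(net, c(X = 3L), sim_config(t_end = 1000, burn_in = 0,
                                                    seed = 1, record_mode = "event"))
  expect_true(tr$absorbed)
  expect_identical(tr$counts[nrow(tr$counts), "X"][[1]], 0L)
})

test_that("waiting times match the analytic exponential mean", {
  # single channel X -> 0 at rate c with X = n: mean wait 1/(c n)
  c_ <- 0.1; n <- 50L
  net <- decay_network(c_)
  set.seed(42)
  waits <- replicate(20000, draw_next_event(c(X = n), net)$wait)
  mu <- 1 / (c_ * n)
  se <- mu / sqrt(length(waits))  # exponential: sd = mean
  expect_lt(abs(mean(waits) - mu), 3 * se)
})

test_that("equal-propensity channels are selected symmetrically", {
  net <- capswitch:::.make_network("X", list(
    list(reac = c(X = 1), prod = c(X = 1), rate = 1),
    list(reac = c(X = 1), prod = c(X = 1), rate = 1)))
  set.seed(43)
  picks <- replicate(20000, draw_next_event(c(X = 5L), net)$reaction)
  p_hat <- mean(picks == 1L)
  se <- sqrt(0.25 / length(picks))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("simulation is deterministic for a fixed seed", {
  net <- build_growth_capsulation_network(default_rates())
  s0 <- initialize_state(seed = 3)
  cfg <- sim_config(t_end = 5000, burn_in = 1000, seed = 11, record_mode = "event")
  t1 <- simulate_network(net, s0, cfg)
  t2 <- simulate_network(net, s0, cfg)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$counts, t2$counts)
})

test_that("trajectory records respect the burn-in window and stay non-negative", {
  net <- birth_death_network(2, 0.05)
  for (mode in c("event", "grid")) {
    tr <- simulate_network(net, c(X = 0L),
                           sim_config(t_end = 3000, burn_in = 500, seed = 4,
                                      record_mode = mode, grid_step = 10))
    expect_gte(min(tr$times), 500)
    expect_lte(max(tr$times), 3000)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(tr$counts >= 0L))
    expect_identical(tr$times[1], 500)  # state prevailing at burn-in
  }
})

test_that("degenerate windows are rejected", {
  expect_error(sim_config(t_end = 1000, burn_in = 1000), "burn_in")
  expect_error(sim_config(t_end = 0), "t_end")
})

test_that("the max_events safety cap raises a truncation error", {
  net <- birth_death_network(100, 0.001)
  expect_error(
    simulate_network(net, c(X = 0L),
                     sim_config(t_end = 1e6, burn_in = 0, seed = 1,
                                max_events = 500)),
    "max_events")
})

test_that("birth-death occupancy matches the Poisson stationary law", {
  # 0 -> X at a, X -> 0 at b: stationary distribution Poisson(a/b)
  a <- 5; b <- 0.1
  net <- birth_death_network(a, b)
  tr <- simulate_network(net, c(X = 50L),
                         sim_config(t_end = 55000, burn_in = 5000, seed = 9,
                                    grid_step = 50))
  x <- tr$counts[, "X"]
  expect_lt(abs(mean(x) - a / b), 3 * sqrt(a / b) / sqrt(length(x)))
  # Poisson: variance equals the mean (generous factor for autocorrelation)
  expect_lt(abs(var(x) / mean(x) - 1), 0.25)
})

test_that("event-count scaling is linear in the rate constant", {
  # pure birth 0 -> X: events in [0, T] ~ Poisson(k T)
  run <- function(k, seed) {
    net <- birth_death_network(k, 0)
    simulate_network(net, c(X = 0L),
                     sim_config(t_end = 1000, burn_in = 0, seed = seed))$n_events
  }
  n1 <- run(2, 21); n2 <- run(4, 22)
  expect_lt(abs(n1 - 2000), 3 * sqrt(2000))
  expect_lt(abs(n2 - 4000), 3 * sqrt(4000))
})

test_that("to_grid is sample-and-hold and preserves occupancy", {
  tr <- square_wave_traj(d_low = 70, d_high = 30, n_cycles = 5)
  g <- to_grid(tr, 1)
  expect_true(all(g$counts[, "CA"] %in% c(0L, 200L)))
  occ_exact <- 0.7
  occ_grid <- mean(g$counts[, "CA"] == 0L)
  expect_lt(abs(occ_grid - occ_exact), 1 / 100)  # within one grid step per cycle
  # constant trajectory: every grid point equals the constant
  ct <- make_ca_traj(c(0, 10), c(5, 5), t_end = 100)
  expect_true(all(to_grid(ct, 10)$counts[, "CA"] == 5L))
  # step equal to the window: single sample at the window start
  g1 <- to_grid(tr, 500)
  expect_identical(g1$times[1], 0)
  expect_error(to_grid(tr, 1000), "window")
  expect_error(to_grid(tr, -1), "positive")
})

test_that("trajectories round-trip through TSV + JSON sidecar", {
  net <- build_growth_capsulation_network(default_rates())
  s0 <- initialize_state(seed = 5)
  tr <- simulate_network(net, s0, sim_config(t_end = 3000, burn_in = 500,
                                             seed = 6, grid_step = 100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times)
  expect_identical(back$counts, tr$counts)
  expect_equal(back$rates, tr$rates)
  expect_identical(back$config$t_end, tr$config$t_end)
})
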