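test_that("parameter validation enforces the growth-cost ordering", {
  expect_error(microcolony_params(growth_rate_cap_low = 0.011,
                                  growth_rate_cap_high = 0.012), "costly")
  expect_error(microcolony_params(total_time = 0), "positive")
})

test_that("a switch-free colony is a pure birth process at the Cap- rate", {
  # log population vs time slope recovers the generating Malthusian rate
  rate <- 0.0116
  slopes <- vapply(1:20, function(seed) {
    p <- microcolony_params(per_cell_switch_rate = 0, total_time = 800,
                            seed = seed)
    tree <- generate_microcolony(p)
    fit <- estimate_growth_rate(tree, "CAP_LOW")
    fit$rate
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - rate), 3 * se)
})

test_that("population bookkeeping is self-consistent", {
  p <- microcolony_params(total_time = 500, seed = 2)
  tree <- generate_microcolony(p)
  # census totals match the division count reconstruction at census times
  tot <- tree$census$n_cap_low + tree$census$n_cap_high
  expect_identical(population_size(tree, tree$census$time_min), as.integer(tot))
  # parent division time equals the children's birth time; binary divisions
  kids <- tree$cells[tree$cells$parent > 0L, ]
  expect_true(all(abs(tree$cells$division_min[kids$parent] - kids$birth_min) < 1e-12))
  expect_true(all(table(kids$parent) == 2L))
  # alive cells have no division time
  expect_identical(sum(is.na(tree$cells$division_min)), as.integer(tot[length(tot)]))
})

test_that("Cap+ founders revert to Cap- quickly and before any forward switch", {
  for (seed in 1:20) {
    p <- microcolony_params(founder_phenotype = "CAP_HIGH",
                            founder_reversion_rate = 1,  # mean 1 min
                            total_time = 300, seed = seed)
    tree <- generate_microcolony(p)
    expect_gt(nrow(tree$events), 0L)
    first <- tree$events[which.min(tree$events$time_min), ]
    expect_identical(first$from, "CAP_HIGH")
    expect_identical(first$to, "CAP_LOW")
  }
})

test_that("no switch ever fires below a hard (sd = 0) threshold", {
  p <- microcolony_params(switch_threshold_mean = 8, switch_threshold_sd = 0,
                          per_cell_switch_rate = 5, total_time = 400, seed = 6)
  tree <- generate_microcolony(p)
  sw <- tree$events[tree$events$to == "CAP_HIGH", ]
  expect_gt(nrow(sw), 0L)
  expect_true(all(sw$population >= 8))
})

test_that("first-switch sizes recover the generating Gaussian mean (CLT)", {
  n <- 30; mu <- 200; sigma <- 50
  set.seed(99)
  sizes <- vapply(seq_len(n), function(i) {
    p <- microcolony_params(switch_threshold_mean = mu, switch_threshold_sd = sigma,
                            total_time = 1200)
    as.numeric(first_switch_size(generate_microcolony(p, stop_at_first_switch = TRUE)))
  }, 0)
  expect_true(all(is.finite(sizes)))
  expect_lt(abs(mean(sizes) - mu), 3 * sigma / sqrt(n))
})

test_that("threshold-dominated first-switch sizes look Gaussian", {
  # in the high-switch-rate limit the first-switch size converges to the
  # drawn Gaussian threshold; Shapiro should rarely reject
  set.seed(123)
  reject <- vapply(1:12, function(b) {
    sizes <- vapply(1:40, function(i) {
      p <- microcolony_params(switch_threshold_mean = 200,
                              switch_threshold_sd = 50,
                              per_cell_switch_rate = 1, total_time = 1200)
      as.numeric(first_switch_size(generate_microcolony(p, stop_at_first_switch = TRUE)))
    }, 0)
    shapiro.test(sizes)$p.value < 0.01
  }, TRUE)
  expect_lte(sum(reject), 1L)
})

test_that("censored colonies are flagged and growth cost orders population sizes", {
  # unreachable threshold: observation ends with no switch
  p <- microcolony_params(switch_threshold_mean = 1e9, switch_threshold_sd = 0,
                          total_time = 300, seed = 3)
  s <- first_switch_size(generate_microcolony(p))
  expect_true(is.na(s))
  expect_true(attr(s, "censored"))
  expect_gt(attr(s, "final_size"), 1)
  # Cap+ founder trees have no defined first-switch size
  ph <- microcolony_params(founder_phenotype = "CAP_HIGH", seed = 1,
                           total_time = 100)
  expect_error(first_switch_size(generate_microcolony(ph)), "Cap\\+ founder")
  # all-Cap+ colonies grow more slowly than all-Cap- colonies: compare the
  # mean fitted Malthusian rates (final sizes alone are swamped by the
  # unit-exponential founder factor of the branching process)
  set.seed(8)
  lo <- vapply(1:15, function(s) {
    p <- microcolony_params(per_cell_switch_rate = 0, total_time = 800)
    estimate_growth_rate(generate_microcolony(p), "CAP_LOW")$rate
  }, 0)
  hi <- vapply(1:15, function(s) {
    p <- microcolony_params(per_cell_switch_rate = 0,
                            founder_phenotype = "CAP_HIGH",
                            founder_reversion_rate = 0, total_time = 800)
    estimate_growth_rate(generate_microcolony(p), "CAP_HIGH")$rate
  }, 0)
  expect_gt(mean(lo), mean(hi))
})

test_that("assay counts are exact binomial draws with edge cases honoured", {
  expect_true(all(generate_assay(0, seed = 1)$capsulated == 0L))
  expect_true(all(generate_assay(1, seed = 1)$capsulated == 500L))
  expect_error(generate_assay(1.5), "\\[0, 1\\]")
  # binomial oracle at the published switcher proportion
  set.seed(10)
  grand <- replicate(400, mean(generate_assay(0.084)$capsulated / 500))
  se <- sqrt(0.084 * (1 - 0.084) / 500 / 5) / sqrt(length(grand))
  expect_lt(abs(mean(grand) - 0.084), 3 * se)
})

test_that("lineage trees serialize with phenotype histories", {
  p <- microcolony_params(switch_threshold_mean = 20, switch_threshold_sd = 2,
                          total_time = 400, seed = 4)
  tree <- generate_microcolony(p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lineage(tree, path)
  df <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(df), nrow(tree$cells))
  expect_true(any(grepl("CAP_HIGH@", df$phenotype)))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$n_cells, nrow(tree$cells))
})
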