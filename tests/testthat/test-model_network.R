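test_that("the canonical network has exactly one reaction per rate constant", {
  net <- build_growth_capsulation_network(default_rates())
  expect_length(net$reactions, 23L)
  expect_identical(colnames(net$reactants), cap_rate_names())
  expect_setequal(vapply(net$reactions, `[[`, "", "rate"), cap_rate_names())
  # every reaction has at least one reactant or product
  expect_true(all(colSums(net$reactants) + colSums(net$products) > 0))
})

test_that("rate validation names the offending constant", {
  r <- default_rates()
  r["k_tl_ca"] <- -1
  expect_error(build_growth_capsulation_network(r), "k_tl_ca")
  expect_error(build_growth_capsulation_network(r[-1]), "k_uxp_prod")
})

test_that("zero UXP production leaves sequestration release as the only UXP source", {
  r <- default_rates()
  r["k_uxp_prod"] <- 0
  net <- build_growth_capsulation_network(r)
  set.seed(1)
  for (i in 1:10) {
    state <- initialize_state()
    state["A_UXP"] <- 3L; state["CA"] <- 5L; state["mRNAca"] <- 2L
    a <- propensities(net, state)
    expect_identical(unname(a["k_uxp_prod"]), 0)
    makes_uxp <- net$products["UXP", ] > net$reactants["UXP", ]
    expect_identical(names(which(makes_uxp & a > 0)), "k_seq_off")
  }
})

test_that("empty-reactant channels have zero propensity", {
  net <- build_growth_capsulation_network(default_rates())
  state <- stats::setNames(integer(13), cap_species())
  state["DNAca_free"] <- 1L; state["DNAr_free"] <- 1L; state["A"] <- 5L
  a <- propensities(net, state)
  expect_identical(unname(a["k_cap_feedback"]), 0)
  expect_identical(unname(a["k_pyrg_drain"]), 0)
})

test_that("every reaction conserves promoter copy totals", {
  net <- build_growth_capsulation_network(default_rates())
  ca_idx <- c("DNAca_free", "DNAca_act", "DNAca_rep")
  r_idx <- c("DNAr_free", "DNAr_act")
  delta <- net$products - net$reactants
  expect_true(all(colSums(delta[ca_idx, ]) == 0))
  expect_true(all(colSums(delta[r_idx, ]) == 0))
})

test_that("propensities are linear in the rate constant and use combinatorial mass action", {
  net <- build_growth_capsulation_network(default_rates())
  state <- initialize_state(default_init_config(c(120, 120), c(10, 10)))
  state["R"] <- 7L; state["CA"] <- 3L; state["mRNAca"] <- 2L
  a1 <- propensities(net, state)
  net10 <- build_growth_capsulation_network(perturb_rate(default_rates(), "k_dim_on", 10))
  a10 <- propensities(net10, state)
  expect_equal(unname(a10["k_dim_on"]), 10 * unname(a1["k_dim_on"]))
  expect_equal(unname(a10[names(a10) != "k_dim_on"]),
               unname(a1[names(a1) != "k_dim_on"]))
  # R + R -> R2 at R = 7: k * 7 * 6 / 2
  expect_equal(unname(a1["k_dim_on"]), default_rates()[["k_dim_on"]] * 21)
})

test_that("randomized initial states respect the UXP > activator constraint", {
  for (seed in 1:25) {
    s <- initialize_state(seed = seed)
    expect_gt(s[["UXP"]], s[["A"]] + s[["A_UXP"]])
    expect_identical(s[["DNAca_free"]], 1L)
    expect_identical(s[["DNAr_free"]], 1L)
  }
  expect_identical(initialize_state(seed = 7), initialize_state(seed = 7))
  # degenerate ranges give exactly the configured state
  s <- initialize_state(default_init_config(c(100, 100), c(10, 10)))
  expect_identical(s[["UXP"]], 100L)
  expect_identical(s[["A"]], 10L)
  expect_true(all(s[setdiff(cap_species(),
                            c("UXP", "A", "DNAca_free", "DNAr_free"))] == 0L))
  expect_error(initialize_state(default_init_config(c(5, 5), c(10, 10))),
               "UXP > activator")
})

test_that("perturb_rate scales one constant and is invertible", {
  r <- default_rates()
  p <- perturb_rate(r, "k_deg_CA", 10)
  expect_equal(p[["k_deg_CA"]], 10 * r[["k_deg_CA"]])
  expect_identical(p[names(p) != "k_deg_CA"], r[names(r) != "k_deg_CA"])
  expect_identical(perturb_rate(r, "k_deg_CA", 1), r)
  back <- perturb_rate(perturb_rate(r, "k_tl_ca", 10), "k_tl_ca", 0.1)
  expect_equal(back, r, tolerance = 1e-12)
  expect_error(perturb_rate(r, "k_bogus", 2), "valid names")
  expect_error(perturb_rate(r, "k_deg_CA", 0), "positive")
})

test_that("network configuration round-trips through JSON and YAML", {
  r <- perturb_rate(default_rates(), "k_seq_on", 3.7)
  init <- default_init_config(c(60, 90), c(4, 9), 2L, 1L)
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network_config(path, r, init)
    got <- read_network_config(path)
    expect_equal(got$rates, r, tolerance = 1e-12)
    expect_identical(got$init$uxp_range, init$uxp_range)
    expect_identical(got$init$dna_ca_copies, init$dna_ca_copies)
  }
})

test_that("the shipped default config matches default_rates()", {
  path <- system.file("extdata", "growth_capsulation_default.json",
                      package = "capswitch")
  expect_true(nzchar(path))
  expect_equal(read_network_config(path)$rates, default_rates(), tolerance = 1e-12)
})

test_that("the reaction dump is one parseable line per reaction", {
  net <- build_growth_capsulation_network(default_rates())
  txt <- format_reactions(net)
  expect_length(txt, 23L)
  expect_true(all(grepl("^.+ -> .+ @ k_", txt)))
  expect_match(txt[2], "UXP \\+ CA -> 2 CA")
})
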