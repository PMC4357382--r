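test_that("deterministic synchronous doubling recovers ln(2)/interval exactly", {
  tree <- synchronous_tree(interval = 60, n_doublings = 10)
  fit <- estimate_growth_rate(tree, "CAP_LOW")
  expect_lt(abs(fit$rate - log(2) / 60), 1e-6)
  expect_equal(fit$doubling_min, log(2) / fit$rate)
  expect_identical(fit$phenotype, "CAP_LOW")
})

test_that("growth estimation requires enough same-phenotype observations", {
  tree <- synchronous_tree(n_doublings = 2)  # never reaches 32 cells
  expect_error(estimate_growth_rate(tree, "CAP_LOW"), "insufficient")
  expect_error(estimate_growth_rate(synchronous_tree(n_doublings = 10), "CAP_HIGH"),
               "insufficient")
})

test_that("capsulation cost reproduces the printed ~3% arithmetic", {
  cost <- capsulation_cost(growth_fit(0.0116), growth_fit(0.0113))
  expect_equal(cost$cost_percent, 100 * (1 - 0.0113 / 0.0116))
  expect_lt(abs(cost$cost_percent - 2.59), 0.01)
  expect_equal(capsulation_cost(growth_fit(0.01), growth_fit(0.01))$cost_percent, 0)
  expect_equal(capsulation_cost(growth_fit(0.02), growth_fit(0.01))$cost_percent, 50)
  # SE propagation is symmetric in relative errors
  c2 <- capsulation_cost(growth_fit(0.0116, 6.1e-5), growth_fit(0.0113, 2.5e-4))
  expect_true(is.finite(c2$se_percent) && c2$se_percent > 0)
})

test_that("doubling times match the printed division times to one decimal", {
  expect_equal(round(growth_fit(0.0113)$doubling_min, 1), 61.3)
  expect_equal(round(growth_fit(0.0116)$doubling_min, 1), 59.8)
})

test_that("threshold model fits recover a Gaussian mechanism", {
  set.seed(21)
  sizes <- round(rnorm(58, 1870, 660))
  fit <- fit_threshold_models(sizes)
  expect_identical(fit$preferred, "gaussian")
  expect_lt(abs(fit$gaussian$mean - 1870), 3 * 660 / sqrt(58))
  expect_equal(fit$gaussian$aic, 2 * 2 - 2 * fit$gaussian$loglik)
  expect_equal(fit$memoryless$aic, 2 * 1 - 2 * fit$memoryless$loglik)
  expect_error(fit_threshold_models(c(1500, 1500)), "at least 5")
})

test_that("model selection matches the generating mechanism in most batches", {
  set.seed(22)
  gauss_pref <- vapply(1:50, function(b) {
    fit_threshold_models(round(rnorm(58, 1870, 660)))$preferred
  }, "")
  mem_pref <- vapply(1:50, function(b) {
    fit_threshold_models(rmemoryless_sizes(58, 1 / 1869))$preferred
  }, "")
  expect_gte(mean(gauss_pref == "gaussian"), 0.9)
  expect_gte(mean(mem_pref == "memoryless"), 0.9)
})

test_that("censored sizes enter both likelihoods as survival terms", {
  set.seed(23)
  sizes <- round(rnorm(40, 1870, 660))
  fit_plain <- fit_threshold_models(sizes)
  # heavy right-censoring just below the mean pushes the fitted mean up
  fit_cens <- fit_threshold_models(sizes, censor_sizes = rep(1800, 40))
  expect_gt(fit_cens$gaussian$mean, fit_plain$gaussian$mean)
  expect_lt(fit_cens$memoryless$hazard, fit_plain$memoryless$hazard)
  # data-frame input from first_switch_sizes() is accepted
  df <- data.frame(size = c(sizes, rep(NA, 3)),
                   censored = c(rep(FALSE, 40), rep(TRUE, 3)),
                   censor_size = c(rep(NA, 40), rep(2000, 3)))
  expect_s3_class(fit_threshold_models(df), "cap_threshold_fit")
})

test_that("assay proportions report the replicate-based mean and SE", {
  assay <- structure(data.frame(replicate = 1:5, cells = 500,
                                capsulated = rep(42L, 5)),
                     class = c("cap_assay", "data.frame"))
  est <- proportion_capsulated(assay)
  expect_equal(est$mean, 0.084)
  expect_equal(est$se, 0)
  zero <- structure(data.frame(replicate = 1:3, cells = 500,
                               capsulated = 0L),
                    class = c("cap_assay", "data.frame"))
  expect_equal(proportion_capsulated(zero)$mean, 0)
  expect_error(proportion_capsulated(assay[1, , drop = FALSE]), "single replicate")
  # binomial oracle at the published ancestral proportion
  set.seed(30)
  grand <- replicate(500, proportion_capsulated(generate_assay(0.0016))$mean)
  se <- sqrt(0.0016 * (1 - 0.0016) / 500 / 5) / sqrt(length(grand))
  expect_lt(abs(mean(grand) - 0.0016), 3 * se)
})

test_that("the two-sample policy selects branches as stated", {
  set.seed(31)
  x <- rnorm(8)
  res <- two_sample_compare(x, x)
  expect_identical(res$branch, "parametric")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res_w <- two_sample_compare(x, x, policy = "nonparametric")
  expect_identical(res_w$test, "Wilcoxon rank-sum")
  expect_equal(res_w$p_value, 1)
  # well-separated near-constant Gaussian samples: parametric, p < 0.001
  a <- 0.08 + rnorm(5, sd = 1e-4)
  b <- 0.0016 + rnorm(5, sd = 1e-4)
  res2 <- two_sample_compare(a, b)
  expect_identical(res2$branch, "parametric")
  expect_lt(res2$p_value, 0.001)
  # heavily tied, skewed samples go nonparametric
  u <- c(0, 0, 0, 0, 0, 0, 0, 5)
  v <- c(0, 0, 0, 0, 0, 1, 4, 6)
  res3 <- two_sample_compare(u, v)
  expect_identical(res3$branch, "nonparametric")
  expect_error(two_sample_compare(1:2, 1:5), "at least 3")
})
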