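#' Construct a growth-rate fit object
#'
#' @param rate Growth rate (min^-1), the Malthusian parameter.
#' @param se Standard error of the rate.
#' @param n Number of observations behind the fit.
#' @param phenotype Phenotype label.
#' @return An object of class `cap_growth_fit` with the implied doubling
#'   time `ln(2)/rate` (minutes).
#' @export
growth_fit <- function(rate, se = NA_real_, n = NA_integer_,
                       phenotype = NA_character_) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  structure(list(rate = rate, se = se, n = n, phenotype = phenotype,
                 doubling_min = log(2) / rate),
            class = "cap_growth_fit")
}

#' @export
print.cap_growth_fit <- function(x, ...) {
  cat(sprintf("growth rate %.4g min^-1 (SE %.3g, n = %s, %s); doubling %.1f min\n",
              x$rate, x$se, x$n, x$phenotype, x$doubling_min))
  invisible(x)
}

#' Estimate a phenotype's growth rate from a lineage tree
#'
#' Least-squares slope of `ln(population)` versus time, restricted to
#' same-phenotype growth epochs: maximal intervals during which every alive
#' cell carries the requested phenotype. Epochs get separate intercepts but
#' share the slope. Observations with fewer than `min_cells` cells are
#' excluded, which suppresses the small-colony transient of the branching
#' process where `ln(population)` has not yet settled onto its asymptotic
#' linear growth.
#'
#' @param tree A `cap_lineage`.
#' @param phenotype `"CAP_LOW"` or `"CAP_HIGH"`.
#' @param min_cells Minimum population for an observation to enter the fit
#'   (default 32).
#' @return A `cap_growth_fit` (see [growth_fit()]).
#' @export
estimate_growth_rate <- function(tree, phenotype = c("CAP_LOW", "CAP_HIGH"),
                                 min_cells = 32L) {
  phenotype <- match.arg(phenotype)
  cz <- tree$census
  this <- if (phenotype == "CAP_LOW") cz$n_cap_low else cz$n_cap_high
  other <- if (phenotype == "CAP_LOW") cz$n_cap_high else cz$n_cap_low
  use <- other == 0L & this >= min_cells
  if (sum(use) < 3L)
    stop("insufficient observations (", sum(use), " same-phenotype records with >= ",
         min_cells, " cells; need >= 3)")
  epoch <- cumsum(c(1L, diff(which(use)) > 1L))
  d <- data.frame(t = cz$time_min[use], logn = log(this[use]),
                  epoch = factor(epoch))
  fit <- if (nlevels(d$epoch) > 1L) lm(logn ~ 0 + epoch + t, data = d)
         else lm(logn ~ t, data = d)
  rate <- unname(coef(fit)["t"])
  # a deterministic tree fits exactly; the zero-residual warning is benign
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[["t"]])
  if (!is.finite(rate) || rate <= 0)
    stop("estimated growth rate is not positive (", format(rate), ")")
  growth_fit(rate, se, nrow(d), phenotype)
}

#' Capsulation cost from two growth fits
#'
#' The relative growth-rate deficit of Cap+ cells,
#' `100 * (1 - rate_high / rate_low)` percent, with the standard error
#' propagated from both fits. At the measured rates 0.0116 and 0.0113
#' min^-1 the cost is ~3%.
#'
#' @param fit_low Cap- growth fit (a `cap_growth_fit`).
#' @param fit_high Cap+ growth fit.
#' @return List with `cost_percent` and `se_percent`.
#' @export
#' @examples
#' capsulation_cost(growth_fit(0.0116), growth_fit(0.0113))$cost_percent
capsulation_cost <- function(fit_low, fit_high) {
  rl <- fit_low$rate; rh <- fit_high$rate
  if (!is.finite(rl) || rl <= 0) stop("Cap- rate must be positive")
  if (!is.finite(rh) || rh <= 0) stop("Cap+ rate must be positive")
  cost <- 100 * (1 - rh / rl)
  se <- if (is.finite(fit_low$se) && is.finite(fit_high$se))
    100 * (rh / rl) * sqrt((fit_high$se / rh)^2 + (fit_low$se / rl)^2)
  else NA_real_
  list(cost_percent = cost, se_percent = se)
}

# Censored log-likelihoods of the two first-switch-size models.
.loglik_gaussian <- function(par, x, cens) {
  mu <- par[1L]; sigma <- par[2L]
  if (sigma <= 0) return(-Inf)
  ll <- sum(dnorm(x, mu, sigma, log = TRUE))
  if (length(cens))
    ll <- ll + sum(pnorm(cens, mu, sigma, lower.tail = FALSE, log.p = TRUE))
  ll
}

.loglik_memoryless <- function(p, x, cens) {
  # constant per-division switch probability p: a colony of size n has seen
  # n - 1 divisions, so P(first switch at size n) = (1-p)^(n-2) * p, n >= 2,
  # and P(no switch by size c) = (1-p)^(c-1).
  if (p <= 0 || p >= 1) return(-Inf)
  ll <- sum((x - 2) * log1p(-p) + log(p))
  if (length(cens)) ll <- ll + sum((cens - 1) * log1p(-p))
  ll
}

#' Fit Gaussian and memoryless models to first-switch sizes
#'
#' Maximum-likelihood fits of two models for the population size at which a
#' colony first switches Cap- to Cap+: (a) a Gaussian in population size
#' (a size-dependent threshold mechanism) and (b) a memoryless model with a
#' constant per-division switch probability, i.e. a geometric law in
#' population size — the signature of a random process independent of
#' population size. Censored colonies (no switch observed) contribute
#' survival terms to both likelihoods. Model preference is by AIC.
#'
#' @param sizes Numeric vector of observed first-switch sizes, or the data
#'   frame produced by [first_switch_sizes()].
#' @param censor_sizes Population sizes at end of observation for censored
#'   colonies (ignored when `sizes` is a data frame).
#' @return List of class `cap_threshold_fit` with `gaussian` (mean, sd,
#'   loglik, aic), `memoryless` (per-division hazard, loglik, aic),
#'   `preferred` (`"gaussian"` or `"memoryless"`), `n_events`, `n_censored`.
#' @export
fit_threshold_models <- function(sizes, censor_sizes = numeric()) {
  if (is.data.frame(sizes)) {
    censor_sizes <- sizes$censor_size[sizes$censored]
    sizes <- sizes$size[!sizes$censored]
  }
  sizes <- sizes[is.finite(sizes)]
  if (length(sizes) < 5L)
    stop("need at least 5 uncensored first-switch events (got ", length(sizes), ")")
  # Gaussian, censoring-aware
  init <- c(mean(sizes), max(sd(sizes), 1e-6))
  g <- optim(init, function(par) -.loglik_gaussian(par, sizes, censor_sizes),
             method = "Nelder-Mead")
  ll_g <- -g$value
  # memoryless: closed-form MLE of the per-division hazard
  events <- length(sizes)
  trials <- sum(sizes - 2) + sum(censor_sizes - 1) + events
  p_hat <- events / trials
  ll_m <- .loglik_memoryless(p_hat, sizes, censor_sizes)
  aic_g <- 2 * 2 - 2 * ll_g
  aic_m <- 2 * 1 - 2 * ll_m
  structure(list(
    gaussian = list(mean = g$par[1L], sd = g$par[2L], loglik = ll_g,
                    aic = aic_g, k = 2L),
    memoryless = list(hazard = p_hat, loglik = ll_m, aic = aic_m, k = 1L),
    preferred = if (aic_g < aic_m) "gaussian" else "memoryless",
    n_events = events, n_censored = length(censor_sizes)),
    class = "cap_threshold_fit")
}

#' @export
print.cap_threshold_fit <- function(x, ...) {
  cat(sprintf("gaussian: mean %.1f sd %.1f (AIC %.1f) | memoryless: hazard %.3g (AIC %.1f) | preferred: %s\n",
              x$gaussian$mean, x$gaussian$sd, x$gaussian$aic,
              x$memoryless$hazard, x$memoryless$aic, x$preferred))
  invisible(x)
}

#' Mean proportion of capsulated cells with replicate SE
#'
#' @param assay A `cap_assay` (see [generate_assay()]) or a data frame with
#'   `cells` and `capsulated` columns.
#' @return List with `mean`, `se` (sample SD of per-replicate proportions
#'   over the square root of the number of replicates) and `n_replicates`.
#' @export
proportion_capsulated <- function(assay) {
  if (nrow(assay) < 2L) stop("SE undefined with a single replicate")
  props <- assay$capsulated / assay$cells
  list(mean = mean(props), se = sd(props) / sqrt(length(props)),
       n_replicates = length(props))
}

#' Two-sample comparison with a normality-gated test policy
#'
#' Applies the published testing policy: two-sample t tests (pooled, or
#' Welch when a variance test rejects equality) when both samples pass a
#' Shapiro normality check, otherwise a Wilcoxon rank-sum test. The branch
#' that ran is recorded.
#'
#' @param x,y Numeric samples, each of size at least 3.
#' @param policy `"auto"` (normality-gated, default), `"parametric"` or
#'   `"nonparametric"`.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return List with `test`, `statistic`, `p_value`, `branch`.
#' @export
two_sample_compare <- function(x, y, policy = c("auto", "parametric",
                                                "nonparametric"),
                               alpha = 0.05) {
  policy <- match.arg(policy)
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample must contain at least 3 observations")
  normal_ok <- function(v) {
    if (length(unique(v)) < 3L) return(FALSE)  # degenerate: shapiro undefined
    shapiro.test(v)$p.value >= alpha
  }
  branch <- switch(policy,
    parametric = "parametric",
    nonparametric = "nonparametric",
    auto = if (normal_ok(x) && normal_ok(y)) "parametric" else "nonparametric")
  if (branch == "parametric") {
    equal_var <- tryCatch(var.test(x, y)$p.value >= 0.05, error = function(e) TRUE)
    res <- t.test(x, y, var.equal = equal_var)
    list(test = if (equal_var) "two-sample t" else "Welch t",
         statistic = unname(res$statistic), p_value = res$p.value,
         branch = branch)
  } else {
    res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    list(test = "Wilcoxon rank-sum", statistic = unname(res$statistic),
         p_value = res$p.value, branch = branch)
  }
}
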