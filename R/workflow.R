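#' Built-in run profiles
#'
#' `"paper"` uses the published scale: 200,000 s horizon with 10,000 s
#' burn-in, 10 sensitivity-sweep replicates per condition, 58 microcolonies.
#' `"desk"` is a reduced profile for interactive work: shorter horizon,
#' fewer replicates and colonies.
#'
#' @param profile `"desk"` or `"paper"`.
#' @return List with `sim` (a `cap_sim_config`), `dose_replicates`,
#'   `sweep_replicates`, `n_colonies`.
#' @export
run_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper")
    list(name = "paper", sim = sim_config(t_end = 200000, burn_in = 10000),
         dose_replicates = 3L, sweep_replicates = 10L, n_colonies = 58L)
  else
    list(name = "desk", sim = sim_config(t_end = 60000, burn_in = 5000),
         dose_replicates = 2L, sweep_replicates = 3L, n_colonies = 20L)
}

#' Run the full in-silico pipeline
#'
#' Composes the stages end to end: default-rate certification against the
#' calibration targets, the UXP dose sweep, the 47-condition reaction-rate
#' sensitivity sweep, a batch of synthetic microcolonies with the
#' first-switch threshold analysis, growth-rate and capsulation-cost
#' estimation, and a simulated capsule-counting assay. All outputs are TSV
#' files under `out_dir` plus a JSON manifest; every stage's randomness
#' derives from the master seed, so a rerun with the same seed reproduces
#' the TSVs byte for byte.
#'
#' @param out_dir Output directory (created if missing; must be writable).
#' @param master_seed Integer master seed.
#' @param profile `"desk"` (default) or `"paper"`; see [run_profile()].
#' @param rates Base rate set.
#' @param skip_calibration If `TRUE`, skip re-certifying the defaults (the
#'   slowest stage).
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_paper_pipeline <- function(out_dir, master_seed = 1L,
                               profile = c("desk", "paper"),
                               rates = default_rates(),
                               skip_calibration = FALSE) {
  prof <- run_profile(match.arg(profile))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("output directory is not writable: ", out_dir)

  manifest <- list(package_version = as.character(utils::packageVersion("capswitch")),
                   profile = prof$name, master_seed = master_seed,
                   stages = list(), outputs = list())
  record <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status), list(...))
  }

  # 1. calibration certificate for the shipped defaults
  if (!skip_calibration) {
    tg <- calibration_targets(n_seeds = 3)
    ev <- evaluate_calibration(rates, tg, prof$sim,
                               master_seed = .derive_seed(master_seed, 10L))
    record("calibration", if (ev$pass) "ok" else "failed",
           low = as.list(ev$low), high = as.list(ev$high))
  } else record("calibration", "skipped")

  # 2. UXP dose sweep
  dose <- run_dose_sweep(dose_sweep_config(
    replicates = prof$dose_replicates, rates = rates, sim = prof$sim,
    master_seed = .derive_seed(master_seed, 20L)))
  p_dose <- file.path(out_dir, "dose_sweep.tsv")
  write_sweep(dose, p_dose)
  record("dose_sweep", "ok", rows = nrow(dose))
  manifest$outputs$dose_sweep <- p_dose

  # 3. 47-condition sensitivity sweep
  sweep <- run_sensitivity_sweep(rates, replicates = prof$sweep_replicates,
                                 sim = prof$sim,
                                 master_seed = .derive_seed(master_seed, 30L))
  p_sweep <- file.path(out_dir, "sensitivity_sweep.tsv")
  write_sweep(sweep, p_sweep)
  for (lbl in names(sweep$curves))
    write.table(sweep$curves[[lbl]],
                file.path(out_dir, sprintf("curve_%s.tsv", lbl)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  record("sensitivity_sweep", if (sweep$failed) "partial" else "ok",
         conditions = length(unique(sweep$rows$condition)),
         rows = nrow(sweep$rows))
  manifest$outputs$sensitivity_sweep <- p_sweep

  # 4. microcolony batch + threshold analysis
  set.seed(.derive_seed(master_seed, 40L))
  trees <- lapply(seq_len(prof$n_colonies), function(i)
    generate_microcolony(microcolony_params(), stop_at_first_switch = TRUE))
  fss <- first_switch_sizes(trees)
  p_fss <- file.path(out_dir, "first_switch_sizes.tsv")
  write.table(fss, p_fss, sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- fit_threshold_models(fss)
  record("microcolony", "ok", n_colonies = prof$n_colonies,
         mean_first_switch = mean(fss$size, na.rm = TRUE),
         n_censored = sum(fss$censored),
         preferred_model = fit$preferred,
         gaussian_mean = fit$gaussian$mean, gaussian_sd = fit$gaussian$sd)
  manifest$outputs$first_switch_sizes <- p_fss

  # 5. growth-rate and cost estimation on pure-phenotype colonies
  set.seed(.derive_seed(master_seed, 50L))
  tree_lo <- generate_microcolony(microcolony_params(
    per_cell_switch_rate = 0, total_time = 800))
  tree_hi <- generate_microcolony(microcolony_params(
    per_cell_switch_rate = 0, founder_phenotype = "CAP_HIGH",
    founder_reversion_rate = 0, total_time = 800))
  fit_lo <- estimate_growth_rate(tree_lo, "CAP_LOW")
  fit_hi <- estimate_growth_rate(tree_hi, "CAP_HIGH")
  cost <- capsulation_cost(fit_lo, fit_hi)
  growth <- data.frame(
    phenotype = c("CAP_LOW", "CAP_HIGH"),
    rate_per_min = c(fit_lo$rate, fit_hi$rate),
    se = c(fit_lo$se, fit_hi$se),
    doubling_min = c(fit_lo$doubling_min, fit_hi$doubling_min))
  p_growth <- file.path(out_dir, "growth_fits.tsv")
  write.table(growth, p_growth, sep = "\t", quote = FALSE, row.names = FALSE)
  record("growth", "ok", cost_percent = cost$cost_percent)
  manifest$outputs$growth_fits <- p_growth

  # 6. capsule counting assay at the two observed proportions
  assay_anc <- generate_assay(0.0016, seed = .derive_seed(master_seed, 60L))
  assay_sw <- generate_assay(0.084, seed = .derive_seed(master_seed, 61L))
  props <- data.frame(
    strain = c("ancestor", "switcher"),
    generating_p = c(0.0016, 0.084),
    mean = c(proportion_capsulated(assay_anc)$mean,
             proportion_capsulated(assay_sw)$mean),
    se = c(proportion_capsulated(assay_anc)$se,
           proportion_capsulated(assay_sw)$se))
  p_assay <- file.path(out_dir, "assay_proportions.tsv")
  write.table(props, p_assay, sep = "\t", quote = FALSE, row.names = FALSE)
  record("assay", "ok")
  manifest$outputs$assay_proportions <- p_assay

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
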