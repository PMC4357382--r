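# Condition seeds derived from a master seed via a fixed counter scheme, so
# conditions are independent but the whole sweep is reproducible.
.derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 104729 * as.numeric(counter)) %% 2147483647L)
}

# One simulate + classify + summarize run. All randomness (initial state and
# SSA path) flows from the single seed.
.run_condition <- function(rates, init_config, sim, seed, threshold = NULL) {
  set.seed(seed)
  state <- initialize_state(init_config)
  cfg <- sim
  cfg$seed <- NULL
  net <- build_growth_capsulation_network(rates)
  traj <- simulate_network(net, state, cfg)
  segs <- classify_states(traj, threshold)
  occ <- occupancy_summary(segs, traj)
  list(traj = traj, segs = segs, occ = occ)
}

.occ_row <- function(occ) {
  dwell_low <- unname(occ$mean_dwell["CAP_LOW"])
  dwell_high <- unname(occ$mean_dwell["CAP_HIGH"])
  data.frame(fraction_cap_low = occ$fraction_cap_low,
             switch_events = occ$switch_events,
             mean_dwell_low_s = ifelse(is.na(dwell_low), NA_real_, dwell_low),
             mean_dwell_high_s = ifelse(is.na(dwell_high), NA_real_, dwell_high),
             threshold = occ$threshold,
             two_state = min(occ$fraction_cap_low, occ$fraction_cap_high) >= 0.01)
}

#' Dose-sweep configuration
#'
#' The default levels span the published 1,000-fold range of UXP production:
#' low (0.003, switchers), intermediate (0.3) and high (3, ancestors),
#' in molecules per second.
#'
#' @param levels UXP production rates (molecules/s).
#' @param replicates Simulations per level.
#' @param rates Base rate set; `k_uxp_prod` is overridden per level.
#' @param init Initial-state configuration.
#' @param sim A `cap_sim_config`.
#' @param master_seed Integer master seed for the condition-seed scheme.
#' @return A list of class `cap_dose_config`.
#' @export
dose_sweep_config <- function(levels = c(0.003, 0.3, 3), replicates = 3,
                              rates = default_rates(),
                              init = default_init_config(),
                              sim = sim_config(), master_seed = 1L) {
  if (any(levels <= 0)) stop("levels must be positive")
  structure(list(levels = levels, replicates = replicates, rates = rates,
                 init = init, sim = sim, master_seed = master_seed),
            class = "cap_dose_config")
}

#' Run the UXP dose sweep
#'
#' Simulates the network at each UXP production level, calls phenotype states
#' and summarizes occupancy per replicate. At low UXP supply trajectories
#' switch between two widely separated CAP levels; at high supply CAP stays
#' basal and the dichotomy disappears.
#'
#' @param config A `cap_dose_config`.
#' @return Data frame of class `cap_sweep_table`, one row per
#'   (level, replicate), with occupancy statistics.
#' @export
run_dose_sweep <- function(config = dose_sweep_config()) {
  rows <- list()
  counter <- 0L
  for (lv in config$levels) {
    rates <- config$rates
    rates["k_uxp_prod"] <- lv
    for (rep in seq_len(config$replicates)) {
      counter <- counter + 1L
      seed <- .derive_seed(config$master_seed, counter)
      res <- .run_condition(rates, config$init, config$sim, seed)
      rows[[counter]] <- cbind(
        data.frame(condition = sprintf("uxp_%g", lv), uxp_level = lv,
                   replicate = rep, seed = seed),
        .occ_row(res$occ))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cap_sweep_table", "data.frame")
  out
}

#' Run the one-at-a-time reaction-rate sensitivity sweep
#'
#' Each of the 23 rate constants is decreased and then increased ten-fold,
#' one at a time, and each of the resulting 46 perturbed conditions plus the
#' baseline (47 in total) is simulated `replicates` times. The fraction of
#' time spent Cap- is reported per run, averaged per condition, and the mean
#' cumulative occupancy curve over replicates is recorded per condition.
#'
#' @param base Base rate set (the baseline condition).
#' @param factor Perturbation factor (default 10).
#' @param replicates Runs per condition (default 10).
#' @param sim A `cap_sim_config`.
#' @param init Initial-state configuration.
#' @param master_seed Integer master seed.
#' @param curve_levels CAP levels for the cumulative occupancy curves
#'   (default 0 to 250).
#' @return A list of class `cap_sensitivity_sweep`: `rows` (one per
#'   condition x replicate, with per-condition failures recorded in
#'   `status`), `summary` (per-condition means and medians), and `curves`
#'   (named list of mean cumulative occupancy curves).
#' @export
run_sensitivity_sweep <- function(base = default_rates(), factor = 10,
                                  replicates = 10, sim = sim_config(),
                                  init = default_init_config(),
                                  master_seed = 1L,
                                  curve_levels = 0:250) {
  base <- .validate_rates(base)
  conditions <- data.frame(label = "baseline", rate = "baseline", factor = 1,
                           stringsAsFactors = FALSE)
  for (nm in cap_rate_names()) {
    conditions <- rbind(conditions,
      data.frame(label = sprintf("%s_x%g", nm, 1 / factor), rate = nm,
                 factor = 1 / factor),
      data.frame(label = sprintf("%s_x%g", nm, factor), rate = nm,
                 factor = factor))
  }
  # factor = 1 would otherwise give each rate the same label twice
  conditions$label <- make.unique(conditions$label)
  rows <- list()
  curves <- list()
  any_failed <- FALSE
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    rates <- if (cond$rate == "baseline") base
             else perturb_rate(base, cond$rate, cond$factor)
    cond_rows <- list()
    cond_curves <- list()
    for (rep in seq_len(replicates)) {
      # common random numbers: replicate r uses the same seed in every
      # condition, pairing conditions for the one-at-a-time comparison
      seed <- .derive_seed(master_seed, rep)
      res <- tryCatch(.run_condition(rates, init, sim, seed),
                      error = function(e) e)
      if (inherits(res, "error")) {
        any_failed <- TRUE
        cond_rows[[rep]] <- cbind(
          data.frame(condition = cond$label, rate = cond$rate,
                     factor = cond$factor, replicate = rep, seed = seed),
          data.frame(fraction_cap_low = NA_real_, switch_events = NA_integer_,
                     mean_dwell_low_s = NA_real_, mean_dwell_high_s = NA_real_,
                     threshold = NA_real_, two_state = NA),
          data.frame(status = conditionMessage(res)))
      } else {
        cond_rows[[rep]] <- cbind(
          data.frame(condition = cond$label, rate = cond$rate,
                     factor = cond$factor, replicate = rep, seed = seed),
          .occ_row(res$occ), data.frame(status = "ok"))
        cond_curves[[rep]] <-
          cumulative_occupancy_curve(res$traj, curve_levels)$cumulative_seconds
      }
    }
    rows[[ci]] <- do.call(rbind, cond_rows)
    if (length(cond_curves))
      curves[[cond$label]] <- data.frame(
        level = curve_levels,
        mean_cumulative_seconds = Reduce(`+`, cond_curves) / length(cond_curves))
  }
  rows <- do.call(rbind, rows)
  ok <- rows$status == "ok"
  summary <- do.call(rbind, lapply(split(rows[ok, ], rows$condition[ok]), function(d)
    data.frame(condition = d$condition[1L], rate = d$rate[1L],
               factor = d$factor[1L], n = nrow(d),
               mean_fraction_cap_low = mean(d$fraction_cap_low),
               median_fraction_cap_low = median(d$fraction_cap_low),
               mean_switch_events = mean(d$switch_events),
               median_switch_events = median(d$switch_events),
               prop_two_state = mean(d$two_state))))
  summary <- summary[match(conditions$label, summary$condition), ]
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary, curves = curves,
                 failed = any_failed, master_seed = master_seed),
            class = "cap_sensitivity_sweep")
}

#' Calibration targets for the default rate set
#'
#' Reaction rates were chosen so that switching is the equivalent of several
#' cell divisions apart (epigenetic heritability) in the low-UXP regime while
#' the high-UXP regime stays basal. The targets certify this: at
#' `uxp_low` both states occupy at least `min_occupancy` of the window with
#' mean dwell at least `min_dwell_s`, and switching is observed
#' (`min_switches_low` state changes per window); at `uxp_high` at most
#' `max_switches_high` state changes occur. All statistics are medians over
#' `n_seeds` seeds.
#'
#' @param uxp_low,uxp_high The low/high UXP production rates (molecules/s).
#' @param min_occupancy Minimum per-state occupancy fraction at low UXP.
#' @param min_dwell_s Minimum per-state mean dwell (seconds) at low UXP.
#' @param min_switches_low Minimum switch events per window at low UXP.
#' @param max_switches_high Maximum switch events per window at high UXP.
#' @param n_seeds Seeds per regime.
#' @return A list of class `cap_calibration_targets`.
#' @export
calibration_targets <- function(uxp_low = 0.003, uxp_high = 3,
                                min_occupancy = 0.10, min_dwell_s = 7200,
                                min_switches_low = 2, max_switches_high = 1,
                                n_seeds = 5) {
  structure(list(uxp_low = uxp_low, uxp_high = uxp_high,
                 min_occupancy = min_occupancy, min_dwell_s = min_dwell_s,
                 min_switches_low = min_switches_low,
                 max_switches_high = max_switches_high, n_seeds = n_seeds),
            class = "cap_calibration_targets")
}

#' Evaluate a rate set against the calibration targets
#'
#' @param rates Candidate rate set.
#' @param targets A `cap_calibration_targets`.
#' @param sim A `cap_sim_config`.
#' @param init Initial-state configuration.
#' @param master_seed Integer master seed.
#' @return A list with `pass` plus the measured medians.
#' @export
evaluate_calibration <- function(rates, targets = calibration_targets(),
                                 sim = sim_config(),
                                 init = default_init_config(),
                                 master_seed = 1L) {
  run_regime <- function(level, offset) {
    r <- rates
    r["k_uxp_prod"] <- level
    stats <- lapply(seq_len(targets$n_seeds), function(i) {
      res <- .run_condition(r, init, sim, .derive_seed(master_seed, offset + i))
      occ <- res$occ
      dl <- occ$mean_dwell
      pick <- function(s) if (s %in% names(dl)) dl[[s]] else NA_real_
      c(occ_low = occ$fraction_cap_low, occ_high = occ$fraction_cap_high,
        dwell_low = pick("CAP_LOW"), dwell_high = pick("CAP_HIGH"),
        switches = occ$switch_events)
    })
    m <- do.call(rbind, stats)
    apply(m, 2, median, na.rm = FALSE)
  }
  low <- run_regime(targets$uxp_low, 0L)
  high <- run_regime(targets$uxp_high, 1000L)
  pass_low <- !any(is.na(low[c("dwell_low", "dwell_high")])) &&
    min(low["occ_low"], low["occ_high"]) >= targets$min_occupancy &&
    min(low["dwell_low"], low["dwell_high"]) >= targets$min_dwell_s &&
    low["switches"] >= targets$min_switches_low
  pass_high <- high["switches"] <= targets$max_switches_high
  list(pass = isTRUE(pass_low && pass_high), low = low, high = high,
       pass_low = isTRUE(pass_low), pass_high = isTRUE(pass_high))
}

#' Calibrate default rate constants
#'
#' Checks the base guess against the calibration targets; if it fails, runs a
#' budgeted random search perturbing each rate log-uniformly around the base
#' guess until a rate set meets all targets.
#'
#' @param targets A `cap_calibration_targets`.
#' @param base_guess Starting rate set (default the shipped defaults).
#' @param sim A `cap_sim_config`.
#' @param init Initial-state configuration.
#' @param n_draws Search budget (candidate rate sets after the base guess).
#' @param spread Log10 half-width of the search box around the base guess.
#' @param master_seed Integer master seed.
#' @return A list of class `cap_calibration`: the certified `rates` and the
#'   evaluation `report`. Errors when the budget is exhausted, carrying the
#'   best-found diagnostics in the message.
#' @export
calibrate_defaults <- function(targets = calibration_targets(),
                               base_guess = default_rates(),
                               sim = sim_config(),
                               init = default_init_config(),
                               n_draws = 25, spread = 0.5,
                               master_seed = 1L) {
  base_guess <- .validate_rates(base_guess)
  ev <- evaluate_calibration(base_guess, targets, sim, init, master_seed)
  if (ev$pass)
    return(structure(list(rates = base_guess, report = ev, draws_used = 0L),
                     class = "cap_calibration"))
  best <- ev
  set.seed(.derive_seed(master_seed, 424243L))
  for (d in seq_len(n_draws)) {
    cand <- base_guess * 10^runif(length(base_guess), -spread, spread)
    names(cand) <- names(base_guess)
    ev <- evaluate_calibration(cand, targets, sim, init,
                               .derive_seed(master_seed, 5000L + d))
    if (ev$pass)
      return(structure(list(rates = cand, report = ev, draws_used = d),
                       class = "cap_calibration"))
    if (sum(ev$pass_low, ev$pass_high) > sum(best$pass_low, best$pass_high))
      best <- ev
  }
  stop("calibration search budget exhausted after ", n_draws,
       " draws; best found: low regime pass = ", best$pass_low,
       ", high regime pass = ", best$pass_high,
       " (median switches low = ", best$low["switches"],
       ", high = ", best$high["switches"], ")")
}

#' Write a sweep table as TSV
#'
#' @param sweep A `cap_sweep_table` or `cap_sensitivity_sweep`.
#' @param path Output TSV path (per-run rows); for sensitivity sweeps a
#'   `<path>.summary.tsv` companion receives the per-condition means.
#' @export
write_sweep <- function(sweep, path) {
  if (inherits(sweep, "cap_sensitivity_sweep")) {
    write.table(sweep$rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sweep$summary, paste0(path, ".summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
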