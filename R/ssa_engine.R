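#' Simulation configuration
#'
#' Horizon and burn-in mirror the published runs: 200,000 simulated seconds
#' with the first 10,000 s discarded, which removes dependence on the
#' randomized initial conditions. Records can be event-resolved or sampled on
#' a fixed grid (sample-and-hold); the state prevailing at the end of burn-in
#' is always the first record.
#'
#' @param t_end Simulated seconds (default 200000).
#' @param burn_in Seconds discarded from the start (default 10000); must
#'   satisfy `0 <= burn_in < t_end`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param record_mode `"grid"` (default) or `"event"`.
#' @param grid_step Grid spacing in seconds for grid mode.
#' @param max_events Safety cap on the number of reaction events.
#' @return A list of class `cap_sim_config`.
#' @export
sim_config <- function(t_end = 200000, burn_in = 10000, seed = NULL,
                       record_mode = c("grid", "event"), grid_step = 20,
                       max_events = 5e7) {
  record_mode <- match.arg(record_mode)
  t_end <- as.numeric(t_end); burn_in <- as.numeric(burn_in)
  grid_step <- as.numeric(grid_step); max_events <- as.numeric(max_events)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (burn_in < 0 || burn_in >= t_end)
    stop("burn_in must satisfy 0 <= burn_in < t_end")
  if (record_mode == "grid" && (!is.finite(grid_step) || grid_step <= 0))
    stop("grid_step must be positive")
  structure(list(t_end = t_end, burn_in = burn_in, seed = seed,
                 record_mode = record_mode, grid_step = grid_step,
                 max_events = max_events),
            class = "cap_sim_config")
}

#' Draw the next reaction event (Gillespie direct method)
#'
#' One step of the direct method: the waiting time is exponential with rate
#' equal to the total propensity, and the channel is chosen with probability
#' proportional to its propensity. Uses the current R RNG stream.
#'
#' @param state Named integer vector of species counts.
#' @param network A `cap_network`.
#' @return A list with `wait` (seconds; `Inf` when all propensities are zero),
#'   `reaction` (channel index, `NA` when absorbed) and `absorbed`.
#' @export
draw_next_event <- function(state, network) {
  a <- propensities(network, state)
  if (any(!is.finite(a)) || any(a < 0))
    stop("internal consistency error: invalid propensity")
  a0 <- sum(a)
  if (a0 <= 0)
    return(list(wait = Inf, reaction = NA_integer_, absorbed = TRUE))
  wait <- stats::rexp(1L, rate = a0)
  j <- findInterval(stats::runif(1L) * a0, cumsum(a)) + 1L
  if (j > length(a)) j <- length(a)
  list(wait = wait, reaction = j, absorbed = FALSE)
}

#' Simulate a reaction network with the Gillespie direct method
#'
#' Exact stochastic simulation of the continuous-time Markov jump process
#' defined by the network's mass-action propensities, from time 0 to
#' `config$t_end`, discarding records before `config$burn_in` (the state
#' prevailing at burn-in seeds the reported path). Identical inputs and seed
#' give identical output.
#'
#' @param network A `cap_network` (or any object with `reactants`/`products`
#'   stoichiometry matrices and a `rates` vector).
#' @param init Named integer vector of initial counts.
#' @param config A `cap_sim_config`.
#' @return An object of class `cap_trajectory`: `times` (seconds, strictly
#'   increasing, all within `[burn_in, t_end]`), `counts` (matrix, one row per
#'   record, one column per species; piecewise-constant between records),
#'   plus the config, rates, realized initial state and event diagnostics.
#' @export
#' @examples
#' net <- build_growth_capsulation_network(default_rates())
#' s0 <- initialize_state(seed = 1)
#' tr <- simulate_network(net, s0, sim_config(t_end = 2000, burn_in = 0, seed = 1))
simulate_network <- function(network, init, config = sim_config()) {
  init <- .validate_state(network, init)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .ssa_simulate(init, unname(network$rates[colnames(network$reactants)]),
                       network$reactants, network$products,
                       config$t_end, config$burn_in,
                       if (config$record_mode == "event") 0L else 1L,
                       config$grid_step, config$max_events)
  if (isTRUE(res$truncated))
    stop("max_events (", format(config$max_events),
         ") exceeded at simulated time ", format(res$final_time),
         " after ", format(res$n_events), " events")
  counts <- res$counts
  colnames(counts) <- network$species
  structure(list(times = res$times, counts = counts,
                 species = network$species,
                 config = config, rates = network$rates, init = init,
                 n_events = res$n_events, absorbed = res$absorbed,
                 id = paste0("traj-", format(config$seed %||% "stream"), "-",
                             format(res$n_events))),
            class = "cap_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cap_trajectory <- function(x, ...) {
  cat("cap_trajectory:", nrow(x$counts), "records over [",
      min(x$times), ",", max(x$times), "] s;",
      format(x$n_events), "events\n")
  invisible(x)
}

#' Resample a trajectory onto a fixed time grid
#'
#' Sample-and-hold: each grid point takes the last recorded state at or
#' before it. Time-weighted statistics computed on the grid converge to the
#' event-resolved values as the step shrinks.
#'
#' @param traj A `cap_trajectory`.
#' @param step Grid spacing in seconds; must not exceed the recorded window.
#' @return A gridded `cap_trajectory`.
#' @export
to_grid <- function(traj, step) {
  if (!is.finite(step) || step <= 0) stop("step must be positive")
  t0 <- traj$times[1L]
  t1 <- traj$config$t_end
  if (step > t1 - t0) stop("step exceeds the trajectory window")
  grid <- seq(t0, t1, by = step)
  idx <- findInterval(grid, traj$times)
  out <- traj
  out$times <- grid
  out$counts <- traj$counts[idx, , drop = FALSE]
  out$config$record_mode <- "grid"
  out$config$grid_step <- step
  out
}

#' Write / read a trajectory as TSV with a JSON sidecar
#'
#' The TSV has a `time_s` column followed by one column per species; seed,
#' rates and configuration go to `<path>.json`. Round-trips are lossless.
#'
#' @param traj A `cap_trajectory`.
#' @param path TSV file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = traj$times, traj$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(species = traj$species,
               config = unclass(traj$config),
               rates = as.list(traj$rates),
               init = as.list(traj$init),
               n_events = traj$n_events, absorbed = traj$absorbed, id = traj$id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- sim_config(t_end = meta$config$t_end, burn_in = meta$config$burn_in,
                    seed = meta$config$seed,
                    record_mode = meta$config$record_mode,
                    grid_step = meta$config$grid_step,
                    max_events = meta$config$max_events)
  counts <- as.matrix(df[, meta$species, drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(times = df$time_s, counts = counts, species = meta$species,
                 config = cfg, rates = unlist(meta$rates),
                 init = unlist(meta$init),
                 n_events = meta$n_events, absorbed = meta$absorbed,
                 id = meta$id),
            class = "cap_trajectory")
}

# Build a small ad-hoc mass-action network (used by tests and oracles).
# reactions: list of list(reac = c(X = 1), prod = c(), rate = <number>)
.make_network <- function(species, reactions, rate_names = NULL) {
  n <- length(reactions)
  if (is.null(rate_names)) rate_names <- paste0("k", seq_len(n))
  reac <- matrix(0L, length(species), n, dimnames = list(species, rate_names))
  prod <- matrix(0L, length(species), n, dimnames = list(species, rate_names))
  rates <- numeric(n)
  for (j in seq_len(n)) {
    rj <- reactions[[j]]$reac; pj <- reactions[[j]]$prod
    if (length(rj)) reac[names(rj), j] <- as.integer(rj)
    if (length(pj)) prod[names(pj), j] <- as.integer(pj)
    rates[j] <- reactions[[j]]$rate
  }
  names(rates) <- rate_names
  structure(list(species = species, reactions = reactions,
                 reactants = reac, products = prod, rates = rates),
            class = "cap_network")
}
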