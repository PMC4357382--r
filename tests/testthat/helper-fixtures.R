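# Small ad-hoc networks and hand-built trajectories used across tests.

birth_death_network <- function(a, b) {
  capswitch:::.make_network("X", list(
    list(reac = c(), prod = c(X = 1), rate = a),
    list(reac = c(X = 1), prod = c(), rate = b)))
}

decay_network <- function(c) {
  capswitch:::.make_network("X", list(
    list(reac = c(X = 1), prod = c(), rate = c)))
}

# A trajectory object built from explicit record times and CA values;
# the record at times[i] holds until times[i + 1] (the last until t_end).
make_ca_traj <- function(times, ca, t_end, burn_in = 0) {
  counts <- cbind(CA = as.integer(ca))
  structure(list(times = times, counts = counts, species = "CA",
                 config = sim_config(t_end = t_end, burn_in = burn_in,
                                     grid_step = 1),
                 rates = c(k = 1), init = c(CA = ca[1L]),
                 n_events = length(times), absorbed = FALSE,
                 id = "fixture"),
            class = "cap_trajectory")
}

# Square wave: alternating low/high values with given durations, repeated.
square_wave_traj <- function(low = 0, high = 200, d_low = 70, d_high = 30,
                             n_cycles = 10) {
  times <- c(0, cumsum(rep(c(d_low, d_high), n_cycles)))
  times <- times[-length(times)]
  ca <- rep(c(low, high), n_cycles)
  make_ca_traj(times, ca, t_end = n_cycles * (d_low + d_high))
}

# A lineage-tree stand-in with deterministic synchronous doubling every
# `interval` minutes (only the fields estimate_growth_rate consults).
synchronous_tree <- function(interval = 60, n_doublings = 10,
                             phenotype = "CAP_LOW") {
  times <- interval * (0:n_doublings)
  n <- 2^(0:n_doublings)
  census <- data.frame(time_min = times,
                       n_cap_low = if (phenotype == "CAP_LOW") n else 0L,
                       n_cap_high = if (phenotype == "CAP_HIGH") n else 0L)
  structure(list(cells = NULL, events = data.frame(), census = census,
                 threshold = Inf,
                 params = microcolony_params(founder_phenotype = phenotype),
                 final_time = max(times), first_switch_seen = FALSE),
            class = "cap_lineage")
}

# Memoryless first-switch sizes: constant per-division switch probability p
# gives P(N = n) = p (1 - p)^(n - 2) for n >= 2.
rmemoryless_sizes <- function(n, p) 2 + stats::rgeom(n, p)
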