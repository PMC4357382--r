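#' Parameters for the synthetic microcolony generator
#'
#' Defaults reproduce the measured single-cell conditions: Cap- cells divide
#' at 0.0116 min^-1 and Cap+ cells at 0.0113 min^-1 (capsulation costs ~3%
#' growth), and the first Cap- to Cap+ switch occurs once the colony exceeds
#' a per-colony Gaussian threshold of 1870 +/- 660 cells. Above the
#' threshold, Cap- cells switch stochastically at a per-cell rate; the
#' default rate is high so first-switch sizes converge to the drawn
#' threshold (the threshold-dominated regime). Cap+ founder cells revert to
#' Cap- on a fast exponential clock before any growth-phase switching.
#'
#' @param growth_rate_cap_low Cap- division rate, min^-1 (Malthusian; the
#'   implied division time is ln(2)/rate).
#' @param growth_rate_cap_high Cap+ division rate, min^-1; must not exceed
#'   the Cap- rate (capsulation is costly).
#' @param switch_threshold_mean,switch_threshold_sd Gaussian parameters of
#'   the per-colony switching threshold (cells).
#' @param per_cell_switch_rate Cap- to Cap+ switch rate per cell per minute,
#'   active only while the population is at or above the colony's threshold.
#' @param founder_phenotype `"CAP_LOW"` or `"CAP_HIGH"`.
#' @param founder_reversion_rate Reversion rate (min^-1) of founder-phase
#'   Cap+ cells (default mean reversion time 30 min).
#' @param total_time Simulated minutes. The default (1500) makes censoring
#'   negligible at the default threshold: colony size is `W exp(r t)` with a
#'   unit-exponential founder factor `W`, so a window of many doubling times
#'   is needed before slow-starting colonies have crossed the threshold.
#' @param max_cells Safety cap on colony size.
#' @param seed Optional integer seed.
#' @return A list of class `cap_microcolony_params`.
#' @export
microcolony_params <- function(growth_rate_cap_low = 0.0116,
                               growth_rate_cap_high = 0.0113,
                               switch_threshold_mean = 1870,
                               switch_threshold_sd = 660,
                               per_cell_switch_rate = 0.1,
                               founder_phenotype = c("CAP_LOW", "CAP_HIGH"),
                               founder_reversion_rate = 1 / 30,
                               total_time = 1500,
                               max_cells = 50000,
                               seed = NULL) {
  founder_phenotype <- match.arg(founder_phenotype)
  if (growth_rate_cap_low <= 0 || growth_rate_cap_high <= 0)
    stop("growth rates must be positive")
  if (growth_rate_cap_high > growth_rate_cap_low)
    stop("growth_rate_cap_high must not exceed growth_rate_cap_low (capsulation is costly)")
  if (total_time <= 0) stop("total_time must be positive")
  if (switch_threshold_sd < 0) stop("switch_threshold_sd must be >= 0")
  structure(list(growth_rate_cap_low = growth_rate_cap_low,
                 growth_rate_cap_high = growth_rate_cap_high,
                 switch_threshold_mean = switch_threshold_mean,
                 switch_threshold_sd = switch_threshold_sd,
                 per_cell_switch_rate = per_cell_switch_rate,
                 founder_phenotype = founder_phenotype,
                 founder_reversion_rate = founder_reversion_rate,
                 total_time = total_time, max_cells = max_cells, seed = seed),
            class = "cap_microcolony_params")
}

#' Generate a synthetic microcolony lineage tree
#'
#' Markov branching process from a single founder: every cell divides after
#' an exponential waiting time with its phenotype's rate (binary divisions;
#' phenotype is inherited, i.e. heritable along lineages between switch
#' events). Each colony draws a switching threshold from the configured
#' Gaussian; Cap- cells switch to Cap+ stochastically only while the
#' population is at or above that threshold. Founder-phase Cap+ cells revert
#' to Cap- on an exponential clock.
#'
#' @param params A `cap_microcolony_params`.
#' @param stop_at_first_switch If `TRUE`, stop simulating just after the
#'   first Cap- to Cap+ switch (the statistic of interest for threshold
#'   analyses); the tree is then censored in time but not in that event.
#' @return An object of class `cap_lineage`: `cells` (id, parent, birth and
#'   division times in minutes, phenotype at birth), `events` (phenotype
#'   changes with population size at the event), `census` (population
#'   composition after every event), the drawn `threshold`, and the params.
#' @export
generate_microcolony <- function(params = microcolony_params(),
                                 stop_at_first_switch = FALSE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  thr <- if (params$switch_threshold_sd == 0) params$switch_threshold_mean
         else max(2, rnorm(1, params$switch_threshold_mean, params$switch_threshold_sd))

  cap <- 1024L
  parent <- integer(cap); birth <- numeric(cap)
  division <- rep(NA_real_, cap); pheno <- character(cap)
  grow <- function(n_needed) {
    while (n_needed > cap) {
      cap <<- cap * 2L
      length(parent) <<- cap; length(birth) <<- cap
      division2 <- rep(NA_real_, cap); division2[seq_along(division)] <- division
      division <<- division2
      length(pheno) <<- cap
    }
  }

  founder_high <- params$founder_phenotype == "CAP_HIGH"
  parent[1L] <- 0L; birth[1L] <- 0
  pheno[1L] <- params$founder_phenotype
  n_cells <- 1L

  # alive-cell pools: Cap- cells, founder-phase Cap+ (revertible), committed Cap+
  low <- if (founder_high) integer() else 1L
  hiF <- if (founder_high) 1L else integer()
  hiC <- integer()

  r_lo <- params$growth_rate_cap_low
  r_hi <- params$growth_rate_cap_high
  s <- params$per_cell_switch_rate
  rev_rate <- params$founder_reversion_rate

  ev_t <- numeric(); ev_id <- integer(); ev_from <- character()
  ev_to <- character(); ev_pop <- integer()
  cz_t <- numeric(256L); cz_lo <- integer(256L); cz_hi <- integer(256L)
  n_cz <- 0L
  push_census <- function(t) {
    n_cz <<- n_cz + 1L
    if (n_cz > length(cz_t)) {
      length(cz_t) <<- 2L * length(cz_t)
      length(cz_lo) <<- length(cz_t); length(cz_hi) <<- length(cz_t)
    }
    cz_t[n_cz] <<- t
    cz_lo[n_cz] <<- length(low)
    cz_hi[n_cz] <<- length(hiF) + length(hiC)
  }
  push_census(0)

  t <- 0
  first_switch_seen <- FALSE
  repeat {
    n_lo <- length(low); n_hiF <- length(hiF); n_hiC <- length(hiC)
    pop <- n_lo + n_hiF + n_hiC
    rate_div_lo <- r_lo * n_lo
    rate_div_hi <- r_hi * (n_hiF + n_hiC)
    rate_switch <- if (pop >= thr) s * n_lo else 0
    rate_rev <- rev_rate * n_hiF
    total <- rate_div_lo + rate_div_hi + rate_switch + rate_rev
    if (total <= 0) break
    t <- t + rexp(1L, total)
    if (t > params$total_time) { t <- params$total_time; break }
    u <- runif(1L) * total
    if (u < rate_div_lo + rate_div_hi) {
      # division: pick phenotype pool, then a uniform cell within it
      if (u < rate_div_lo) {
        i <- sample.int(n_lo, 1L); id <- low[i]
        low[i] <- low[n_lo]; low <- low[-n_lo]
        kids_pool <- "low"
      } else {
        j <- sample.int(n_hiF + n_hiC, 1L)
        if (j <= n_hiF) {
          id <- hiF[j]; hiF[j] <- hiF[n_hiF]; hiF <- hiF[-n_hiF]
          kids_pool <- "hiF"
        } else {
          j <- j - n_hiF
          id <- hiC[j]; hiC[j] <- hiC[n_hiC]; hiC <- hiC[-n_hiC]
          kids_pool <- "hiC"
        }
      }
      grow(n_cells + 2L)
      k1 <- n_cells + 1L; k2 <- n_cells + 2L
      parent[k1] <- id; parent[k2] <- id
      birth[k1] <- t; birth[k2] <- t
      ph <- if (kids_pool == "low") "CAP_LOW" else "CAP_HIGH"
      pheno[k1] <- ph; pheno[k2] <- ph
      division[id] <- t
      n_cells <- k2
      if (kids_pool == "low") low <- c(low, k1, k2)
      else if (kids_pool == "hiF") hiF <- c(hiF, k1, k2)
      else hiC <- c(hiC, k1, k2)
      if (n_cells >= params$max_cells) break
    } else if (u < rate_div_lo + rate_div_hi + rate_switch) {
      # Cap- -> Cap+ switch (population at or above the colony threshold)
      i <- sample.int(n_lo, 1L); id <- low[i]
      low[i] <- low[n_lo]; low <- low[-n_lo]
      hiC <- c(hiC, id)
      ev_t <- c(ev_t, t); ev_id <- c(ev_id, id)
      ev_from <- c(ev_from, "CAP_LOW"); ev_to <- c(ev_to, "CAP_HIGH")
      ev_pop <- c(ev_pop, pop)
      first_switch_seen <- TRUE
      if (stop_at_first_switch) { push_census(t); break }
    } else {
      # founder-phase Cap+ reversion
      i <- sample.int(n_hiF, 1L); id <- hiF[i]
      hiF[i] <- hiF[n_hiF]; hiF <- hiF[-n_hiF]
      low <- c(low, id)
      ev_t <- c(ev_t, t); ev_id <- c(ev_id, id)
      ev_from <- c(ev_from, "CAP_HIGH"); ev_to <- c(ev_to, "CAP_LOW")
      ev_pop <- c(ev_pop, pop)
    }
    push_census(t)
  }

  cells <- data.frame(id = seq_len(n_cells), parent = parent[seq_len(n_cells)],
                      birth_min = birth[seq_len(n_cells)],
                      division_min = division[seq_len(n_cells)],
                      phenotype_birth = pheno[seq_len(n_cells)],
                      stringsAsFactors = FALSE)
  events <- data.frame(time_min = ev_t, cell_id = ev_id, from = ev_from,
                       to = ev_to, population = ev_pop, stringsAsFactors = FALSE)
  census <- data.frame(time_min = cz_t[seq_len(n_cz)],
                       n_cap_low = cz_lo[seq_len(n_cz)],
                       n_cap_high = cz_hi[seq_len(n_cz)])
  structure(list(cells = cells, events = events, census = census,
                 threshold = thr, params = params, final_time = t,
                 first_switch_seen = first_switch_seen),
            class = "cap_lineage")
}

#' @export
print.cap_lineage <- function(x, ...) {
  n_alive <- sum(is.na(x$cells$division_min))
  cat("cap_lineage:", nrow(x$cells), "cells (", n_alive, "alive ),",
      nrow(x$events), "phenotype events; threshold", round(x$threshold, 1),
      "cells\n")
  invisible(x)
}

#' Colony population size over time
#'
#' Binary divisions without death: the population at time `t` is one plus the
#' number of divisions up to `t`. Cross-checked against the per-event census
#' kept by the generator.
#'
#' @param tree A `cap_lineage`.
#' @param times Times (minutes) at which to evaluate.
#' @return Integer vector of population sizes.
#' @export
population_size <- function(tree, times) {
  div <- sort(tree$cells$division_min[!is.na(tree$cells$division_min)])
  1L + findInterval(times, div)
}

#' Population size at the first Cap- to Cap+ switch
#'
#' @param tree A `cap_lineage` grown from a Cap- founder.
#' @return The population size (cells) at the first switch, or `NA` with
#'   attribute `censored = TRUE` (and `final_size`, the size at the end of
#'   observation) if no switch occurred.
#' @export
first_switch_size <- function(tree) {
  if (tree$params$founder_phenotype == "CAP_HIGH")
    stop("first-switch size is undefined for a Cap+ founder tree")
  sw <- tree$events[tree$events$from == "CAP_LOW" & tree$events$to == "CAP_HIGH", ]
  if (!nrow(sw)) {
    n_final <- with(tree$census, n_cap_low[nrow(tree$census)] +
                      n_cap_high[nrow(tree$census)])
    return(structure(NA_real_, censored = TRUE, final_size = n_final))
  }
  sw$population[which.min(sw$time_min)]
}

#' First-switch sizes for a batch of colonies
#'
#' @param trees List of `cap_lineage` objects.
#' @return Data frame with `size`, `censored`, and `censor_size` (the size at
#'   end of observation for censored colonies, `NA` otherwise).
#' @export
first_switch_sizes <- function(trees) {
  rows <- lapply(trees, function(tr) {
    s <- first_switch_size(tr)
    if (isTRUE(attr(s, "censored")))
      data.frame(size = NA_real_, censored = TRUE,
                 censor_size = attr(s, "final_size"))
    else data.frame(size = as.numeric(s), censored = FALSE,
                    censor_size = NA_real_)
  })
  do.call(rbind, rows)
}

#' Simulate a capsule counting assay
#'
#' Emulates the scoring of capsulation state for a fixed number of cells per
#' replicate preparation: independent binomial draws at the generating
#' proportion.
#'
#' @param p Generating proportion of Cap+ cells, in `[0, 1]`.
#' @param cells_per_rep Cells scored per replicate (default 500).
#' @param replicates Number of replicates (default 5; at least 3 in the
#'   assay protocol).
#' @param seed Optional integer seed.
#' @return An object of class `cap_assay`: data frame with `replicate`,
#'   `cells`, `capsulated`; the generating `p` is an attribute.
#' @export
generate_assay <- function(p, cells_per_rep = 500L, replicates = 5L,
                           seed = NULL) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- rbinom(replicates, cells_per_rep, p)
  structure(data.frame(replicate = seq_len(replicates),
                       cells = cells_per_rep, capsulated = counts),
            p = p, class = c("cap_assay", "data.frame"))
}

#' Write a lineage tree as TSV plus a JSON manifest
#'
#' One row per cell; per-cell phenotype history is encoded as
#' `"state@start;state@time;..."` from the birth phenotype and the recorded
#' switch events.
#'
#' @param tree A `cap_lineage`.
#' @param path TSV path; the manifest goes to `<path>.json`.
#' @export
write_lineage <- function(tree, path) {
  hist <- sprintf("%s@%.6g", tree$cells$phenotype_birth, tree$cells$birth_min)
  if (nrow(tree$events)) {
    for (k in seq_len(nrow(tree$events))) {
      id <- tree$events$cell_id[k]
      hist[id] <- paste0(hist[id], ";", sprintf("%s@%.6g", tree$events$to[k],
                                                tree$events$time_min[k]))
    }
  }
  df <- data.frame(tree$cells[, c("id", "parent", "birth_min", "division_min")],
                   phenotype = hist)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(params = unclass(tree$params),
                            threshold = tree$threshold,
                            final_time = tree$final_time,
                            n_cells = nrow(tree$cells)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
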