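#' @useDynLib capswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif sd median quantile optim optimize lm coef vcov
#'   shapiro.test t.test wilcox.test var.test rbinom rnorm pnorm dnorm
#' @importFrom utils write.table read.table head tail
NULL

#' Species of the growth-capsulation network
#'
#' The 14 molecular species tracked by the model: the UTP-proportional signal
#' molecule (UXP), CAP polymer units (CA), the transcriptional activator free
#' (A) and sequestered by UXP (A_UXP), the CAP biosynthetic gene promoter in
#' its free, activator-bound and repressor-dimer-bound configurations, the CAP
#' transcript, the repressor-gene promoter free and CAP-bound, the repressor
#' transcript, and repressor monomer and dimer. Degradation products are a
#' conceptual sink and are not tracked.
#'
#' @return Character vector of species names.
#' @export
cap_species <- function() {
  c("UXP", "CA", "A", "A_UXP",
    "DNAca_free", "DNAca_act", "DNAca_rep", "mRNAca",
    "DNAr_free", "DNAr_act", "mRNAr", "R", "R2")
}

#' Names of the 23 reaction rate constants
#'
#' One rate constant per reaction channel, addressable by name and by stable
#' index (the index order is used by the one-at-a-time sensitivity sweep).
#'
#' @return Character vector of length 23.
#' @export
cap_rate_names <- function() {
  c("k_uxp_prod", "k_cap_feedback", "k_pyrg_drain", "k_seq_on", "k_seq_off",
    "k_act_bind", "k_act_unbind", "k_tx_active", "k_tx_basal", "k_tl_ca",
    "k_capDNAr_bind", "k_capDNAr_unbind", "k_tx_rep", "k_tl_rep",
    "k_dim_on", "k_dim_off", "k_rep_bind", "k_rep_unbind",
    "k_deg_mRNAca", "k_deg_mRNAr", "k_deg_CA", "k_deg_R", "k_deg_R2")
}

# Reaction table: one channel per rate constant. Stoichiometries realize the
# verbal model: constant UXP supply, a CAP-driven positive-feedback drain on
# UXP, a PyrG drain (PyrG folded into the constant), activator sequestration
# by UXP, activator-driven plus basal transcription of the CAP genes
# (polymerase folded into the constants), a CAP-triggered repressor gene,
# repressor dimerization and cooperative promoter repression, and first-order
# turnover of mRNA and protein.
.cap_reaction_table <- function() {
  list(
    list(rate = "k_uxp_prod",       block = "A", reac = c(),                        prod = c(UXP = 1),
         label = "0 -> UXP (constant UXP supply)"),
    list(rate = "k_cap_feedback",   block = "A", reac = c(UXP = 1, CA = 1),         prod = c(CA = 2),
         label = "UXP + CA -> 2 CA (CAP synthesis draws UXP into capsule production)"),
    list(rate = "k_pyrg_drain",     block = "A", reac = c(UXP = 1),                 prod = c(),
         label = "UXP -> 0 (PyrG branch: nucleotide metabolism)"),
    list(rate = "k_seq_on",         block = "A", reac = c(A = 1, UXP = 1),          prod = c(A_UXP = 1),
         label = "A + UXP -> A_UXP (UXP sequesters the activator)"),
    list(rate = "k_seq_off",        block = "A", reac = c(A_UXP = 1),               prod = c(A = 1, UXP = 1),
         label = "A_UXP -> A + UXP"),
    list(rate = "k_act_bind",       block = "B", reac = c(A = 1, DNAca_free = 1),   prod = c(DNAca_act = 1),
         label = "A + DNAca_free -> DNAca_act"),
    list(rate = "k_act_unbind",     block = "B", reac = c(DNAca_act = 1),           prod = c(A = 1, DNAca_free = 1),
         label = "DNAca_act -> A + DNAca_free"),
    list(rate = "k_tx_active",      block = "B", reac = c(DNAca_act = 1),           prod = c(DNAca_act = 1, mRNAca = 1),
         label = "DNAca_act -> DNAca_act + mRNAca (activated transcription)"),
    list(rate = "k_tx_basal",       block = "B", reac = c(DNAca_free = 1),          prod = c(DNAca_free = 1, mRNAca = 1),
         label = "DNAca_free -> DNAca_free + mRNAca (basal transcription)"),
    list(rate = "k_tl_ca",          block = "B", reac = c(mRNAca = 1),              prod = c(mRNAca = 1, CA = 1),
         label = "mRNAca -> mRNAca + CA (translation / CAP synthesis)"),
    list(rate = "k_capDNAr_bind",   block = "C", reac = c(CA = 1, DNAr_free = 1),   prod = c(DNAr_act = 1),
         label = "CA + DNAr_free -> DNAr_act (CAP triggers the repressor gene)"),
    list(rate = "k_capDNAr_unbind", block = "C", reac = c(DNAr_act = 1),            prod = c(CA = 1, DNAr_free = 1),
         label = "DNAr_act -> CA + DNAr_free"),
    list(rate = "k_tx_rep",         block = "C", reac = c(DNAr_act = 1),            prod = c(DNAr_act = 1, mRNAr = 1),
         label = "DNAr_act -> DNAr_act + mRNAr"),
    list(rate = "k_tl_rep",         block = "C", reac = c(mRNAr = 1),               prod = c(mRNAr = 1, R = 1),
         label = "mRNAr -> mRNAr + R"),
    list(rate = "k_dim_on",         block = "C", reac = c(R = 2),                   prod = c(R2 = 1),
         label = "R + R -> R2 (repressor dimerization, cooperativity)"),
    list(rate = "k_dim_off",        block = "C", reac = c(R2 = 1),                  prod = c(R = 2),
         label = "R2 -> R + R"),
    list(rate = "k_rep_bind",       block = "C", reac = c(R2 = 1, DNAca_free = 1),  prod = c(DNAca_rep = 1),
         label = "R2 + DNAca_free -> DNAca_rep (repressed promoter: halted synthesis)"),
    list(rate = "k_rep_unbind",     block = "C", reac = c(DNAca_rep = 1),           prod = c(R2 = 1, DNAca_free = 1),
         label = "DNAca_rep -> R2 + DNAca_free"),
    list(rate = "k_deg_mRNAca",     block = "D", reac = c(mRNAca = 1),              prod = c(),
         label = "mRNAca -> 0"),
    list(rate = "k_deg_mRNAr",      block = "D", reac = c(mRNAr = 1),               prod = c(),
         label = "mRNAr -> 0"),
    list(rate = "k_deg_CA",         block = "D", reac = c(CA = 1),                  prod = c(),
         label = "CA -> 0"),
    list(rate = "k_deg_R",          block = "D", reac = c(R = 1),                   prod = c(),
         label = "R -> 0"),
    list(rate = "k_deg_R2",         block = "D", reac = c(R2 = 1),                  prod = c(),
         label = "R2 -> 0")
  )
}

#' Default rate constants for the growth-capsulation network
#'
#' The shipped defaults (units: s^-1 for first-order, molecule^-1 s^-1 for
#' bimolecular channels, molecules s^-1 for the zero-order UXP supply) were
#' chosen by timescale analysis and certified by [calibrate_defaults()]
#' against the calibration targets: at low UXP supply (`k_uxp_prod = 0.003`)
#' both phenotype states are occupied with dwell times spanning several cell
#' divisions, while at high supply (`k_uxp_prod = 3`) CAP expression stays
#' basal. The same values live in
#' `system.file("extdata", "growth_capsulation_default.json", package = "capswitch")`.
#'
#' @return Named numeric vector of the 23 rate constants.
#' @export
#' @examples
#' r <- default_rates()
#' r["k_uxp_prod"]
default_rates <- function() {
  c(k_uxp_prod       = 0.003,
    k_cap_feedback   = 1e-6,
    k_pyrg_drain     = 0.01,
    k_seq_on         = 0.02,
    k_seq_off        = 0.01,
    k_act_bind       = 1e-4,
    k_act_unbind     = 1.2e-4,
    k_tx_active      = 0.04,
    k_tx_basal       = 1e-4,
    k_tl_ca          = 0.015,
    k_capDNAr_bind   = 5e-6,
    k_capDNAr_unbind = 5e-4,
    k_tx_rep         = 0.01,
    k_tl_rep         = 0.01,
    k_dim_on         = 1e-3,
    k_dim_off        = 1e-3,
    k_rep_bind       = 5e-3,
    k_rep_unbind     = 2e-4,
    k_deg_mRNAca     = 2e-3,
    k_deg_mRNAr      = 2e-3,
    k_deg_CA         = 1e-3,
    k_deg_R          = 5e-4,
    k_deg_R2         = 2e-4)
}

.validate_rates <- function(rates) {
  nm <- cap_rate_names()
  if (is.null(names(rates))) stop("rates must be a named numeric vector")
  missing <- setdiff(nm, names(rates))
  if (length(missing))
    stop("missing rate constant(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(rates), nm)
  if (length(extra))
    stop("unknown rate constant(s): ", paste(extra, collapse = ", "))
  rates <- rates[nm]
  bad <- nm[!is.finite(rates) | rates < 0]
  if (length(bad))
    stop("negative or non-finite rate constant(s): ", paste(bad, collapse = ", "))
  rates
}

#' Build the 23-reaction growth-capsulation network
#'
#' Assembles the mass-action reaction system around the UTP bifurcation point:
#' constant UXP supply, the PyrG drain, CAP positive feedback on the UXP pool,
#' sequestration of the CAP-gene activator by UXP, activated and basal
#' transcription, a CAP-triggered repressor with dimerization and cooperative
#' promoter repression, and first-order turnover. One reaction channel per
#' rate constant.
#'
#' @param rates Named numeric vector with exactly the 23 constants of
#'   [cap_rate_names()]; see [default_rates()].
#' @return An object of class `cap_network`: reaction list plus reactant and
#'   product stoichiometry matrices (species x reactions).
#' @export
#' @examples
#' net <- build_growth_capsulation_network(default_rates())
#' length(net$reactions)
build_growth_capsulation_network <- function(rates = default_rates()) {
  rates <- .validate_rates(rates)
  sp <- cap_species()
  tab <- .cap_reaction_table()
  n <- length(tab)
  reac <- matrix(0L, nrow = length(sp), ncol = n, dimnames = list(sp, NULL))
  prod <- matrix(0L, nrow = length(sp), ncol = n, dimnames = list(sp, NULL))
  for (j in seq_len(n)) {
    rj <- tab[[j]]$reac
    pj <- tab[[j]]$prod
    if (length(rj)) reac[names(rj), j] <- as.integer(rj)
    if (length(pj)) prod[names(pj), j] <- as.integer(pj)
  }
  colnames(reac) <- colnames(prod) <- vapply(tab, `[[`, "", "rate")
  structure(list(species = sp, reactions = tab, reactants = reac,
                 products = prod, rates = rates),
            class = "cap_network")
}

#' @export
print.cap_network <- function(x, ...) {
  cat("growth-capsulation network:", length(x$reactions), "reactions,",
      length(x$species), "species\n")
  cat(format_reactions(x), sep = "\n")
  invisible(x)
}

#' Human-readable reaction list
#'
#' One line per reaction, `reactants -> products @ rate_name`, for
#' documentation and diffing.
#'
#' @param network A `cap_network`.
#' @return Character vector, one element per reaction.
#' @export
format_reactions <- function(network) {
  side <- function(v) {
    nz <- v[v > 0L]
    if (!length(nz)) return("0")
    paste(ifelse(nz > 1L, paste0(nz, " ", names(nz)), names(nz)), collapse = " + ")
  }
  vapply(seq_along(network$reactions), function(j) {
    sprintf("%s -> %s @ %s",
            side(network$reactants[, j]), side(network$products[, j]),
            colnames(network$reactants)[j])
  }, "")
}

#' Mass-action propensities of every channel in a state
#'
#' Combinatorial mass action: for a channel consuming `s` copies of a species
#' present at `x` copies the contribution is `choose(x, s)`, so dimerization
#' R + R has propensity `k * R * (R - 1) / 2`.
#'
#' @param network A `cap_network`.
#' @param state Named integer vector of species counts (see [cap_species()]).
#' @return Numeric vector of per-channel propensities named by rate constant.
#' @export
propensities <- function(network, state) {
  state <- .validate_state(network, state)
  a <- .ssa_propensities(state, unname(network$rates[colnames(network$reactants)]),
                         network$reactants)
  names(a) <- colnames(network$reactants)
  a
}

.validate_state <- function(network, state) {
  sp <- network$species
  if (is.null(names(state))) {
    if (length(state) != length(sp)) stop("state must have ", length(sp), " species")
    names(state) <- sp
  }
  missing <- setdiff(sp, names(state))
  if (length(missing)) stop("state is missing species: ", paste(missing, collapse = ", "))
  state <- state[sp]
  if (any(state < 0) || any(state != round(state)))
    stop("species counts must be non-negative integers")
  storage.mode(state) <- "integer"
  state
}

#' Default initial-state configuration
#'
#' Sampling ranges for randomized initial counts, with fixed promoter copy
#' numbers. Initial UXP is drawn so that it strictly outnumbers the total
#' activator pool, mirroring the randomized initialization used for the
#' published simulations.
#'
#' @param uxp_range Integer range for the initial UXP count.
#' @param activator_range Integer range for the total activator count.
#' @param dna_ca_copies,dna_r_copies Promoter copy numbers (single locus by
#'   default).
#' @return A list of class `cap_init_config`.
#' @export
default_init_config <- function(uxp_range = c(50L, 200L),
                                activator_range = c(5L, 20L),
                                dna_ca_copies = 1L, dna_r_copies = 1L) {
  structure(list(uxp_range = as.integer(uxp_range),
                 activator_range = as.integer(activator_range),
                 dna_ca_copies = as.integer(dna_ca_copies),
                 dna_r_copies = as.integer(dna_r_copies)),
            class = "cap_init_config")
}

#' Draw a randomized initial state
#'
#' Samples initial UXP and activator counts from the configured ranges under
#' the constraint that UXP strictly outnumbers activator molecules; all other
#' species start at zero except the promoters, which start free at their
#' configured copy numbers.
#'
#' @param config A `cap_init_config` (see [default_init_config()]). Degenerate
#'   ranges (`c(n, n)`) give a deterministic state.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Named integer vector over [cap_species()].
#' @export
initialize_state <- function(config = default_init_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$uxp_range[2] <= config$activator_range[1])
    stop("configured ranges cannot satisfy UXP > activator")
  a_tot <- if (config$activator_range[1] == config$activator_range[2])
    config$activator_range[1]
  else sample(config$activator_range[1]:config$activator_range[2], 1L)
  lo <- max(config$uxp_range[1], a_tot + 1L)
  if (lo > config$uxp_range[2])
    stop("configured ranges cannot satisfy UXP > activator")
  uxp <- if (lo == config$uxp_range[2]) lo else sample(lo:config$uxp_range[2], 1L)
  state <- stats::setNames(integer(length(cap_species())), cap_species())
  state["UXP"] <- uxp
  state["A"] <- a_tot
  state["DNAca_free"] <- config$dna_ca_copies
  state["DNAr_free"] <- config$dna_r_copies
  state
}

#' Multiply one rate constant by a factor
#'
#' Returns a copy of `rates` with only the named constant scaled; the input
#' is unchanged. This is the primitive behind the one-at-a-time ten-fold
#' sensitivity sweep.
#'
#' @param rates Named numeric vector of the 23 rate constants.
#' @param name One of [cap_rate_names()].
#' @param factor Positive scalar.
#' @return The perturbed rate vector.
#' @export
#' @examples
#' r <- perturb_rate(default_rates(), "k_deg_CA", 10)
perturb_rate <- function(rates, name, factor) {
  rates <- .validate_rates(rates)
  if (length(name) != 1L || !name %in% cap_rate_names())
    stop("unknown rate name '", name, "'; valid names: ",
         paste(cap_rate_names(), collapse = ", "))
  if (!is.finite(factor) || factor <= 0) stop("factor must be a positive scalar")
  rates[name] <- rates[name] * factor
  rates
}

#' Read or write a network configuration file
#'
#' The configuration holds the 23 rate constants plus the initial-state block;
#' JSON is canonical and YAML is accepted. Round-trips are lossless.
#'
#' @param path File path; dialect chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_network_config()` returns `list(rates, init)`.
#' @export
read_network_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- .validate_rates(unlist(raw$rates))
  init <- default_init_config(
    uxp_range = as.integer(raw$init$uxp_range),
    activator_range = as.integer(raw$init$activator_range),
    dna_ca_copies = as.integer(raw$init$dna_ca_copies),
    dna_r_copies = as.integer(raw$init$dna_r_copies))
  list(rates = rates, init = init)
}

#' @rdname read_network_config
#' @param rates Named numeric vector of the 23 rate constants.
#' @param init A `cap_init_config`.
#' @export
write_network_config <- function(path, rates, init = default_init_config()) {
  rates <- .validate_rates(rates)
  obj <- list(rates = as.list(rates),
              init = list(uxp_range = init$uxp_range,
                          activator_range = init$activator_range,
                          dna_ca_copies = init$dna_ca_copies,
                          dna_r_copies = init$dna_r_copies))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
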