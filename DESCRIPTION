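Package: capswitch
Title: Stochastic Simulation of Bistable Capsule Switching in Pseudomonas fluorescens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the growth-capsulation model of stochastic capsule
    (CAP) switching in Pseudomonas fluorescens SBW25/1B4: a 23-reaction
    mass-action network around the UTP bifurcation point simulated with the
    Gillespie direct method, trajectory phenotype analyses (Cap-/Cap+ state
    calls, dwell times, occupancy fractions, cumulative occupancy curves),
    UXP dose and one-at-a-time reaction-rate sensitivity sweeps, a synthetic
    microcolony generator (phenotype-dependent branching growth, Gaussian
    population-size switching threshold, binomial capsule-counting assay),
    and the matching inference stage (growth-rate and capsulation-cost
    estimation, Gaussian-versus-memoryless threshold model comparison,
    proportion estimates, and a two-sample test policy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
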