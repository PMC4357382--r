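---
title: "The growth-capsulation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The growth-capsulation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological problem

*Pseudomonas fluorescens* SBW25 derivatives carrying a single mutation in
`carB` (genotype 1B⁴) switch stochastically between noncapsulated (Cap⁻) and
capsulated (Cap⁺) cell states, visible as translucent/opaque colony
dimorphism. The mechanistic proposal is metabolic: the mutation lowers the
supply of pyrimidine intermediates, exposing a decision point at which UTP is
partitioned either towards nucleotide metabolism (via PyrG, leading to
division and Cap⁻) or towards polymer precursor synthesis (via GalU, leading
to capsule production and Cap⁺). `capswitch` implements a stochastic
reaction-network realization of that proposal — the growth-capsulation
model — together with the in-silico experiments built on it and a synthetic
single-cell (microcolony) data generator with its matching inference stage.

# The reaction network

The model tracks an abstract signal molecule, UXP, whose level is
proportional to UTP, plus the CAP polymer (`CA`), a transcriptional
activator that UXP sequesters, the CAP-gene promoter and transcript, and a
CAP-triggered repressor with its own promoter, transcript, monomer and
dimer. There are 23 mass-action reaction channels, one per rate constant
(`format_reactions(build_growth_capsulation_network())` prints them all):

* **UXP economy** — constant supply (`k_uxp_prod`, the dose knob), a
  first-order PyrG drain (`k_pyrg_drain`, with PyrG folded into the
  constant), and a CAP-catalysed consumption channel `UXP + CA -> 2 CA`
  (`k_cap_feedback`): once a cell commits to capsule synthesis, CAP
  production itself keeps the UXP pool low, which is the phenotypic-memory
  feedback.
* **Activator sequestration** — `A + UXP <-> A_UXP`. At high UXP almost all
  activator is sequestered and CAP transcription is basal; when UXP falls
  the free activator binds the CAP promoter.
* **Transcription and translation** — activator-bound transcription
  (`k_tx_active`), weak basal transcription from the free promoter
  (`k_tx_basal`), and translation (`k_tl_ca`). DNA polymerase is folded
  into the transcription constants.
* **The return switch** — CAP binds a repressor-gene promoter
  (`k_capDNAr_bind`), driving expression of a repressor that dimerizes
  (`k_dim_on`/`k_dim_off`, giving cooperativity) and occupies the CAP
  promoter (`k_rep_bind`); a repressed promoter transcribes nothing. The
  decay of repressor (`k_deg_R`, `k_deg_R2`) sets how long the Cap⁻ state
  lasts before the system can respond to the low-UXP signal again.
* **Turnover** — first-order degradation of both mRNAs, CAP, and the
  repressor species.

Promoter species are conserved (one copy each by default), and the
degradation products are a conceptual sink rather than tracked species. Two
structural choices deserve note. First, the repressor is given its own
promoter species (`DNAr`): the model narrative requires a repressor whose
expression is triggered by Cap⁺ through direct regulation by CAP, and a
second promoter is the minimal realization of that. Second, the CAP
feedback channel is written autocatalytically (`UXP + CA -> 2 CA`); a
translation-only reading is also defensible, but the autocatalytic form
makes "CAP synthesis draws UTP into capsule production" an explicit
reaction while remaining sub-critical at high UXP
(`k_cap_feedback * UXP < k_deg_CA` for the shipped constants), so it cannot
run away in the basal regime.

Repression halts synthesis only; bound transcripts are not actively
degraded — baseline mRNA turnover continues unchanged. Propensities use
combinatorial mass action, so dimerization `R + R -> R2` fires at
`k * R * (R - 1) / 2`.

# Simulation

`simulate_network()` is an exact Gillespie direct-method simulator (compiled
core, R's own RNG stream, so `set.seed()` governs reproducibility; a single
stream serves both the waiting-time and channel draws). The default horizon
is 200,000 simulated seconds with the first 10,000 s discarded as burn-in —
the state prevailing at the end of burn-in seeds the reported path. Initial
states are randomized under the constraint that UXP strictly outnumbers
activator molecules. Records are event-resolved or sampled on a fixed grid
(sample-and-hold); time-weighted statistics on the grid converge to the
event-resolved values as the step shrinks, and the sweeps use a 20 s grid.

# Calibrated default rate constants

The original rate values are not published, so the package ships its own
set, chosen by timescale analysis and certified by `calibrate_defaults()`
against explicit targets: at `k_uxp_prod = 0.003` both phenotype states
must each occupy at least 10% of the window with mean dwell of at least two
hours (two division equivalents) and at least two switch events per window;
at `k_uxp_prod = 3` at most one switch event per window (medians over
seeds). The design logic, in units of seconds and molecules:

* UXP at high supply settles near `k_uxp_prod / k_pyrg_drain = 300`
  molecules, enough to sequester ~99.7% of a ten-molecule activator pool;
  at low supply UXP is near zero and the activator is free.
* During Cap⁺, the active promoter sustains ~20 transcripts and ~300 CAP
  molecules (relaxation time `1/k_deg_CA = 1000` s), far above the basal
  level of ~1–2 molecules, so the two states are widely separated.
* The Cap⁺ episode ends when enough repressor dimer has accumulated to
  capture the promoter during an activator-unbound interval; the Cap⁻
  episode ends when the dimer pool has decayed. Both timescales are several
  thousand seconds, giving dwell times of a few division equivalents.

Because these constants are calibrated stand-ins, the published sweep
occupancy endpoints (Cap⁻ fractions of 11.6%–90.4%) are matched only
qualitatively — the corresponding checks assert a wide tunability span and
retained bistability rather than those exact numbers.

# Phenotype calls and occupancy

No numeric state-call threshold is published. The default rule computes an
exact time-weighted two-cluster split of the CAP values and calls the
trajectory bimodal when the cluster centres are at least 30 molecules apart
and the minor cluster holds at least 2% of the window; the threshold is
then the midpoint of the centres (~150 molecules for the shipped defaults).
Unimodal trajectories fall back to a fixed 20 molecules, well below the
~100-molecule high-expression extreme. The threshold used is always
recorded in the outputs, since occupancy numbers are only interpretable
together with the rule that produced them. A single threshold (no
hysteresis) keeps occupancy statistics well defined; a debounce for
ultra-short segments was considered and left off to stay faithful to the
raw state calls. Shot noise around the high level occasionally produces
brief threshold crossings, which slightly inflates switch counts — another
reason the dwell and occupancy checks are phrased as medians.

# The sweeps

The dose sweep runs the network at UXP production 0.003 / 0.3 / 3
(the 1,000-fold range; low = switchers, high = ancestors). The sensitivity
sweep perturbs each of the 23 constants ten-fold down and up, one at a time
(47 conditions with the baseline), with ten replicates per condition, and
reports per-run and per-condition-mean Cap⁻ occupancy plus mean cumulative
occupancy curves. Replicates use common random numbers — replicate *r*
carries the same derived seed in every condition — which pairs conditions
for the one-at-a-time comparison and makes a factor-1 perturbation
reproduce the baseline rows exactly. Replicate aggregation is the mean
(matching the ten-run mean curves of the original analysis), with medians
reported alongside for robustness.

# The synthetic microcolony generator

The generator emulates the time-lapse observations of single Cap⁻ founder
cells growing into microcolonies:

* **Growth** is a Markov branching process: exponential division waiting
  times at 0.0116 min⁻¹ (Cap⁻) and 0.0113 min⁻¹ (Cap⁺) — the measured
  rates, interpreted as Malthusian parameters so the implied division times
  are `ln(2)/rate` = 59.8 and 61.3 min. Fixed-interval division laws were
  not used because only rates are reported and the exponential law keeps
  the branching oracle analytically tractable.
* **Switching**: each colony draws a threshold from a Gaussian with mean
  1870 and SD 660 cells; Cap⁻ cells switch stochastically at a per-cell
  rate only while the population is at or above the threshold. The default
  per-cell rate (0.1 min⁻¹) puts the generator in the threshold-dominated
  regime, where the first-switch size converges to the drawn threshold and
  the Gaussian is reproduced essentially exactly. The generator takes no
  position on whether the real cue is population size or a density signal;
  the threshold is simply on cell count.
* **Founder reversion**: Cap⁺ founder cells revert to Cap⁻ on an
  exponential clock (default mean 30 min — "a very short time frame" is
  not quantified, so this sits well below the ~60 min division time).
* **Censoring**: colonies are observed to `total_time` (default 720 min,
  by which a Cap⁻ colony reaches ~4,000 cells, beyond virtually all
  threshold draws); colonies that never switch are reported as censored.

What the generator deliberately does not model: spatial colony geometry,
GFP fluorescence (phenotype is recorded directly, standing in for the
reported 100% GFP–capsule correlation), imaging noise, or cell death.
Passing tests therefore show that the inference stage recovers the
parameters of this idealized process, not that it would survive
segmentation artefacts in real micrographs.

# Inference

Growth rates are estimated as the least-squares slope of `ln(population)`
versus time over same-phenotype epochs (separate intercepts per epoch,
common slope). Observations below 32 cells are excluded by default: early
in a branching process `ln N(t)` has a stochastic offset that is still
drifting, and dropping the small-colony transient removes most of the
resulting slope bias at negligible cost in precision. The capsulation cost
is `100 (1 - r⁺/r⁻)` percent with the delta-method SE.

First-switch sizes are compared between two maximum-likelihood models: a
Gaussian in population size, and a memoryless foil with constant
per-division switch probability *p*, under which the first-switch size is
geometric — `P(N = n) = p (1 - p)^(n-2)` for `n >= 2` — the formal version
of "a random process independent of population size" (reported in the
original analysis as the Poisson alternative). Censored colonies enter both
likelihoods as survival terms. Preference is by AIC (k = 2 vs k = 1). Fits
are on raw sizes, not log sizes; the original scale is the natural one for
a cell-count threshold, and the choice is configurable upstream of the fit
by transforming the inputs.

The capsule counting assay is emulated as binomial draws (500 cells per
replicate, 5 replicates), summarized by the mean of per-replicate
proportions with SE = SD/√n. The two-sample policy mirrors the stated
testing protocol: Shapiro normality gate at α = 0.05 per group (the
original check is unnamed; Shapiro is the standard choice at these sample
sizes), then a pooled or Welch t test (Welch when an F test rejects equal
variances), otherwise Wilcoxon rank-sum.

# Problem sizes and numerical choices

The analysis scripts and acceptance checks run at the published scale:
200,000 s horizon, 47 × 10 sensitivity runs, 58 microcolonies, 500 × 5
assay draws. Unit tests use reduced horizons and smaller colonies chosen so
that each oracle retains its stated power (e.g. 3-SE bands). Degenerate
inputs are rejected loudly rather than repaired: zero-width simulation
windows, negative thresholds, unsorted level grids, Cap⁺-founder trees in
first-switch statistics, and single-replicate SEs are all errors. When all
propensities vanish the simulator reports an absorbed trajectory rather
than inventing events, and an event-count safety cap turns runaway
parameter sets into a diagnosable truncation error.

# Known limitations

* The rate constants are calibrated stand-ins; quantitative occupancy
  values under perturbation are specific to this parameterization.
* Thresholded state calls without debounce over-count switches when CAP
  noise grazes the threshold.
* The lineage generator's exponential division times overdisperse
  division-age distributions relative to real cells; first-switch-size
  statistics are insensitive to this in the threshold-dominated regime,
  but age-structured quantities would not be.
* Single-cell network simulations and the microcolony generator are not
  coupled: the network models CAP copy number within one cell, while the
  colony model abstracts switching into rates, as the two analyses do in
  the source material.
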