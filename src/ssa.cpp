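#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Combinatorial mass-action propensity for one reaction:
// k * prod_i choose(x_i, s_i), the number of distinct reactant combinations.
static double propensity_one(const std::vector<int>& x,
                             const int* stoich, int n_species, double k) {
  double a = k;
  for (int i = 0; i < n_species; ++i) {
    int s = stoich[i];
    if (s == 0) continue;
    int xi = x[i];
    if (xi < s) return 0.0;
    // falling factorial / s!
    double c = 1.0;
    for (int j = 0; j < s; ++j) c *= (xi - j);
    for (int j = 2; j <= s; ++j) c /= j;
    a *= c;
  }
  return a;
}

// [[Rcpp::export(name = ".ssa_propensities")]]
NumericVector ssa_propensities(IntegerVector state, NumericVector rates,
                               IntegerMatrix reactants) {
  int n_species = reactants.nrow(), n_rxn = reactants.ncol();
  std::vector<int> x(state.begin(), state.end());
  NumericVector a(n_rxn);
  for (int r = 0; r < n_rxn; ++r)
    a[r] = propensity_one(x, &reactants(0, r), n_species, rates[r]);
  return a;
}

// Gillespie direct method. Uses R's RNG stream (set.seed() controls it).
// record_mode: 0 = event-resolved, 1 = fixed grid with step grid_step.
// Records cover [burn_in, t_end]; the state prevailing at burn_in is the
// first record in both modes.
// [[Rcpp::export(name = ".ssa_simulate")]]
List ssa_simulate(IntegerVector init, NumericVector rates,
                  IntegerMatrix reactants, IntegerMatrix products,
                  double t_end, double burn_in,
                  int record_mode, double grid_step, double max_events) {
  int n_species = reactants.nrow(), n_rxn = reactants.ncol();
  std::vector<int> x(init.begin(), init.end());
  std::vector<double> a(n_rxn);

  std::vector<double> rec_t;
  std::vector<int> rec_x;  // row-major per record
  bool absorbed = false;
  double n_events = 0.0;
  bool truncated = false;

  // grid bookkeeping
  double next_grid = burn_in;
  long n_grid = 0;
  if (record_mode == 1)
    n_grid = (long)std::floor((t_end - burn_in) / grid_step) + 1;

  double t = 0.0;
  bool burn_recorded = false;

  auto record = [&](double time) {
    rec_t.push_back(time);
    for (int i = 0; i < n_species; ++i) rec_x.push_back(x[i]);
  };

  GetRNGstate();
  for (;;) {
    double a0 = 0.0;
    for (int r = 0; r < n_rxn; ++r) {
      a[r] = propensity_one(x, &reactants(0, r), n_species, rates[r]);
      if (a[r] < 0.0 || !R_finite(a[r])) {
        PutRNGstate();
        stop("internal consistency error: propensity %d is %f", r + 1, a[r]);
      }
      a0 += a[r];
    }

    double t_next;
    int chosen = -1;
    if (a0 <= 0.0) {
      absorbed = true;
      t_next = R_PosInf;
    } else {
      double u1 = unif_rand();
      t_next = t - std::log(u1) / a0;
      double u2 = unif_rand() * a0;
      double cum = 0.0;
      for (int r = 0; r < n_rxn; ++r) {
        cum += a[r];
        if (u2 <= cum) { chosen = r; break; }
      }
      if (chosen < 0) chosen = n_rxn - 1;  // float guard
    }

    // emit records for grid points passed before the next event fires
    if (record_mode == 1) {
      while (n_grid > 0 && next_grid <= t_end && next_grid < t_next) {
        record(next_grid);
        next_grid += grid_step;
        --n_grid;
      }
    } else {
      if (!burn_recorded && t_next > burn_in) {
        record(burn_in);
        burn_recorded = true;
      }
    }

    if (t_next > t_end || absorbed) break;

    // apply stoichiometry
    for (int i = 0; i < n_species; ++i) {
      x[i] += products(i, chosen) - reactants(i, chosen);
      if (x[i] < 0) {
        PutRNGstate();
        stop("internal consistency error: negative count for species %d", i + 1);
      }
    }
    t = t_next;
    n_events += 1.0;
    if (record_mode == 0 && t >= burn_in) record(t);
    if (n_events >= max_events) { truncated = true; break; }
  }
  PutRNGstate();

  int n_rec = rec_t.size();
  IntegerMatrix counts(n_rec, n_species);
  NumericVector times(n_rec);
  for (int r = 0; r < n_rec; ++r) {
    times[r] = rec_t[r];
    for (int i = 0; i < n_species; ++i)
      counts(r, i) = rec_x[(size_t)r * n_species + i];
  }
  IntegerVector final_state(x.begin(), x.end());
  return List::create(_["times"] = times, _["counts"] = counts,
                      _["n_events"] = n_events, _["absorbed"] = absorbed,
                      _["truncated"] = truncated, _["final_state"] = final_state,
                      _["final_time"] = t);
}
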