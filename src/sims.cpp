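#include <Rcpp.h>
using namespace Rcpp;

// Constant-size Moran process, one replicate per row.
// Self-loops are aggregated: the holding time in a state is geometric with
// success probability p_up + p_down, and conditional on a move the step is
// up with probability r / (1 + r) (independent of the state, since the
// up/down ratio of this chain is constant).
// Returns a matrix with columns (absorbed: 1 fixed / 0 lost / -1 unabsorbed,
// elementary steps taken).
// [[Rcpp::export]]
NumericMatrix cpp_moran_sim(int N, double r, int i0, double max_steps,
                            int reps) {
  NumericMatrix out(reps, 2);
  const double p_up_given_move = r / (1.0 + r);
  for (int rep = 0; rep < reps; ++rep) {
    double steps = 0.0;
    int k = i0;
    int absorbed = (k == 0) ? 0 : (k == N ? 1 : -1);
    while (absorbed < 0 && steps < max_steps) {
      double denom = (r * k + (double)(N - k)) * (double)N;
      double p_move = (1.0 + r) * (double)k * (double)(N - k) / denom;
      // geometric holding time (number of trials incl. the move)
      double hold = 1.0 + R::rgeom(p_move);
      steps += hold;
      if (steps > max_steps) { steps = max_steps; break; }
      if (unif_rand() < p_up_given_move) ++k; else --k;
      if (k == 0) absorbed = 0;
      else if (k == N) absorbed = 1;
    }
    out(rep, 0) = absorbed;
    out(rep, 1) = steps;
  }
  return out;
}

// Yule process with irreversible mutation: population grows by one per
// division; the dividing cell is uniform among living cells; a wild-type
// division yields one mutant daughter with probability mu. Returns the
// mutant count when the population first reaches n_stop.
// [[Rcpp::export]]
NumericVector cpp_yule_sim(int n0, double mu, int n_stop, int reps) {
  NumericVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    double wt = n0, m = 0.0;
    while (wt + m < n_stop) {
      double total = wt + m;
      if (unif_rand() * total < wt) {
        if (mu > 0.0 && unif_rand() < mu) m += 1.0; else wt += 1.0;
      } else {
        m += 1.0;
      }
    }
    out[rep] = m;
  }
  return out;
}

// Tau-leaping stochastic engine for the mutant lineage in a population of
// time-varying size N(t). Per-mutant transition rates are the exact
// continuous-time Moran rates (division events at rate b per cell; one
// death and one fitness-biased replacement per event):
//   up:   b (1 + s) (1 - f) / (1 + s f)  + max(dlnN/dt, 0)
//   down: b (1 - f) / (1 + s f)          + max(-dlnN/dt, 0)
// with f = M / N(t); the dlnN/dt terms couple the lineage to the
// population's net growth so neutral lineages keep a constant expected
// frequency. At small f these reduce to a supercritical branching process
// (birth b(1+s), death b at constant N). Poisson influx of newly mutated
// cells enters at rate mu * b * (N - M) (recurrent mutation at wild-type
// divisions).
// Arguments are per-step vectors on a uniform grid of width dt. Stops when
// M >= thr[k] (switch to the deterministic engine) or at the end of the
// grid. Returns (stop index 1-based or 0 if never switched, M at stop/end,
// full path of M at each grid point; NA beyond the stop).
// [[Rcpp::export]]
List cpp_branch_path(NumericVector Nt, NumericVector gam, NumericVector st,
                     NumericVector thr, double mu, double b, double dt,
                     double m0) {
  int n = Nt.size();
  NumericVector path(n);
  double M = m0;
  int switch_idx = 0;
  for (int k = 0; k < n; ++k) {
    if (M >= thr[k]) {
      switch_idx = k + 1;
      for (int j = k; j < n; ++j) path[j] = NA_REAL;
      path[k] = M;
      break;
    }
    double N = Nt[k];
    if (M > N) M = N;
    double f = (N > 0.0) ? M / N : 0.0;
    double s = st[k];
    double moran = b * (1.0 - f) / (1.0 + s * f);
    double g = gam[k];
    double birth_rate = moran * (1.0 + s) + (g > 0.0 ? g : 0.0);
    double death_rate = moran + (g < 0.0 ? -g : 0.0);
    double wt = N - M;
    if (wt < 0.0) wt = 0.0;
    double births = (M > 0.0) ? R::rpois(M * birth_rate * dt) : 0.0;
    double deaths = (M > 0.0) ? R::rpois(M * death_rate * dt) : 0.0;
    double influx = (mu > 0.0) ? R::rpois(mu * b * wt * dt) : 0.0;
    M += births - deaths + influx;
    if (M < 0.0) M = 0.0;
    if (M > N) M = N;
    path[k] = M;
    if (M <= 0.0 && mu <= 0.0) { // extinct with no recurrent supply
      for (int j = k + 1; j < n; ++j) path[j] = 0.0;
      break;
    }
  }
  return List::create(_["switch_idx"] = switch_idx, _["M"] = M,
                      _["path"] = path);
}
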