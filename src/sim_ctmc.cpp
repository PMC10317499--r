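#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie) of a finite-state continuous-time
// Markov chain, aggregated on the fly into alternating open/shut sojourns.
// Durations are returned in milliseconds; Q is in s^-1.  Uses R's RNG so
// results are reproducible under set.seed().
//
// [[Rcpp::export]]
List sim_ctmc_intervals(NumericMatrix Q, int start, int n_intervals,
                        IntegerVector open_states) {
  const int ns = Q.nrow();
  if (start < 1 || start > ns) stop("invalid start state");
  std::vector<double> exit_rate(ns);
  std::vector< std::vector<double> > cum(ns, std::vector<double>(ns));
  std::vector<bool> is_open(ns, false);
  for (int i = 0; i < open_states.size(); ++i) {
    int s = open_states[i];
    if (s < 1 || s > ns) stop("invalid open state index");
    is_open[s - 1] = true;
  }
  for (int i = 0; i < ns; ++i) {
    exit_rate[i] = -Q(i, i);
    if (exit_rate[i] <= 0) stop("absorbing state in rate matrix");
    double acc = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (j != i) acc += Q(i, j);
      cum[i][j] = acc;
    }
    for (int j = 0; j < ns; ++j) cum[i][j] /= acc;
  }

  std::vector<double> dur;
  std::vector<int> op;
  std::vector<int> last_state; // state occupied when each interval ended
  dur.reserve(n_intervals);
  op.reserve(n_intervals);

  RNGScope scope;
  int s = start - 1;
  bool cur_open = is_open[s];
  double cur = 0.0;

  while ((int)dur.size() < n_intervals) {
    double dt = R::exp_rand() / exit_rate[s] * 1000.0; // ms
    if (is_open[s] == cur_open) {
      cur += dt;
    } else {
      dur.push_back(cur);
      op.push_back(cur_open ? 1 : 0);
      last_state.push_back(s + 1);
      cur_open = is_open[s];
      cur = dt;
    }
    double u = R::unif_rand();
    int nxt = 0;
    while (cum[s][nxt] < u) ++nxt;
    s = nxt;
  }
  return List::create(Named("open") = wrap(op),
                      Named("duration_ms") = wrap(dur));
}
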