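#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time Markov trajectory: embedded-chain jumps with
// exponential waiting times. Runs until accumulated time exceeds
// `duration` (ms) or `max_transitions` is hit. Uses R's RNG so results are
// reproducible under set.seed().
//
// Q: generator matrix (1/ms). start: 0-based initial state.
// Returns list(state = 1-based state sequence, dwell = dwell per visit, ms)
// [[Rcpp::export(name = ".ctmc_simulate")]]
List ctmc_simulate(NumericMatrix Q, int start, double duration,
                   int max_transitions) {
  const int n = Q.nrow();
  std::vector<double> exit_rate(n);
  std::vector<std::vector<double>> cumprob(n);
  std::vector<std::vector<int>> target(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != i && Q(i, j) > 0) tot += Q(i, j);
    }
    exit_rate[i] = tot;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != i && Q(i, j) > 0) {
        acc += Q(i, j) / tot;
        cumprob[i].push_back(acc);
        target[i].push_back(j);
      }
    }
  }
  std::vector<int> states;
  std::vector<double> dwells;
  states.reserve(1024);
  dwells.reserve(1024);
  int s = start;
  double t = 0.0;
  for (int k = 0; k < max_transitions; ++k) {
    double dt = R::exp_rand() / exit_rate[s];
    states.push_back(s + 1);
    dwells.push_back(dt);
    t += dt;
    if (t >= duration) break;
    double u = R::unif_rand();
    const std::vector<double>& cp = cumprob[s];
    int m = (int)cp.size();
    int j = 0;
    while (j < m - 1 && u > cp[j]) ++j;
    s = target[s][j];
  }
  return List::create(_["state"] = wrap(states), _["dwell"] = wrap(dwells));
}
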