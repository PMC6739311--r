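#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Random-sequential heat-bath dynamics. One sweep = n single-site
// updates at uniformly random updatable sites. Each update draws the new
// spin from its conditional equilibrium distribution given the CURRENT
// in-neighbour spins: P(s = +1) = 1 / (1 + exp(-2 h / T)); the T = 0
// limit is the step function with a fair coin at h = 0. Exactly two
// uniforms from R's stream are consumed per update (site, then
// decision), so trajectories are reproducible from set.seed() and the
// symmetric flip/keep draw negates exactly under global spin reversal.
//
// symmetric_draw = true decides flip-vs-keep (P(flip) depends on the
// current spin); false redraws the spin directly against P(s = +1).
// Both are exact heat-bath samplers.
// [[Rcpp::export]]
List ising_run_cpp(int n, IntegerVector in_ptr, IntegerVector in_idx,
                   IntegerVector spins0, double temperature,
                   int sweeps_transient, int sweeps_observe,
                   List subsets, IntegerVector update_sites,
                   bool symmetric_draw) {
  const int* ptr = in_ptr.begin();
  const int* idx = in_idx.begin();
  std::vector<int> s(spins0.begin(), spins0.end());

  int n_upd = update_sites.size();
  if (n_upd == 0) stop("no updatable sites");
  const int* upd = update_sites.begin();

  int nsub = subsets.size();
  std::vector<std::vector<int> > subs(nsub);
  for (int k = 0; k < nsub; ++k)
    subs[k] = as<std::vector<int> >(subsets[k]);

  NumericMatrix m(sweeps_observe, nsub);
  int total = sweeps_transient + sweeps_observe;

  for (int sweep = 0; sweep < total; ++sweep) {
    for (int u = 0; u < n; ++u) {
      int pick = (int)(unif_rand() * n_upd);
      if (pick == n_upd) pick = n_upd - 1;
      int i = upd[pick];
      int h = 0;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) h += s[idx[k]];
      double p_up;
      if (temperature > 0.0) {
        p_up = 1.0 / (1.0 + std::exp(-2.0 * h / temperature));
      } else {
        p_up = h > 0 ? 1.0 : (h < 0 ? 0.0 : 0.5);
      }
      double udraw = unif_rand();
      if (symmetric_draw) {
        double p_flip = s[i] == 1 ? 1.0 - p_up : p_up;
        if (udraw < p_flip) s[i] = -s[i];
      } else {
        s[i] = udraw < p_up ? 1 : -1;
      }
    }
    if (sweep >= sweeps_transient) {
      int row = sweep - sweeps_transient;
      for (int k = 0; k < nsub; ++k) {
        const std::vector<int>& sub = subs[k];
        long acc = 0;
        for (size_t j = 0; j < sub.size(); ++j) acc += s[sub[j]];
        m(row, k) = (double)acc / (double)sub.size();
      }
    }
  }
  return List::create(_["m"] = m,
                      _["spins"] = IntegerVector(s.begin(), s.end()));
}
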