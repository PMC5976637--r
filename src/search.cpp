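#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rejection-sampling inner loop for one block of candidate metacommunities.
//
// Draw d (0-based within the block) consumes uniforms d*N .. d*N + N - 1, in
// order, from R's RNG stream; the caller seeds the stream per block so the
// overall draw sequence is defined by (master seed, block index, draw index)
// only. Colonisation rates are sorted ascending so rank 1 (best competitor)
// is the worst coloniser, then the sequential equilibrium recursion runs
// with early exit on the first non-positive occupancy.
//
// [[Rcpp::export(name = ".block_search_cpp")]]
List block_search_cpp(int n_draws, int n_species, double c_low, double c_high,
                      double m0, double tol) {
  std::vector<double> cvals(n_species);
  std::vector<NumericVector> accepted;
  std::vector<int> idx;
  for (int d = 0; d < n_draws; ++d) {
    bool tie = true;
    while (tie) {
      for (int i = 0; i < n_species; ++i) cvals[i] = R::runif(c_low, c_high);
      std::sort(cvals.begin(), cvals.end());
      tie = false;  // ties have probability zero; re-draw if they occur
      for (int i = 1; i < n_species; ++i)
        if (cvals[i] == cvals[i - 1]) { tie = true; break; }
    }
    double S = 0.0, A = 0.0;
    bool ok = true;
    for (int i = 0; i < n_species; ++i) {
      double pi = (1.0 - S) - (m0 + A) / cvals[i];
      if (pi <= tol) { ok = false; break; }
      S += pi;
      A += cvals[i] * pi;
    }
    if (ok) {
      accepted.push_back(NumericVector(cvals.begin(), cvals.end()));
      idx.push_back(d + 1);
    }
  }
  return List::create(_["accepted"] = wrap(accepted),
                      _["draw_index"] = wrap(idx),
                      _["n_draws"] = n_draws);
}
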