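#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <numeric>
#include <cmath>

using namespace Rcpp;

// Monte-Carlo kernel for the clustered-substitution null model.
//
// For each replicate and each sequence load m, draws m distinct positions
// with probability proportional to `weights` (weighted sampling without
// replacement via smallest exponential keys E_i / w_i, distributionally
// identical to R's sequential `sample(prob=)`), then counts maximal runs of
// adjacent positions. Run lengths above max_k are accumulated in the max_k
// column. Replicate r uses an RNG stream derived from (seed, r) only, so
// results are reproducible independently of execution order.
//
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_runs(NumericVector weights, IntegerVector positions,
                                IntegerVector loads, int reps, int max_k,
                                double seed) {
  const int P = weights.size();
  if (positions.size() != P) stop("weights/positions length mismatch");
  const int n_seq = loads.size();
  for (int s = 0; s < n_seq; ++s) {
    if (loads[s] > P) stop("load exceeds available positions for sequence %d",
                           s + 1);
  }
  IntegerMatrix out(reps, max_k);
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<double> keys(P);
  std::vector<int> idx(P);
  std::vector<int> sel;
  const uint64_t base = static_cast<uint64_t>(seed);

  for (int r = 0; r < reps; ++r) {
    std::mt19937_64 rng(base * 0x9E3779B97F4A7C15ULL + static_cast<uint64_t>(r) + 1ULL);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (int s = 0; s < n_seq; ++s) {
      const int m = loads[s];
      if (m <= 0) continue;
      for (int i = 0; i < P; ++i) {
        const double u = 1.0 - unif(rng);      // in (0, 1]
        keys[i] = -std::log(u) / w[i];
      }
      std::iota(idx.begin(), idx.end(), 0);
      if (m < P) {
        std::nth_element(idx.begin(), idx.begin() + m - 1, idx.end(),
                         [&](int a, int b) { return keys[a] < keys[b]; });
      }
      sel.assign(idx.begin(), idx.begin() + m);
      for (std::size_t j = 0; j < sel.size(); ++j) sel[j] = positions[sel[j]];
      std::sort(sel.begin(), sel.end());
      int run = 1;
      for (int j = 1; j <= m; ++j) {
        if (j < m && sel[j] == sel[j - 1] + 1) {
          ++run;
        } else {
          const int kk = std::min(run, max_k);
          out(r, kk - 1) += 1;
          run = 1;
        }
      }
    }
  }
  return out;
}
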