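#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Monte-Carlo two-group permutation resampling for the combined-state
// pairwise tests: counts how many of nPerm random splits of v into
// groups of size n1 / (n - n1) give |mean1 - mean2| >= obs.  Uses R's
// RNG (a partial Fisher-Yates shuffle per permutation), so results
// are reproducible under set.seed().

// [[Rcpp::export(name = ".pairPermCount")]]
int pairPermCount(NumericVector v, int n1, int nPerm, double obs) {
  const int n = v.size();
  const int n2 = n - n1;
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty");
  const double total = std::accumulate(v.begin(), v.end(), 0.0);
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  int count = 0;
  for (int b = 0; b < nPerm; ++b) {
    for (int j = 0; j < n1; ++j) {
      int k = j + static_cast<int>(unif_rand() * (n - j));
      if (k >= n) k = n - 1;          // guard against unif_rand() == 1
      std::swap(idx[j], idx[k]);
    }
    double s = 0.0;
    for (int j = 0; j < n1; ++j) s += v[idx[j]];
    const double stat = std::fabs(s / n1 - (total - s) / n2);
    // tie-tolerant: summation order must not break exact ties
    if (stat >= obs - 1e-9 * (std::fabs(obs) + 1.0)) ++count;
  }
  return count;
}
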