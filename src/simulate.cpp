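#include <Rcpp.h>
using namespace Rcpp;

// Balls-in-bins dispersal replicates. Per replicate: the retained pollen
// count is M with probability w applied either binomially (stochastic
// thinning) or as a fixed round(w*M); each retained pollen lands uniformly
// on one of h spatial units; the fertilized count is the number of the F
// designated ovule-units (taken as units 0..F-1 by exchangeability) that
// receive at least one pollen. Uses R's RNG, so set.seed() governs results.
// [[Rcpp::export]]
IntegerVector dispersal_replicates_cpp(int F, int M, int h, double w,
                                       int reps, bool stochastic_retention) {
  IntegerVector fert(reps);
  std::vector<int> mark(F, -1);
  int retained_fixed = (int) std::lround(w * (double) M);
  for (int r = 0; r < reps; ++r) {
    int retained = stochastic_retention
      ? (int) R::rbinom((double) M, w)
      : retained_fixed;
    int count = 0;
    for (int j = 0; j < retained; ++j) {
      int u = (int) (unif_rand() * h);
      if (u >= h) u = h - 1;  // guard the unif_rand() == 1.0 edge
      if (u < F && mark[u] != r) {
        mark[u] = r;
        ++count;
      }
    }
    fert[r] = count;
  }
  return fert;
}
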