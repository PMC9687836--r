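#include <Rcpp.h>
using namespace Rcpp;

// Count label permutations whose rank-sum statistic is at least as extreme as
// the observed one. `ranks` are the midranks of the pooled sample; a
// permutation draws n_case of them without replacement and the deviation is
// |ranksum - n_case * (N + 1) / 2| (equivalent to the deviation of the
// Mann-Whitney U from its null mean, since midranks sum to N(N+1)/2).
// Uses R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export]]
double mc_ranksum_exceed(NumericVector ranks, int n_case, int n_sim,
                         double obs_dev) {
  const int N = ranks.size();
  if (n_case <= 0 || n_case >= N)
    stop("n_case must be strictly between 0 and the pooled size");
  std::vector<double> pool(ranks.begin(), ranks.end());
  const double mu = n_case * (N + 1.0) / 2.0;
  const double eps = 1e-9;
  double exceed = 0.0;
  for (int s = 0; s < n_sim; ++s) {
    // partial Fisher-Yates: place a random n_case-subset in pool[0..n_case)
    double rs = 0.0;
    for (int i = 0; i < n_case; ++i) {
      int j = i + (int)R_unif_index(N - i);
      std::swap(pool[i], pool[j]);
      rs += pool[i];
    }
    if (std::abs(rs - mu) >= obs_dev - eps) exceed += 1.0;
  }
  return exceed;
}
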