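#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Monte-Carlo tail counts for the ambient-pool multinomial test.
//
// For every unique barcode total T (ascending), draws `niters` count vectors
// from Multinomial(T, prob) and counts, for each observed barcode with that
// total, how many simulated vectors have conditional log-likelihood at or
// below the barcode's observed log-likelihood. Simulation is incremental:
// one stream of gene draws per iteration is extended from one total to the
// next, updating the log-likelihood in O(1) per added count, so the cost is
// niters * max(total) draws regardless of how many totals are tested.
//
// prob:      ambient probability vector (genes)
// totals:    sorted unique totals, ascending
// obs_ll:    observed log-likelihood per tested barcode
// obs_group: 0-based index into `totals` per tested barcode
// niters:    Monte-Carlo iterations
//
// Returns an integer vector of tail counts per barcode. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector mc_ambient_tail_counts(NumericVector prob, IntegerVector totals,
                                     NumericVector obs_ll,
                                     IntegerVector obs_group, int niters) {
  const int G = prob.size();
  const int nT = totals.size();
  const int nB = obs_ll.size();
  if (nT == 0 || nB == 0) return IntegerVector(0);

  std::vector<double> cum(G);
  double acc = 0.0;
  for (int g = 0; g < G; ++g) { acc += prob[g]; cum[g] = acc; }
  for (int g = 0; g < G; ++g) cum[g] /= acc;
  std::vector<double> logp(G);
  for (int g = 0; g < G; ++g)
    logp[g] = std::log(prob[g] / acc);

  const int tmax = totals[nT - 1];
  // logtab[k] = log(k), k = 1..tmax
  std::vector<double> logtab(tmax + 1);
  for (int k = 1; k <= tmax; ++k) logtab[k] = std::log((double) k);

  // barcodes grouped by total index
  std::vector< std::vector<int> > groups(nT);
  for (int b = 0; b < nB; ++b) {
    int gidx = obs_group[b];
    if (gidx < 0 || gidx >= nT) stop("obs_group out of range");
    groups[gidx].push_back(b);
  }

  IntegerVector tail(nB);
  std::vector<int> counts(G);
  const double tol = 1e-8;

  for (int it = 0; it < niters; ++it) {
    std::fill(counts.begin(), counts.end(), 0);
    double ll = 0.0;
    int t = 0;
    for (int j = 0; j < nT; ++j) {
      const int target = totals[j];
      for (; t < target; ) {
        double u = unif_rand();
        int g = (int) (std::lower_bound(cum.begin(), cum.end(), u) -
                       cum.begin());
        if (g >= G) g = G - 1;
        ++counts[g];
        ++t;
        // lgamma(t+1) gains log(t); lgamma(x_g+1) gains log(x_g)
        ll += logp[g] + logtab[t] - logtab[counts[g]];
      }
      const std::vector<int>& grp = groups[j];
      for (size_t q = 0; q < grp.size(); ++q)
        if (ll <= obs_ll[grp[q]] + tol) ++tail[grp[q]];
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return tail;
}
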