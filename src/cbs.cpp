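#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation arc statistic.
//
// For a segment x[0..m-1], consider every circular arc (i, j], 0 <= i < j <= m
// (the arc wraps conceptually; complements of edge-touching arcs are the edge
// pieces). The statistic is the absolute standardized difference between the
// arc mean and the complement mean,
//   |mean_arc - mean_rest| / sqrt(1/k + 1/(m-k)),
// the segment-wide variance being a permutation-invariant constant that is
// dropped. Arcs are restricted so that both the arc and its complement hold
// at least min_w markers.

static double max_arc_stat(const double *x, int m, int min_w,
                           int *best_i, int *best_j) {
  std::vector<double> S(m + 1, 0.0);
  for (int t = 0; t < m; ++t) S[t + 1] = S[t] + x[t];
  const double total = S[m];
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j <= m; ++j) {
      int k = j - i;
      int rest = m - k;
      if (k < min_w || rest < min_w) continue;
      double arc = S[j] - S[i];
      double d = arc / k - (total - arc) / rest;
      double stat = std::fabs(d) / std::sqrt(1.0 / k + 1.0 / rest);
      if (stat > best) {
        best = stat;
        bi = i;
        bj = j;
      }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_w) {
  int i = -1, j = -1;
  double stat = max_arc_stat(REAL(x), x.size(), min_w, &i, &j);
  return List::create(_["stat"] = stat, _["i"] = i, _["j"] = j);
}

// Permutation p-value for the observed max arc statistic, with early
// termination once the exceedance count can no longer reach significance.
// Uses R's RNG (Fisher-Yates via unif_rand) so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List cbs_perm_pvalue(NumericVector x, double obs_stat, int min_w,
                     int n_perm, double alpha) {
  int m = x.size();
  std::vector<double> work(REAL(x), REAL(x) + m);
  RNGScope scope;
  int exceed = 0;
  int done = 0;
  // once exceed > alpha * n_perm the test cannot be accepted
  const int cutoff = (int)std::floor(alpha * n_perm) + 1;
  for (int b = 0; b < n_perm; ++b) {
    for (int t = m - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(work[t], work[u]);
    }
    double stat = max_arc_stat(work.data(), m, min_w, nullptr, nullptr);
    if (stat >= obs_stat) ++exceed;
    ++done;
    if (exceed >= cutoff) break;
  }
  return List::create(_["p"] = (double)exceed / (double)done,
                      _["n_done"] = done);
}
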