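#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Max circular-arc statistic for one segment of a signal.
// Arcs are (i, j], 0 <= i < j <= n, with both the arc (length k) and its
// complement at least min_width bins. The statistic is the mean difference
// between arc and complement scaled by sqrt(k (n-k) / n); the residual-sd
// factor is constant under permutation so it is dropped from the test.
static double max_arc_stat(const std::vector<double>& S, int n, int min_width,
                           int* best_i, int* best_j) {
  double tot = S[n];
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int k = min_width; k <= n - min_width; ++k) {
    double ik = 1.0 / k, ink = 1.0 / (n - k);
    double w = std::sqrt((double)k * (n - k) / n);
    for (int i = 0; i + k <= n; ++i) {
      double arc = (S[i + k] - S[i]);
      double d = arc * ik - (tot - arc) * ink;
      double s = std::fabs(d) * w;
      if (s > best) { best = s; bi = i; bj = i + k; }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best < 0 ? 0.0 : best;
}

static void prefix_sums(const std::vector<double>& x, std::vector<double>& S) {
  int n = (int)x.size();
  S.resize(n + 1);
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
  int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["stat"] = 0.0, _["i"] = NA_INTEGER, _["j"] = NA_INTEGER);
  std::vector<double> xv(x.begin(), x.end()), S;
  prefix_sums(xv, S);
  int bi, bj;
  double s = max_arc_stat(S, n, min_width, &bi, &bj);
  return List::create(_["stat"] = s, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the max arc statistic, with early stopping: once
// the exceedance count guarantees p >= alpha the remaining permutations
// cannot change the accept/reject decision. Uses R's RNG (honours set.seed).
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue(NumericVector x, double obs, int min_width,
                       int n_perm, double alpha) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), S;
  int stop_count = (int)std::ceil(alpha * n_perm);
  int exceed = 0, done = 0;
  double eps = 1e-12 * (std::fabs(obs) + 1.0);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xv[i], xv[j]);
    }
    prefix_sums(xv, S);
    double s = max_arc_stat(S, n, min_width, nullptr, nullptr);
    if (s >= obs - eps) ++exceed;
    ++done;
    if (exceed >= stop_count) break;
  }
  return (double)exceed / (double)done;
}
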