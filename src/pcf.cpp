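#include <Rcpp.h>
using namespace Rcpp;

// Optimal piecewise-constant fit by dynamic programming over breakpoints.
// Minimizes sum of within-segment squared deviations + gamma per breakpoint,
// subject to a minimum segment length kmin. Ties in cost are broken toward
// fewer segments, then toward earlier breakpoints (via smallest last segment
// start during backtracking).
//
// Returns integer vector of 1-based segment start indices.
// [[Rcpp::export]]
IntegerVector pcf_segment_cpp(NumericVector x, double gamma, int kmin) {
  int n = x.size();
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  // cost[j]: optimal cost of segmenting x[0..j-1]; cost[0] = -gamma so that
  // each segment contributes +gamma, giving (K-1) breakpoints penalized.
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> cost(n + 1, INF), inv(n + 1, 0.0);
  std::vector<int> nseg(n + 1, 0), back(n + 1, -1);
  for (int len = 1; len <= n; ++len) inv[len] = 1.0 / (double)len;
  cost[0] = -gamma;
  const double eps = 1e-12;
  for (int j = kmin; j <= n; ++j) {
    const double sj1 = s1[j], sj2 = s2[j];
    double best = INF;
    int besti = -1, bestn = 0;
    // last segment spans i+1..j (0-based x[i..j-1]), length j-i >= kmin;
    // iterating i upward prefers earlier breakpoints / fewer segments on ties
    for (int i = 0; i <= j - kmin; ++i) {
      const double ci = cost[i];
      if (ci + gamma > best + eps) continue;  // sse >= 0: cannot improve
      const double sum = sj1 - s1[i];
      const double c = ci + (sj2 - s2[i]) - sum * sum * inv[j - i] + gamma;
      if (c < best - eps) {
        best = c; besti = i; bestn = nseg[i] + 1;
      } else if (c <= best + eps && nseg[i] + 1 < bestn) {
        best = std::min(c, best); besti = i; bestn = nseg[i] + 1;
      }
    }
    cost[j] = best; back[j] = besti; nseg[j] = bestn;
  }
  if (cost[n] == INF) {
    // shorter than kmin: single segment
    IntegerVector starts(1); starts[0] = 1; return starts;
  }
  std::vector<int> starts;
  for (int j = n; j > 0; j = back[j]) starts.push_back(back[j] + 1);
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}
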