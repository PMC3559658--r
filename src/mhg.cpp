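#include <Rcpp.h>
using namespace Rcpp;

// Exact p-value of the minimum-hypergeometric (mHG) statistic.
//
// Under a uniform random arrangement of B ones among N positions, computes
// P(mHG score <= s) by dynamic programming over the (n, b) lattice of
// prefix states. A path that first enters the rejection region
// {(n, b): HGT(b; N, B, n) <= s, 1 <= n < N} contributes its probability
// mass to the p-value and is not propagated further; this accumulates the
// hit probability directly and avoids the catastrophic cancellation of
// 1 - P(avoid) when p is tiny.
//
// Hypergeometric tails per lattice row are computed in linear space from
// the top pmf down via the standard pmf ratio recurrence; the extreme
// values involved (>= 1/C(N,B)) stay comfortably inside double range for
// the problem sizes this package meets. Region membership uses a small
// relative tolerance because s is itself one of the HGT values of the
// observed list.
// [[Rcpp::export]]
double mhg_pvalue_cpp(double s, int N, int B) {
  if (B <= 0) return 1.0;
  if (s >= 1.0) return 1.0;
  std::vector<double> lf(N + 1);
  lf[0] = 0.0;
  for (int i = 1; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  const double thresh = s * (1.0 + 1e-9);

  // W[b] = P(first n labels contain b ones, no earlier prefix in region)
  std::vector<double> W(B + 1, 0.0), Wnew(B + 1, 0.0), tail(B + 2, 0.0);
  W[0] = 1.0;
  double phit = 0.0;
  for (int n = 1; n <= N; ++n) {
    int bmax = std::min(n, B);
    int bmin = std::max(0, B - (N - n));
    // tail[b] = P(X >= b), X ~ Hypergeom(N, B, n), for b in bmin..bmax
    double lpmf_top = lf[B] - lf[bmax] - lf[B - bmax]
                    + lf[N - B] - lf[n - bmax] - lf[(N - B) - (n - bmax)]
                    - (lf[N] - lf[n] - lf[N - n]);
    double pmf = std::exp(lpmf_top);
    tail[bmax + 1] = 0.0;
    tail[bmax] = pmf;
    for (int b = bmax; b > bmin; --b) {
      // pmf(b-1) = pmf(b) * b * (N-B-n+b) / ((B-b+1) * (n-b+1))
      pmf *= (double)b * (double)(N - B - n + b) /
             ((double)(B - b + 1) * (double)(n - b + 1));
      tail[b - 1] = tail[b] + pmf;
    }
    double inv = 1.0 / (double)(N - n + 1);
    for (int b = bmax; b >= 0; --b) {
      double p1 = (b > 0) ? W[b - 1] * ((double)(B - b + 1) * inv) : 0.0;
      double p0 = W[b] * ((double)((N - n + 1) - (B - b)) * inv);
      double pin = p1 + p0;
      if (n < N && b >= bmin && tail[b] <= thresh) {
        phit += pin;
        Wnew[b] = 0.0;
      } else {
        Wnew[b] = pin;
      }
    }
    std::swap(W, Wnew);
  }
  if (phit > 1.0) phit = 1.0;
  return phit;
}
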