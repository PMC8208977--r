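#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a 2-state HMM over independent bursts.
// logdens: n x 2 matrix of per-step log emission densities.
// burst_start: 1-based indices of the first step of each burst.
// Bursts multiply, i.e. the recursion restarts at delta at every
// burst_start. Returns the total log-likelihood.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                       NumericVector delta, IntegerVector burst_start) {
  const int n = logdens.nrow();
  if (n == 0) return 0.0;
  std::vector<bool> restart(n, false);
  for (int k = 0; k < burst_start.size(); ++k) {
    int i = burst_start[k] - 1;
    if (i < 0 || i >= n) stop("burst_start out of range");
    restart[i] = true;
  }
  if (!restart[0]) stop("first step must start a burst");

  double ll = 0.0, a0 = 0.0, a1 = 0.0;
  for (int i = 0; i < n; ++i) {
    // log emission, shifted by the row max for scaling
    double l0 = logdens(i, 0), l1 = logdens(i, 1);
    double m = l0 > l1 ? l0 : l1;
    if (!R_finite(m)) {
      if (m == R_NegInf) return R_NegInf;  // impossible observation
      stop("non-finite emission log-density");
    }
    double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m);
    double p0, p1;
    if (restart[i]) {
      p0 = delta[0]; p1 = delta[1];
    } else {
      p0 = a0 * Gamma(0, 0) + a1 * Gamma(1, 0);
      p1 = a0 * Gamma(0, 1) + a1 * Gamma(1, 1);
    }
    a0 = p0 * e0; a1 = p1 * e1;
    double c = a0 + a1;
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c) + m;
    a0 /= c; a1 /= c;
  }
  return ll;
}

// Viterbi decoding for the same 2-state layout; ties broken toward
// state 1 (encamped). Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                              NumericVector delta, IntegerVector burst_start) {
  const int n = logdens.nrow();
  IntegerVector path(n);
  if (n == 0) return path;
  std::vector<bool> restart(n, false);
  for (int k = 0; k < burst_start.size(); ++k) restart[burst_start[k] - 1] = true;

  NumericMatrix lG(2, 2);
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) lG(a, b) = std::log(Gamma(a, b));
  double ld0 = std::log(delta[0]), ld1 = std::log(delta[1]);

  std::vector<int> back0(n), back1(n);
  double v0 = 0.0, v1 = 0.0;
  int seg_start = 0;

  auto trace = [&](int from, int to, double s0, double s1) {
    // backtrack a finished segment [from, to]
    int s = (s1 > s0) ? 1 : 0;  // tie -> encamped (state 0)
    for (int i = to; i >= from; --i) {
      path[i] = s + 1;
      s = (s == 0) ? back0[i] : back1[i];
    }
  };

  for (int i = 0; i < n; ++i) {
    if (restart[i]) {
      if (i > 0) trace(seg_start, i - 1, v0, v1);
      seg_start = i;
      v0 = ld0 + logdens(i, 0);
      v1 = ld1 + logdens(i, 1);
      back0[i] = back1[i] = -1;
    } else {
      double c00 = v0 + lG(0, 0), c10 = v1 + lG(1, 0);
      double c01 = v0 + lG(0, 1), c11 = v1 + lG(1, 1);
      back0[i] = (c10 > c00) ? 1 : 0;
      back1[i] = (c11 > c01) ? 1 : 0;
      double n0 = ((c10 > c00) ? c10 : c00) + logdens(i, 0);
      double n1 = ((c11 > c01) ? c11 : c01) + logdens(i, 1);
      v0 = n0; v1 = n1;
    }
  }
  trace(seg_start, n - 1, v0, v1);
  return path;
}
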