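#include <Rcpp.h>
using namespace Rcpp;

// Stable binomial pmf over e = 0..n at success probability p, written
// into w. Forward recurrence from (1-p)^n for p <= 0.5, backward from
// p^n otherwise, so neither tail underflows the anchor term.
static void binom_weights(int n, double p, std::vector<double> &w) {
  if (p <= 0.5) {
    double q = 1.0 - p, term = 1.0;
    for (int i = 0; i < n; ++i) term *= q;     // (1-p)^n
    double ratio = (q > 0.0) ? p / q : 0.0;
    w[0] = term;
    for (int e = 0; e < n; ++e)
      w[e + 1] = w[e] * ((double)(n - e) / (double)(e + 1)) * ratio;
  } else {
    double term = 1.0;
    for (int i = 0; i < n; ++i) term *= p;     // p^n
    double ratio = (p > 0.0) ? (1.0 - p) / p : 0.0;
    w[n] = term;
    for (int e = n; e > 0; --e)
      w[e - 1] = w[e] * ((double)e / (double)(n - e + 1)) * ratio;
  }
}

// Composite-likelihood sweep scan for one chromosome.
//
// T:      (n+1) x (n+1) hitchhiking transition matrix (rows: escaped e,
//         cols: final derived count f).
// Tpoly:  row sums of T over polymorphic columns f = 1..n-1.
// Tclass: (n+1) x nclass matrix; column c is the transition mass landing
//         in observed class c (folded classes pre-summed).
// b:      background class probabilities.
// pos:    site positions (bp); cls: 1-based class index per site.
// centers: window centers; alphas: intensity grid.
// [[Rcpp::export]]
List clr_scan_cpp(NumericMatrix T, NumericVector Tpoly, NumericMatrix Tclass,
                  NumericVector b, NumericVector pos, IntegerVector cls,
                  NumericVector centers, NumericVector alphas,
                  double d_min_clamp, double neutral_tol, double mass_floor) {
  const int n = T.nrow() - 1;
  const int S = pos.size();
  const int W = centers.size();
  const int A = alphas.size();
  std::vector<double> w(n + 1);
  std::vector<double> logb(S);
  for (int i = 0; i < S; ++i) logb[i] = std::log(b[cls[i] - 1]);

  NumericVector clr(W, NA_REAL);
  IntegerVector aidx(W, NA_INTEGER);
  if (S == 0) return List::create(_["clr"] = clr, _["alpha_idx"] = aidx);

  const double log_tol = -std::log(neutral_tol);
  // positions are sorted: per (window, alpha) only sites within the
  // neutral-shortcut radius R = -log(tol)/alpha of the center contribute
  // a nonzero log-ratio, so restrict the inner loop to that range
  for (int wi = 0; wi < W; ++wi) {
    double best = R_NegInf;
    int besta = 0;
    for (int ai = 0; ai < A; ++ai) {
      const double alpha = alphas[ai];
      const double R = log_tol / alpha;
      const double *pb = pos.begin(), *pe_ = pos.end();
      const int lo = std::lower_bound(pb, pe_, centers[wi] - R) - pb;
      const int hi = std::upper_bound(pb, pe_, centers[wi] + R) - pb;
      double ll = 0.0;
      for (int i = lo; i < hi; ++i) {
        double d = std::fabs(pos[i] - centers[wi]);
        if (d < d_min_clamp) d = d_min_clamp;
        const double ad = alpha * d;
        if (ad > log_tol) continue;
        const double p = 1.0 - std::exp(-ad);
        binom_weights(n, p, w);
        double Z = 0.0, Pc = 0.0;
        const int c = cls[i] - 1;
        for (int e = 0; e <= n; ++e) {
          Z += w[e] * Tpoly[e];
          Pc += w[e] * Tclass(e, c);
        }
        if (Z < mass_floor) continue;          // fall back to background
        ll += std::log(Pc / Z) - logb[i];
      }
      if (ll > best) { best = ll; besta = ai; }
    }
    clr[wi] = 2.0 * best;
    aidx[wi] = besta + 1;
  }
  return List::create(_["clr"] = clr, _["alpha_idx"] = aidx);
}
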