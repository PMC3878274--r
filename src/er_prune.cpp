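#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for the k-state equal-rates chain, exploiting the
// closed form P(t) = e I + (1-e)/k J with e = exp(-k q t): a matrix-vector
// product collapses to one exponential plus a rescale. Partials are
// renormalized at every edge to avoid underflow; an impossible data set
// returns -Inf.
//
// pa, ch: postorder edge endpoints (1-based node ids), el: edge lengths,
// part0: (n_nodes x k) initial partials (tip indicators, internals 1),
// root: 1-based id of the root node, fitzjohn: root prior switch.
// [[Rcpp::export(name = ".er_prune_cpp")]]
double er_prune_cpp(IntegerVector pa, IntegerVector ch, NumericVector el,
                    double q, int k, NumericMatrix part0, int root,
                    bool fitzjohn) {
  int ne = pa.size();
  int n_nodes = part0.nrow();
  NumericMatrix part(clone(part0));
  double logscale = 0.0;
  for (int i = 0; i < ne; ++i) {
    int c = ch[i] - 1, p = pa[i] - 1;
    double e = std::exp(-k * q * el[i]);
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += part(c, j);
    s /= k;
    double m = 0.0;
    for (int j = 0; j < k; ++j) {
      double msg = e * part(c, j) + (1.0 - e) * s;
      part(p, j) *= msg;          // temporarily unscaled
      if (part(p, j) > m) m = part(p, j);
    }
    if (m <= 0.0 || !R_finite(m)) return R_NegInf;
    for (int j = 0; j < k; ++j) part(p, j) /= m;
    logscale += std::log(m);
  }
  int r = root - 1;
  double lik;
  if (fitzjohn) {
    double s = 0.0, s2 = 0.0;
    for (int j = 0; j < k; ++j) { s += part(r, j); s2 += part(r, j) * part(r, j); }
    if (s <= 0.0) return R_NegInf;
    lik = s2 / s;
  } else {
    lik = 0.0;
    for (int j = 0; j < k; ++j) lik += part(r, j);
    lik /= k;
  }
  if (lik <= 0.0) return R_NegInf;
  (void)n_nodes;
  return std::log(lik) + logscale;
}
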