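#include <Rcpp.h>
#include <cmath>

// One fused Adam update for a parameter block: returns the new parameter
// values and updates the moment buffers, all in a single pass.
// [[Rcpp::export(name = ".adam_update")]]
Rcpp::List adam_update(Rcpp::NumericVector p, Rcpp::NumericVector g,
                       Rcpp::NumericVector m, Rcpp::NumericVector v,
                       double lr, double beta1, double beta2, double eps,
                       double bc1, double bc2) {
  R_xlen_t n = p.size();
  Rcpp::NumericVector pn(n), mn(n), vn(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    mn[i] = mi;
    vn[i] = vi;
    pn[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  pn.attr("dim") = p.attr("dim");
  return Rcpp::List::create(Rcpp::Named("p") = pn, Rcpp::Named("m") = mn,
                            Rcpp::Named("v") = vn);
}
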