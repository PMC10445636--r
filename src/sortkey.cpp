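#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <numeric>

// Neighbor sort key: species, quantized distance and atom index packed into
// one 64-bit integer, S = alpha * 1e15 + floor(r * 1e8) * 1e5 + j.  Field
// widths admit alpha < 9223, r < 92 A and j < 1e5 without overlap; the key
// is computed and compared in true 64-bit arithmetic here because doubles
// lose exactness above 2^53.

static int64_t key_of(int alpha, double r, int j) {
  if (alpha < 0 || alpha >= 9223)
    Rcpp::stop("sort key overflow: species index must be in [0, 9223)");
  if (!(r >= 0.0) || r >= 92.0)
    Rcpp::stop("sort key overflow: distance must be in [0, 92) Angstrom");
  if (j < 0 || j >= 100000)
    Rcpp::stop("sort key overflow: atom index must be in [0, 1e5)");
  int64_t q = (int64_t)std::floor(r * 1e8);
  return (int64_t)alpha * 1000000000000000LL + q * 100000LL + (int64_t)j;
}

// [[Rcpp::export(name = ".sort_key_num")]]
Rcpp::NumericVector sort_key_num(Rcpp::IntegerVector alpha,
                                 Rcpp::NumericVector r,
                                 Rcpp::IntegerVector j) {
  R_xlen_t n = alpha.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (double)key_of(alpha[i], r[i], j[i]);
  return out;
}

// [[Rcpp::export(name = ".sort_key_str")]]
Rcpp::CharacterVector sort_key_str(Rcpp::IntegerVector alpha,
                                   Rcpp::NumericVector r,
                                   Rcpp::IntegerVector j) {
  R_xlen_t n = alpha.size();
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::to_string(key_of(alpha[i], r[i], j[i]));
  return out;
}

// Order (1-based) of the triples by their 64-bit key, ties impossible for
// distinct j within one neighborhood; std::stable_sort keeps determinism.
// [[Rcpp::export(name = ".sort_key_order")]]
Rcpp::IntegerVector sort_key_order(Rcpp::IntegerVector alpha,
                                   Rcpp::NumericVector r,
                                   Rcpp::IntegerVector j) {
  R_xlen_t n = alpha.size();
  std::vector<int64_t> keys(n);
  for (R_xlen_t i = 0; i < n; ++i) keys[i] = key_of(alpha[i], r[i], j[i]);
  std::vector<R_xlen_t> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::stable_sort(idx.begin(), idx.end(),
                   [&keys](R_xlen_t a, R_xlen_t b) { return keys[a] < keys[b]; });
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)idx[i] + 1;
  return out;
}
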