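#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads, transposed direct-form II.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi:  n_sections x 2 initial state (may be all zeros).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  std::vector<double> z1(ns), z2(ns);
  for (int s = 0; s < ns; ++s) { z1[s] = zi(s, 0); z2[s] = zi(s, 1); }
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = y[i];
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double out = b0 * v + z1[s];
      z1[s] = b1 * v - a1 * out + z2[s];
      z2[s] = b2 * v - a2 * out;
      v = out;
    }
    y[i] = v;
  }
  return y;
}
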