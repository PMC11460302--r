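#include <Rcpp.h>
using namespace Rcpp;

// Trapezoid-rule convolution of a uniformly sampled signal with exp(-alpha t):
// y_i = e^{-alpha dt} y_{i-1} + (dt/2)(A_i + e^{-alpha dt} A_{i-1}).
// This is the exact trapezoid quadrature of the convolution integral and the
// hot inner loop of every kinetic model evaluation.
// [[Rcpp::export]]
NumericVector conv_exp_cpp(NumericVector A, double dt, double alpha) {
  R_xlen_t n = A.size();
  NumericVector y(n);
  if (n == 0) return y;
  double d = std::exp(-alpha * dt);
  double h = dt / 2.0;
  y[0] = 0.0;
  for (R_xlen_t i = 1; i < n; ++i)
    y[i] = d * y[i - 1] + h * (A[i] + d * A[i - 1]);
  return y;
}

// Cumulative trapezoid integral on a uniform grid.
// [[Rcpp::export]]
NumericVector cumtrapz_cpp(NumericVector A, double dt) {
  R_xlen_t n = A.size();
  NumericVector y(n);
  if (n == 0) return y;
  double h = dt / 2.0;
  y[0] = 0.0;
  for (R_xlen_t i = 1; i < n; ++i)
    y[i] = y[i - 1] + h * (A[i] + A[i - 1]);
  return y;
}
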