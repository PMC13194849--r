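#include <Rcpp.h>
using namespace Rcpp;

// Convolution y(t) = int_0^t exp(-alpha (t - s)) f(s) ds for f piecewise
// linear on the (possibly non-uniform) grid t. Exact for the interpolant:
// per-interval update y_{i} = e^{-alpha h} y_{i-1} + w0 f_{i-1} + w1 f_i with
//   I1 = int_0^h e^{-alpha(h-s)} ds,  I2 = int_0^h e^{-alpha(h-s)} s ds,
//   w0 = I1 - I2/h, w1 = I2/h.
// Series fallback keeps the weights stable as alpha*h -> 0.
// [[Rcpp::export]]
NumericVector conv_exp_lin(NumericVector t, NumericVector f, double alpha) {
  int n = t.size();
  if (f.size() != n) stop("t and f must have equal length");
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double h = t[i] - t[i - 1];
    if (h <= 0) stop("time grid must be strictly increasing");
    double x = alpha * h;
    double e, I1, I2;
    if (x < 1e-6) {
      e = std::exp(-x);
      I1 = h * (1.0 - x / 2.0 + x * x / 6.0);
      I2 = h * h * (0.5 - x / 3.0 + x * x / 8.0);
    } else {
      e = std::exp(-x);
      I1 = -std::expm1(-x) / alpha;
      I2 = (h - I1) / alpha;
    }
    double w1 = I2 / h;
    double w0 = I1 - w1;
    y[i] = y[i - 1] * e + f[i - 1] * w0 + f[i] * w1;
  }
  return y;
}
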