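#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase FIR smoothing evaluated only at the decimated sample positions.
// h must be symmetric with odd length; edges are handled by replicating the
// boundary samples.
// [[Rcpp::export(name = ".fir_decimate")]]
NumericVector fir_decimate(NumericVector x, NumericVector h, int q) {
  int n = x.size(), nh = h.size(), half = (nh - 1) / 2;
  int n_out = (n + q - 1) / q;
  NumericVector out(n_out);
  for (int k = 0; k < n_out; ++k) {
    int c = k * q;
    double acc = 0.0;
    for (int j = 0; j < nh; ++j) {
      int i = c + j - half;
      if (i < 0) i = 0;
      if (i >= n) i = n - 1;
      acc += h[j] * x[i];
    }
    out[k] = acc;
  }
  return out;
}

// AR(1) recursion with piecewise-constant coefficient and innovation SD.
// e: standard-normal innovations; seg_end: 1-based inclusive end index of
// each segment; phi, sd: per-segment AR coefficient and innovation SD.
// [[Rcpp::export(name = ".ar1_piecewise")]]
NumericVector ar1_piecewise(NumericVector e, IntegerVector seg_end,
                            NumericVector phi, NumericVector sd) {
  int n = e.size();
  NumericVector x(n);
  double last = 0.0;
  int s = 0;
  for (int i = 0; i < n; ++i) {
    while (i >= seg_end[s]) ++s;
    last = phi[s] * last + sd[s] * e[i];
    x[i] = last;
  }
  return x;
}
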