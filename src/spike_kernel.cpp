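#include <Rcpp.h>
using namespace Rcpp;

// Sum of a causal kernel placed at each spike sample index (1-based);
// sparse direct convolution of a spike train with a kernel.
// [[Rcpp::export(name = ".spike_kernel_sum")]]
NumericVector spike_kernel_sum(IntegerVector idx, NumericVector kern, int n) {
  NumericVector out(n);
  const int klen = kern.size();
  for (int s = 0; s < idx.size(); s++) {
    const int i0 = idx[s] - 1;
    const int imax = std::min(n - i0, klen);
    for (int j = 0; j < imax; j++) out[i0 + j] += kern[j];
  }
  return out;
}

// Economy pink-noise shaping filter: sum of three AR(1) processes with
// staggered poles plus a direct term, applied column-wise to white noise.
// [[Rcpp::export(name = ".pink_filter")]]
NumericMatrix pink_filter(NumericMatrix white) {
  const int n = white.nrow(), nc = white.ncol();
  const double p0 = 0.99765, p1 = 0.96300, p2 = 0.57000;
  const double g0 = 0.0990460, g1 = 0.2965164, g2 = 1.0526913, gd = 0.1848;
  NumericMatrix out(n, nc);
  for (int c = 0; c < nc; c++) {
    double b0 = 0, b1 = 0, b2 = 0;
    for (int i = 0; i < n; i++) {
      const double w = white(i, c);
      b0 = p0 * b0 + g0 * w;
      b1 = p1 * b1 + g1 * w;
      b2 = p2 * b2 + g2 * w;
      out(i, c) = b0 + b1 + b2 + gd * w;
    }
  }
  return out;
}
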