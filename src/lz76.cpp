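#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 complexity (exhaustive-history production count) of a symbol
// sequence, via the Kaspar-Schuster scanning procedure. Returns the number of
// words in the exhaustive production parsing; deterministic.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  int c = 1;     // first symbol is always a word
  int l = 1;     // length of history already parsed
  int i = 0;     // start offset of current candidate match within history
  int k = 1;     // current extension length
  int k_max = 1; // longest match seen for current word
  while (l + k <= n) {
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k > n) { c++; break; }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) { // no prefix reproduces the extension: new word
        c++;
        l += k_max;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
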