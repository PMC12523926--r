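#include <Rcpp.h>

// LZ76 exhaustive-history component count of a symbol sequence.
//
// Kaspar & Schuster's formulation of Lempel & Ziv's production complexity:
// scan left to right, extending the current component while it can be copied
// from any earlier starting position (copies may overrun into the component
// itself); when no earlier position reproduces the block, close the
// component. The trailing block counts as a component even if reproducible.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(Rcpp::IntegerVector s) {
  const int n = s.size();
  if (n == 0) Rcpp::stop("empty sequence");
  if (n == 1) return 1;
  int c = 1;        // components parsed so far (first symbol is one)
  int l = 1;        // 0-based start of the current component
  int i = 0;        // candidate copy-source start in the history
  int k = 1;        // current extension length
  int k_max = 1;    // longest extension seen for this component
  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {  // exhausted the history: block is novel
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
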