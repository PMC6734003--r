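#include <Rcpp.h>
using namespace Rcpp;

// Count position pairs (i, j), j - i > min_loop + min_stem, at which a
// perfect reverse-complement stem of length >= min_stem begins, i.e.
// seq[i + t] pairs Watson-Crick with seq[j - t] for t = 0 .. min_stem - 1.
// Encoding: A=0, C=1, G=2, T=3; complement is 3 - code.
// [[Rcpp::export(name = ".stem_pair_count")]]
int stem_pair_count(IntegerVector code, int min_stem, int min_loop) {
  const int n = code.size();
  if (n == 0) return 0;
  long long count = 0;
  const int gap = min_loop + min_stem;
  for (int i = 0; i + gap < n; ++i) {
    for (int j = i + gap + 1; j < n; ++j) {
      bool ok = true;
      for (int t = 0; t < min_stem; ++t) {
        const int a = i + t, b = j - t;
        if (b < 0 || a >= n || code[a] != 3 - code[b]) { ok = false; break; }
      }
      if (ok) ++count;
    }
  }
  if (count > INT_MAX) count = INT_MAX;
  return (int) count;
}
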