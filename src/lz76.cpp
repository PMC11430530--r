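#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv (1976) complexity: number of components in the exhaustive
// production history of a binary sequence. A phrase is extended while the
// candidate s[l..l+k-1] is reproducible from the extended history
// s[1..l+k-2] (occurs as a substring starting before position l); each
// failed extension closes a component, and the trailing (possibly
// reproducible) phrase counts as one. Two-pointer scan after
// Kaspar & Schuster.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector bits) {
  const int n = bits.size();
  if (n == 0) stop("lz76: empty sequence");
  for (int j = 0; j < n; ++j) {
    if (bits[j] == NA_INTEGER || (bits[j] != 0 && bits[j] != 1))
      stop("lz76: non-binary symbol at position %d", j + 1);
  }
  if (n == 1) return 1;

  int c = 1;     // first symbol is always its own component
  int l = 1;     // 0-based start index of the current phrase
  int i = 0;     // 0-based start of the candidate copy source (i < l)
  int k = 1;     // current candidate extension length
  int kmax = 1;  // longest reproducible extension found for this phrase

  while (true) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
      if (l + k > n) {  // reached the end while still reproducible
        ++c;
        break;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {  // no history start point can reproduce the extension
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
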