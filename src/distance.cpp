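#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Restricted Damerau-Levenshtein distance (optimal string alignment):
// unit-cost insertion, deletion, substitution and adjacent transposition,
// with no substring edited more than once. Three rolling rows keep memory
// at O(min-side) per call.
static int dl_dist_one(const std::string& a, const std::string& b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  std::vector<int> prev2(n + 1), prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                          prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, prev2[j - 2] + 1);
      cur[j] = best;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
IntegerVector dl_distance_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  R_xlen_t n = std::max(nx, ny);
  if (nx == 0 || ny == 0) return IntegerVector(0);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i % nx]) || CharacterVector::is_na(y[i % ny])) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string a = as<std::string>(x[i % nx]);
    std::string b = as<std::string>(y[i % ny]);
    out[i] = dl_dist_one(a, b);
  }
  return out;
}
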