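#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Classic O(|a|*|b|) dynamic-programming longest common subsequence on
// pre-split symbol sequences (each element one character; multibyte UTF-8
// is handled by splitting in R with strsplit(x, "")). Symbols are compared
// as CHARSXP pointers: R interns strings in its global cache, so identical
// characters share one SEXP and pointer equality is string equality.
static int lcs_len(const CharacterVector& a, const CharacterVector& b,
                   std::vector<int>& prev, std::vector<int>& cur) {
  const R_xlen_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  prev.assign(m + 1, 0);
  cur.assign(m + 1, 0);
  for (R_xlen_t i = 1; i <= n; ++i) {
    const SEXP ai = a[i - 1];
    for (R_xlen_t j = 1; j <= m; ++j) {
      if (ai == b[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lcs_length_cpp(CharacterVector a, CharacterVector b) {
  std::vector<int> prev, cur;
  return lcs_len(a, b, prev, cur);
}

// Dice-normalised similarity 2L/(|a|+|b|) of one query against a list of
// candidate sequences; the hot loop of the fuzzy concept matcher.
// [[Rcpp::export]]
NumericVector lcs_sim_batch_cpp(CharacterVector a, List b_list) {
  const R_xlen_t k = b_list.size();
  NumericVector out(k);
  const double la = static_cast<double>(a.size());
  std::vector<int> prev, cur;
  for (R_xlen_t i = 0; i < k; ++i) {
    CharacterVector b(b_list[i]);
    const double lb = static_cast<double>(b.size());
    if (la + lb == 0.0) { out[i] = NA_REAL; continue; }
    out[i] = 2.0 * lcs_len(a, b, prev, cur) / (la + lb);
  }
  return out;
}
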