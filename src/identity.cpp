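#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Number of identical aligned residue pairs in an optimal global alignment
// scored match = 1, mismatch = 0, gap = 0. With free gaps and mismatches the
// optimum equals the longest-common-subsequence length, computed here with a
// two-row dynamic programme.
static int alignedIdentity(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    int *p = prev.data(), *c = cur.data();
    for (size_t j = 1; j <= m; ++j) {
      const int diag = p[j - 1] + (ai == b[j - 1] ? 1 : 0);
      const int keep = p[j] > c[j - 1] ? p[j] : c[j - 1];
      c[j] = diag > keep ? diag : keep;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".identityScore")]]
int identityScore(std::string a, std::string b) {
  return alignedIdentity(a, b);
}

// [[Rcpp::export(name = ".identityMatrix")]]
NumericMatrix identityMatrix(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i) {
    S(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double shorter = std::min(s[i].size(), s[j].size());
      const double v = alignedIdentity(s[i], s[j]) / shorter;
      S(i, j) = v;
      S(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return S;
}
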