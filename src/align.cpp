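#include <Rcpp.h>
using namespace Rcpp;

// Per-start-position Hamming mismatch counts of `primer` slid along
// `tmpl` (plus strand, exact character comparison: any ambiguity symbol
// in the template that is not the primer base counts as a mismatch).
// [[Rcpp::export]]
IntegerVector cpp_mm_scan(std::string tmpl, std::string primer) {
  const int n = tmpl.size(), k = primer.size();
  if (k > n) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  for (int s = 0; s <= n - k; ++s) {
    int mm = 0;
    for (int j = 0; j < k; ++j) {
      if (tmpl[s + j] != primer[j]) ++mm;
    }
    out[s] = mm;
  }
  return out;
}

// End-gap-free global alignment (match +1, mismatch 0, gap -1; terminal
// gaps unpenalized). Deterministic: the traceback starts at the best cell
// on the last row/column (last column top-to-bottom, then last row
// left-to-right, strictly-greater updates) and prefers diagonal over up
// over left. Identity = matches / columns over the aligned region
// (terminal overhangs excluded).
// [[Rcpp::export]]
List cpp_align_identity(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int up = S[i - 1][j] - 1;
      int left = S[i][j - 1] - 1;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S[i][j] = best;
    }
  }
  int bi = n, bj = m, bscore = S[n][m];
  for (int i = 1; i <= n; ++i) {
    if (S[i][m] > bscore) { bscore = S[i][m]; bi = i; bj = m; }
  }
  for (int j = 1; j <= m; ++j) {
    if (S[n][j] > bscore) { bscore = S[n][j]; bi = n; bj = j; }
  }
  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    int diag = S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
    if (S[i][j] == diag) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (S[i][j] == S[i - 1][j] - 1) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  double identity = columns > 0 ? (double)matches / columns : 0.0;
  return List::create(_["score"] = bscore, _["matches"] = matches,
                      _["columns"] = columns, _["identity"] = identity);
}
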