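#include <Rcpp.h>
using namespace Rcpp;

// Global (end-to-end) alignment identity between two encoded nucleotide
// sequences. Sequences arrive as integer codes 0..3 = A,C,G,T; 4 = N, which
// never counts as a match (N is scored as a mismatch against everything,
// including another N).
//
// Among all score-optimal alignments the reported alignment is chosen by the
// deterministic lexicographic rule: maximize score, then matches, then
// minimize alignment columns. All three objectives are additive per column,
// so the lexicographic optimum has optimal substructure and a single DP pass
// suffices.

struct Cell {
  double score;
  int matches;
  int columns;
};

static inline bool better(const Cell& a, const Cell& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.columns < b.columns;
}

// [[Rcpp::export]]
NumericVector nw_identity_cpp(IntegerVector a, IntegerVector b,
                              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);

  prev[0] = {0.0, 0, 0};
  for (int j = 1; j <= m; ++j)
    prev[j] = {prev[j - 1].score + gap, 0, j};

  for (int i = 1; i <= n; ++i) {
    cur[0] = {prev[0].score + gap, 0, i};
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool is_match = (ai == b[j - 1]) && ai < 4;
      Cell diag = {prev[j - 1].score + (is_match ? match : mismatch),
                   prev[j - 1].matches + (is_match ? 1 : 0),
                   prev[j - 1].columns + 1};
      Cell up   = {prev[j].score + gap, prev[j].matches, prev[j].columns + 1};
      Cell left = {cur[j - 1].score + gap, cur[j - 1].matches,
                   cur[j - 1].columns + 1};
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }

  const Cell& fin = prev[m];
  double identity = fin.columns > 0
    ? static_cast<double>(fin.matches) / fin.columns : 1.0;
  return NumericVector::create(_["identity"] = identity,
                               _["score"] = fin.score,
                               _["matches"] = fin.matches,
                               _["columns"] = fin.columns);
}
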