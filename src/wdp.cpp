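#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Wraparound dynamic programming against the infinite cyclic repetition of a
// motif (Fischetti-style, as used by tandem repeat finders). The tract is
// aligned globally (every tract base consumed); the motif phase is free at
// both ends, so a perfect tract of length L scores match * L.
//
// State D[i][j]: best score of tract[1..i] with motif column j consumed last.
// Same-row deletion moves (motif column consumed against a gap) wrap across
// the motif origin; with a negative gap penalty a run of deletions never
// spans a full motif period, so two sweeps per row reach the fixed point.

static inline int subscore(char a, char b, int match, int mismatch) {
  // N is treated as mismatching everything, including itself
  return (a == b && a != 'N') ? match : mismatch;
}

static std::vector<int> wdp_row_scores(const std::string& tract,
                                       const std::string& motif,
                                       int match, int mismatch, int gap) {
  const int n = (int) tract.size();
  const int p = (int) motif.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> prev(p, 0), cur(p, NEG), best(n, NEG);
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < p; ++j) {
        int pj = (j == 0) ? p - 1 : j - 1;
        int v = prev[pj] + subscore(tract[i - 1], motif[j], match, mismatch);
        int ins = prev[j] + gap;   // tract base opposite a gap
        int del = cur[pj] + gap;   // motif column opposite a gap (may wrap)
        if (ins > v) v = ins;
        if (del > v) v = del;
        if (cur[j] > v) v = cur[j];
        cur[j] = v;
      }
    }
    int m = NEG;
    for (int j = 0; j < p; ++j) if (cur[j] > m) m = cur[j];
    best[i - 1] = m;
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".wdp_score")]]
int wdp_score(std::string tract, std::string motif,
              int match = 2, int mismatch = -7, int gap = -7) {
  if (motif.empty()) stop("motif must be nonempty");
  if (tract.empty()) stop("tract must be nonempty");
  std::vector<int> best = wdp_row_scores(tract, motif, match, mismatch, gap);
  return best.back();
}

// Scores of every prefix tract[1..i]; used by the brute-force detection
// oracle (one DP pass yields the global score for all candidate tract ends).
// [[Rcpp::export(name = ".wdp_score_ends")]]
IntegerVector wdp_score_ends(std::string tract, std::string motif,
                             int match = 2, int mismatch = -7, int gap = -7) {
  if (motif.empty()) stop("motif must be nonempty");
  if (tract.empty()) stop("tract must be nonempty");
  std::vector<int> best = wdp_row_scores(tract, motif, match, mismatch, gap);
  return IntegerVector(best.begin(), best.end());
}
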