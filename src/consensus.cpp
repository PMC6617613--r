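// Affine-gap semi-global aligner: the locus sequence is aligned end-to-end,
// consensus overhangs at either end are free.  Used to assign each locus
// position a consensus coordinate for profile analysis.
//
// Scoring: match/mismatch per base; a gap of length g costs
// gap_open + g * gap_extend (both passed as negative numbers).
// Deterministic tie-breaks: highest score, then leftmost consensus end,
// and traceback preference M (substitution) > X (locus insertion) >
// Y (consensus deletion).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_align_consensus(std::string locus, std::string cons, int match,
                         int mismatch, int gap_open, int gap_extend) {
  const long n = (long)locus.size();
  const long w = (long)cons.size();
  if (n == 0 || w == 0) stop("empty sequence");
  if ((n + 1) * (w + 1) > 200000000L) stop("alignment problem too large");

  const int NEG = std::numeric_limits<int>::min() / 4;
  // state matrices, (n+1) x (w+1), row-major
  std::vector<int> M((n + 1) * (w + 1), NEG), X((n + 1) * (w + 1), NEG),
      Y((n + 1) * (w + 1), NEG);
  // traceback: previous state per cell (0=M, 1=X, 2=Y, 3=free start)
  std::vector<uint8_t> tbM((n + 1) * (w + 1), 3), tbX((n + 1) * (w + 1), 3),
      tbY((n + 1) * (w + 1), 3);
  auto at = [w](long i, long j) { return i * (w + 1) + j; };

  for (long i = 1; i <= n; i++) {
    for (long j = 0; j <= w; j++) {
      if (j >= 1) {
        // M: locus[i-1] aligned to cons[j-1]
        int s = (locus[i - 1] == cons[j - 1]) ? match : mismatch;
        int best = NEG;
        uint8_t tb = 3;
        if (i == 1) { best = 0; tb = 3; }  // free consensus prefix
        if (M[at(i - 1, j - 1)] > best) { best = M[at(i - 1, j - 1)]; tb = 0; }
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; tb = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; tb = 2; }
        if (best > NEG) { M[at(i, j)] = best + s; tbM[at(i, j)] = tb; }
      }
      // X: locus[i-1] opposite a consensus gap
      {
        int best = NEG;
        uint8_t tb = 3;
        if (i == 1) { best = 0; tb = 3; }  // insertion before consensus start
        if (M[at(i - 1, j)] > NEG && M[at(i - 1, j)] > best) { best = M[at(i - 1, j)]; tb = 0; }
        if (Y[at(i - 1, j)] > NEG && Y[at(i - 1, j)] > best) { best = Y[at(i - 1, j)]; tb = 2; }
        int open_sc = (best > NEG) ? best + gap_open + gap_extend : NEG;
        int ext_sc = (X[at(i - 1, j)] > NEG) ? X[at(i - 1, j)] + gap_extend : NEG;
        if (open_sc >= ext_sc && open_sc > NEG) { X[at(i, j)] = open_sc; tbX[at(i, j)] = tb; }
        else if (ext_sc > NEG) { X[at(i, j)] = ext_sc; tbX[at(i, j)] = 1; }
      }
      // Y: consensus[j-1] opposite a locus gap (internal deletion)
      if (j >= 1) {
        int best = NEG;
        uint8_t tb = 0;
        if (M[at(i, j - 1)] > NEG) { best = M[at(i, j - 1)]; tb = 0; }
        if (X[at(i, j - 1)] > NEG && X[at(i, j - 1)] > best) { best = X[at(i, j - 1)]; tb = 1; }
        int open_sc = (best > NEG) ? best + gap_open + gap_extend : NEG;
        int ext_sc = (Y[at(i, j - 1)] > NEG) ? Y[at(i, j - 1)] + gap_extend : NEG;
        if (open_sc >= ext_sc && open_sc > NEG) { Y[at(i, j)] = open_sc; tbY[at(i, j)] = tb; }
        else if (ext_sc > NEG) { Y[at(i, j)] = ext_sc; tbY[at(i, j)] = 2; }
      }
    }
  }

  // best end: last locus row, any consensus column (free suffix); prefer
  // higher score, then leftmost column, then state M over X
  int best = NEG;
  long bj = -1;
  int bstate = -1;
  for (long j = 0; j <= w; j++) {
    if (M[at(n, j)] > best) { best = M[at(n, j)]; bj = j; bstate = 0; }
    if (X[at(n, j)] > best) { best = X[at(n, j)]; bj = j; bstate = 1; }
  }
  if (bj < 0) stop("no alignment found");

  IntegerVector map(n, NA_INTEGER);
  long i = n, j = bj;
  int state = bstate;
  while (i > 0) {
    uint8_t prev;
    if (state == 0) {
      map[i - 1] = (int)(j - 1);  // 0-based consensus coordinate
      prev = tbM[at(i, j)];
      i--; j--;
    } else if (state == 1) {
      prev = tbX[at(i, j)];  // locus base has no consensus coordinate
      i--;
    } else {
      prev = tbY[at(i, j)];
      j--;
    }
    if (prev == 3) break;
    state = prev;
  }
  return List::create(_["score"] = best, _["map"] = map);
}
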