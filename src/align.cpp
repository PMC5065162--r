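#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, three-state DP.
// Gap cost convention: a gap of length L costs gap_open + (L-1)*gap_extend
// (the first gapped column pays the open penalty, each further column the
// extend penalty). 'N' never scores as a match: any column involving N gets
// the mismatch score and is never counted as an identity.
//
// Determinism: the end cell is the highest-scoring cell, ties broken by
// larger i+j (prefers longer alignments), then smaller j (smaller consensus
// end). Traceback prefers diagonal, then vertical (gap in b), then
// horizontal, which is deterministic and reproducible.

static inline int subst(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  // H: best local score ending at (i,j); E: ending with gap in b (consumes
  // a[i]); F: ending with gap in a (consumes b[j]).
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcur(m + 1, NEG);
  // traceback: 0 stop, 1 diag, 2 up(E), 3 left(F); for E/F: 0 open, 1 extend
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Fcur.assign(m + 1, NEG);
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t k = (size_t)i * (m + 1) + j;
      // E: gap in b (vertical move, consumes a[i-1])
      int e_open = Hprev[j] + gap_open;
      int e_ext = Eprev[j] + gap_extend;
      if (e_ext > e_open) { Ecur[j] = e_ext; tbE[k] = 1; }
      else { Ecur[j] = e_open; tbE[k] = 0; }
      // F: gap in a (horizontal move, consumes b[j-1])
      int f_open = Hcur[j - 1] + gap_open;
      int f_ext = Fcur[j - 1] + gap_extend;
      if (f_ext > f_open) { Fcur[j] = f_ext; tbF[k] = 1; }
      else { Fcur[j] = f_open; tbF[k] = 0; }
      // H
      int diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; unsigned char dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      Hcur[j] = h; tbH[k] = dir;
      if (h > best ||
          (h == best && (i + j > bi + bj || (i + j == bi + bj && j < bj)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  int n_columns = 0, n_matches = 0, n_gap = 0;
  int i = bi, j = bj;
  int a_end = bi, b_end = bj, a_begin = bi, b_begin = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  if (best > 0) {
    while (i > 0 && j > 0) {
      size_t k = (size_t)i * (m + 1) + j;
      if (state == 0) {
        unsigned char dir = tbH[k];
        if (dir == 0) break;
        if (dir == 1) {
          ++n_columns;
          if (a[i - 1] != 'N' && b[j - 1] != 'N' && a[i - 1] == b[j - 1])
            ++n_matches;
          a_begin = i; b_begin = j;
          --i; --j;
        } else if (dir == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) { // E: vertical, consumes a[i-1]
        ++n_columns; ++n_gap;
        a_begin = i;
        unsigned char ext = tbE[k];
        --i;
        state = ext ? 1 : 0;
      } else { // F: horizontal, consumes b[j-1]
        ++n_columns; ++n_gap;
        b_begin = j;
        unsigned char ext = tbF[k];
        --j;
        state = ext ? 2 : 0;
      }
    }
  } else {
    a_begin = a_end = b_begin = b_end = 0;
  }

  return List::create(
    _["score"] = best,
    _["a_begin"] = a_begin, _["a_end"] = a_end,
    _["b_begin"] = b_begin, _["b_end"] = b_end,
    _["n_columns"] = n_columns, _["n_matches"] = n_matches,
    _["n_gap_columns"] = n_gap
  );
}
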