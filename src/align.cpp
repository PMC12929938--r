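#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and deterministic
// tie-breaking: maximize score; among equal scores prefer fewer gap
// positions, then the smallest read start, then the smallest reference
// start. 'N' scores as a mismatch against anything.

struct Cell {
  int score;   // best local score ending at (i, j)
  int gaps;    // gap positions used by that alignment
  int si, sj;  // 0-based start of the alignment (read, ref)
  char move;   // 'd' diag, 'u' up (gap in ref), 'l' left (gap in read), 's' start
};

static inline bool better(int sc1, int g1, int si1, int sj1,
                          int sc2, int g2, int si2, int sj2) {
  if (sc1 != sc2) return sc1 > sc2;
  if (g1 != g2) return g1 < g2;
  if (si1 != si2) return si1 < si2;
  return sj1 < sj2;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(const std::string &read, const std::string &ref,
                  int match, int mismatch, int gap) {
  int n = read.size(), m = ref.size();
  std::vector<Cell> H((n + 1) * (m + 1));
  auto at = [&](int i, int j) -> Cell & { return H[i * (m + 1) + j]; };
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j)
      at(i, j) = {0, 0, i, j, 's'};

  int bi = 0, bj = 0;  // end cell of best alignment
  int bsc = 0, bg = 0, bsi = 0, bsj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char a = read[i - 1], b = ref[j - 1];
      bool isMatch = (a == b) && a != 'N' && b != 'N';
      int sub = isMatch ? match : mismatch;

      Cell best = {0, 0, i, j, 's'};  // start fresh (empty prefix)
      const Cell &d = at(i - 1, j - 1);
      int sc = d.score + sub;
      if (sc >= 0 &&
          better(sc, d.gaps, d.si, d.sj, best.score, best.gaps, best.si, best.sj)) {
        best = {sc, d.gaps, d.si, d.sj, 'd'};
      }
      const Cell &u = at(i - 1, j);  // consume read base, gap in ref
      sc = u.score + gap;
      if (sc >= 0 &&
          better(sc, u.gaps + 1, u.si, u.sj, best.score, best.gaps, best.si, best.sj)) {
        best = {sc, u.gaps + 1, u.si, u.sj, 'u'};
      }
      const Cell &l = at(i, j - 1);  // consume ref base, gap in read
      sc = l.score + gap;
      if (sc >= 0 &&
          better(sc, l.gaps + 1, l.si, l.sj, best.score, best.gaps, best.si, best.sj)) {
        best = {sc, l.gaps + 1, l.si, l.sj, 'l'};
      }
      at(i, j) = best;
      if (better(best.score, best.gaps, best.si, best.sj, bsc, bg, bsi, bsj)) {
        bsc = best.score; bg = best.gaps; bsi = best.si; bsj = best.sj;
        bi = i; bj = j;
      }
    }
  }

  // traceback
  std::vector<int> ri, rj;  // 0-based, NA (-1) for gap
  int nMatch = 0, nMismatch = 0, nGap = 0;
  int i = bi, j = bj;
  while (bsc > 0 && !(i == 0 && j == 0)) {
    Cell &c = at(i, j);
    if (c.move == 's') break;
    if (c.move == 'd') {
      ri.push_back(i - 1); rj.push_back(j - 1);
      char a = read[i - 1], b = ref[j - 1];
      if (a == b && a != 'N') ++nMatch; else ++nMismatch;
      --i; --j;
    } else if (c.move == 'u') {
      ri.push_back(i - 1); rj.push_back(-1);
      ++nGap; --i;
    } else {
      ri.push_back(-1); rj.push_back(j - 1);
      ++nGap; --j;
    }
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(rj.begin(), rj.end());

  int readStart = bsc > 0 ? bsi : 0, readEnd = bsc > 0 ? bi : 0;
  int refStart = bsc > 0 ? bsj : 0, refEnd = bsc > 0 ? bj : 0;
  IntegerVector readIdx(ri.begin(), ri.end()), refIdx(rj.begin(), rj.end());
  for (int k = 0; k < readIdx.size(); ++k) {
    if (readIdx[k] < 0) readIdx[k] = NA_INTEGER;
    if (refIdx[k] < 0) refIdx[k] = NA_INTEGER;
  }
  return List::create(
    _["score"] = bsc,
    _["read_span"] = IntegerVector::create(readStart, readEnd),
    _["ref_span"] = IntegerVector::create(refStart, refEnd),
    _["n_match"] = nMatch, _["n_mismatch"] = nMismatch,
    _["n_gap_positions"] = nGap,
    _["read_idx"] = readIdx, _["ref_idx"] = refIdx);
}
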