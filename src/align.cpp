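// Affine-gap pairwise alignment (Gotoh) with explicit traceback.
// Convention: a gap of length L costs gap_open + L * gap_ext (both >= 0),
// i.e. opening a gap already pays one extension. Sequences arrive as
// 0-based integer codes indexing the substitution matrix.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Traceback {
  std::vector<int> a1, a2;  // residue indices (1-based for R) or NA for gap
  int i_start, j_start;     // 1-based start positions of the aligned block
};

// state: 0 = H (match/mismatch), 1 = E (gap in seq1: consumes seq2),
//        2 = F (gap in seq2: consumes seq1)
static Traceback traceback(const IntegerMatrix& ptrH,
                           const IntegerMatrix& ptrE,
                           const IntegerMatrix& ptrF,
                           int i, int j, int state, bool local) {
  Traceback tb;
  while (i > 0 || j > 0) {
    if (local && state == 0 && ptrH(i, j) == -1) break;  // hit the 0 cell
    if (state == 0) {
      int p = ptrH(i, j);
      if (p == 0) {  // diagonal
        tb.a1.push_back(i); tb.a2.push_back(j);
        --i; --j;
      } else if (p == 1) { state = 1; }
      else if (p == 2) { state = 2; }
      else break;                      // p == -1 at global origin
    } else if (state == 1) {           // gap in seq1, consume seq2[j]
      int p = ptrE(i, j);
      tb.a1.push_back(NA_INTEGER); tb.a2.push_back(j);
      --j;
      state = (p == 1) ? 1 : 0;
    } else {                           // gap in seq2, consume seq1[i]
      int p = ptrF(i, j);
      tb.a1.push_back(i); tb.a2.push_back(NA_INTEGER);
      --i;
      state = (p == 2) ? 2 : 0;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(tb.a1.begin(), tb.a1.end());
  std::reverse(tb.a2.begin(), tb.a2.end());
  tb.i_start = i + 1;
  tb.j_start = j + 1;
  return tb;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(IntegerVector s1, IntegerVector s2, NumericMatrix submat,
               double gap_open, double gap_ext, bool local) {
  const int n = s1.size(), m = s2.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix ptrH(n + 1, m + 1), ptrE(n + 1, m + 1), ptrF(n + 1, m + 1);

  H(0, 0) = 0.0; E(0, 0) = F(0, 0) = NEG_INF;
  ptrH(0, 0) = -1;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = local ? NEG_INF : -(gap_open + j * gap_ext);
    F(0, j) = NEG_INF;
    H(0, j) = local ? 0.0 : E(0, j);
    ptrH(0, j) = local ? -1 : 1;
    ptrE(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = local ? NEG_INF : -(gap_open + i * gap_ext);
    E(i, 0) = NEG_INF;
    H(i, 0) = local ? 0.0 : F(i, 0);
    ptrH(i, 0) = local ? -1 : 2;
    ptrF(i, 0) = 2;
  }

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in seq1 (horizontal)
      double e_open = H(i, j - 1) - gap_open - gap_ext;
      double e_ext = E(i, j - 1) - gap_ext;
      if (e_open >= e_ext) { E(i, j) = e_open; ptrE(i, j) = 0; }
      else { E(i, j) = e_ext; ptrE(i, j) = 1; }
      // F: gap in seq2 (vertical)
      double f_open = H(i - 1, j) - gap_open - gap_ext;
      double f_ext = F(i - 1, j) - gap_ext;
      if (f_open >= f_ext) { F(i, j) = f_open; ptrF(i, j) = 0; }
      else { F(i, j) = f_ext; ptrF(i, j) = 2; }
      // H
      double diag = H(i - 1, j - 1) + submat(s1[i - 1], s2[j - 1]);
      double h = diag; int p = 0;
      if (E(i, j) > h) { h = E(i, j); p = 1; }
      if (F(i, j) > h) { h = F(i, j); p = 2; }
      if (local && h < 0.0) { h = 0.0; p = -1; }
      H(i, j) = h; ptrH(i, j) = p;
      if (local && h > best) best = h;
    }
  }

  int bi = n, bj = m;
  double score;
  if (local) {
    score = best;
    // choose among tied endpoints: longest alignment, then smallest query
    // (seq1) start, then smallest (i, j) for determinism
    long best_len = -1; int best_qstart = n + 2; bi = 0; bj = 0;
    Traceback best_tb;
    int examined = 0;
    const int max_tied = 256;  // deterministic cap (row-major order) so
                               // junk alignments with many tied endpoints
                               // stay cheap; real optima tie rarely
    for (int i = 1; i <= n && examined < max_tied; ++i) {
      for (int j = 1; j <= m && examined < max_tied; ++j) {
        if (H(i, j) == best) {
          ++examined;
          Traceback tb = traceback(ptrH, ptrE, ptrF, i, j, 0, true);
          long len = (long)tb.a1.size();
          if (len > best_len ||
              (len == best_len && tb.i_start < best_qstart)) {
            best_len = len; best_qstart = tb.i_start;
            best_tb = tb; bi = i; bj = j;
          }
        }
      }
    }
    if (best_len < 0) {  // empty optimal alignment (all-negative scores)
      return List::create(_["score"] = 0.0,
                          _["a1"] = IntegerVector(0),
                          _["a2"] = IntegerVector(0),
                          _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                          _["tstart"] = NA_INTEGER, _["tend"] = NA_INTEGER);
    }
    return List::create(_["score"] = score,
                        _["a1"] = wrap(best_tb.a1),
                        _["a2"] = wrap(best_tb.a2),
                        _["qstart"] = best_tb.i_start, _["qend"] = bi,
                        _["tstart"] = best_tb.j_start, _["tend"] = bj);
  }

  score = H(n, m);
  int state = 0;
  if (E(n, m) == score && ptrH(n, m) == 1) state = 0;  // handled inside
  Traceback tb = traceback(ptrH, ptrE, ptrF, n, m, 0, false);
  return List::create(_["score"] = score,
                      _["a1"] = wrap(tb.a1),
                      _["a2"] = wrap(tb.a2),
                      _["qstart"] = n > 0 ? 1 : NA_INTEGER,
                      _["qend"] = n,
                      _["tstart"] = m > 0 ? 1 : NA_INTEGER,
                      _["tend"] = m);
}
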