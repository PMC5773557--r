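#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh three-state DP).
// Gap convention: the first column of a gap run costs `gap_open`, each
// subsequent column costs `gap_extend`. Traceback ties are broken
// diagonal > up (gap in b, consuming a) > left (gap in a, consuming b);
// within a gap state, closing the gap (returning to the match state) is
// preferred on ties. The best cell is the first maximum encountered scanning
// rows then columns, i.e. the smallest end position in a, then in b.
// All scores are multiples of 0.5, so double comparisons are exact.
//
// a_idx / b_idx are 0-based row/column indices into the substitution matrix.
// The returned col_a / col_b strings encode alignment columns: 'M' = residue
// consumed, '-' = gap; residue letters are filled in by the R wrapper.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a_idx, IntegerVector b_idx,
              NumericMatrix submat, double gap_open, double gap_extend) {
  const int n = a_idx.size(), m = b_idx.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + submat(a_idx[i - 1], b_idx[j - 1]);
      double h = 0;
      if (diag > h) h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string al_a, al_b;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (H(i, j) <= 0) break;
      double diag = (i > 0 && j > 0)
        ? H(i - 1, j - 1) + submat(a_idx[i - 1], b_idx[j - 1]) : NEG;
      if (i > 0 && j > 0 && H(i, j) == diag) {
        al_a.push_back('M'); al_b.push_back('M');
        --i; --j;
      } else if (i > 0 && H(i, j) == F(i, j)) {
        state = 2;
      } else if (j > 0 && H(i, j) == E(i, j)) {
        state = 1;
      } else {
        break;
      }
    } else if (state == 2) {  // gap in b, consume a_i
      al_a.push_back('M'); al_b.push_back('-');
      if (F(i, j) == H(i - 1, j) - gap_open) state = 0;
      --i;
    } else {  // state == 1: gap in a, consume b_j
      al_a.push_back('-'); al_b.push_back('M');
      if (E(i, j) == H(i, j - 1) - gap_open) state = 0;
      --j;
    }
  }
  int start_a = i, start_b = j;
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());

  return List::create(_["score"] = best,
                      _["start_a"] = start_a, _["end_a"] = bi,
                      _["start_b"] = start_b, _["end_b"] = bj,
                      _["col_a"] = al_a, _["col_b"] = al_b);
}
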