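#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap local alignment over integer-indexed residue vectors.
// Gap of length g costs gap_open + g * gap_extend (opening charged once,
// extension per gapped position), matching the convention of BLAST-style
// scoring with e.g. BLOSUM62/11/1.
//
// Traceback is deterministic: at every cell ties resolve diagonal > up
// (consume a residue of `a`, gap in `b`) > left, and the highest-scoring
// cell is the first one encountered in row-major order.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_extend;

  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (move left, consume b[j]); F: gap in b (move up, consume a[i])
      E(i, j) = std::max(H(i, j - 1) - open_cost, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - open_cost, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + mat(a[i - 1] - 1, b[j - 1] - 1);
      double h = 0.0;
      if (diag > h) h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state H
  std::vector<int> apos, bpos;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) == 0.0) break;
      double diag = H(i - 1, j - 1) + mat(a[i - 1] - 1, b[j - 1] - 1);
      if (H(i, j) == diag) {
        apos.push_back(i); bpos.push_back(j);
        --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      apos.push_back(i); bpos.push_back(0);
      bool from_h = (F(i, j) == H(i - 1, j) - open_cost);
      --i;
      if (from_h) state = 0;
    } else {
      apos.push_back(0); bpos.push_back(j);
      bool from_h = (E(i, j) == H(i, j - 1) - open_cost);
      --j;
      if (from_h) state = 0;
    }
  }
  std::reverse(apos.begin(), apos.end());
  std::reverse(bpos.begin(), bpos.end());

  return List::create(_["score"] = best,
                      _["a_pos"] = wrap(apos),
                      _["b_pos"] = wrap(bpos));
}
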