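#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh). Profiles are
// 4 x L matrices of A/C/G/T column frequencies (columns may sum to < 1 when
// member rows carry gaps). Column score:
//   match * <fA, fB> + mismatch * (|fA||fB| - <fA,fB>)
// A gap of length g costs gap_open + g * gap_extend.
// Returns the DP score and the merge path (0 = both, 1 = A only, 2 = B only).

// [[Rcpp::export]]
List cpp_align_profiles(NumericMatrix A, NumericMatrix B,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int la = A.ncol(), lb = B.ncol();
  if ((double) (la + 1) * (lb + 1) > 6.4e7)
    stop("alignment problem too large (%d x %d columns)", la, lb);
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> colsumA(la), colsumB(lb);
  for (int i = 0; i < la; ++i) {
    double s = 0; for (int r = 0; r < 4; ++r) s += A(r, i);
    colsumA[i] = s;
  }
  for (int j = 0; j < lb; ++j) {
    double s = 0; for (int r = 0; r < 4; ++r) s += B(r, j);
    colsumB[j] = s;
  }

  const int w = lb + 1;
  std::vector<double> M((la + 1) * (size_t) w, NEG),
                      X((la + 1) * (size_t) w, NEG),
                      Y((la + 1) * (size_t) w, NEG);
  // traceback: which of M/X/Y fed each cell (per matrix)
  std::vector<uint8_t> tm((la + 1) * (size_t) w, 0),
                       tx((la + 1) * (size_t) w, 0),
                       ty((la + 1) * (size_t) w, 0);
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) { X[i * (size_t) w] = -gap_open - gap_extend * i; tx[i * (size_t) w] = 1; }
  for (int j = 1; j <= lb; ++j) { Y[j] = -gap_open - gap_extend * j; ty[j] = 2; }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      size_t c = (size_t) i * w + j, d = (size_t) (i - 1) * w + (j - 1);
      size_t up = (size_t) (i - 1) * w + j, lf = c - 1;
      double dot = 0;
      for (int r = 0; r < 4; ++r) dot += A(r, i - 1) * B(r, j - 1);
      double sc = match * dot + mismatch * (colsumA[i - 1] * colsumB[j - 1] - dot);
      // M: diagonal
      double m0 = M[d], m1 = X[d], m2 = Y[d];
      if (m0 >= m1 && m0 >= m2) { M[c] = m0 + sc; tm[c] = 0; }
      else if (m1 >= m2)        { M[c] = m1 + sc; tm[c] = 1; }
      else                      { M[c] = m2 + sc; tm[c] = 2; }
      // X: consume A column (gap in B)
      double xo = std::max(M[up], Y[up]) - gap_open - gap_extend;
      double xe = X[up] - gap_extend;
      if (xe >= xo) { X[c] = xe; tx[c] = 1; }
      else          { X[c] = xo; tx[c] = (M[up] >= Y[up]) ? 0 : 2; }
      // Y: consume B column (gap in A)
      double yo = std::max(M[lf], X[lf]) - gap_open - gap_extend;
      double ye = Y[lf] - gap_extend;
      if (ye >= yo) { Y[c] = ye; ty[c] = 2; }
      else          { Y[c] = yo; ty[c] = (M[lf] >= X[lf]) ? 0 : 1; }
    }
  }

  size_t endc = (size_t) la * w + lb;
  int state;  // 0 = M, 1 = X, 2 = Y
  double best = M[endc]; state = 0;
  if (X[endc] > best) { best = X[endc]; state = 1; }
  if (Y[endc] > best) { best = Y[endc]; state = 2; }

  std::vector<int> ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    size_t c = (size_t) i * w + j;
    if (state == 0) { ops.push_back(0); state = tm[c]; --i; --j; }
    else if (state == 1) { ops.push_back(1); state = tx[c]; --i; }
    else { ops.push_back(2); state = ty[c]; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = wrap(ops));
}
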