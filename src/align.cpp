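#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Shared conventions for all dynamic-programming kernels:
//   S is the (m x n) position-wise score matrix: S(i,j) = score of aligning
//   residue i of sequence a to residue j of sequence b (or profile column j).
//   Returned paths are op codes read 5'->3': 1 = diagonal (residue vs
//   residue/column), 2 = up (residue of a against a gap), 3 = left (residue
//   of b / profile column against a gap).
//   Tie-breaks are fixed: diagonal > up > left, and among affine states
//   match-state > up-gap-state > left-gap-state, so tracebacks are
//   deterministic.
//
// Matrices are kept as flat row-length-(n+1) buffers indexed [i * (n + 1) + j]
// with raw pointer access; S is column-major as passed from R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global alignment, linear gap cost `gap` per gapped position.
// [[Rcpp::export]]
List nw_core(NumericMatrix S, double gap) {
  const int m = S.nrow(), n = S.ncol();
  const double *s = REAL(S);
  const size_t W = n + 1;
  std::vector<double> F((m + 1) * W);
  std::vector<signed char> ptr((m + 1) * W);
  for (int i = 1; i <= m; ++i) { F[i * W] = -gap * i; ptr[i * W] = 2; }
  for (int j = 1; j <= n; ++j) { F[j] = -gap * j; ptr[j] = 3; }
  for (int i = 1; i <= m; ++i) {
    const double *Sp = s + (i - 1);           // S(i-1, j-1) = Sp[(j-1) * m]
    double *Fr = &F[i * W], *Fp = &F[(i - 1) * W];
    signed char *Pr = &ptr[i * W];
    for (int j = 1; j <= n; ++j) {
      double d = Fp[j - 1] + Sp[(size_t)(j - 1) * m];
      double u = Fp[j] - gap;
      double l = Fr[j - 1] - gap;
      double best = d; int p = 1;
      if (u > best) { best = u; p = 2; }
      if (l > best) { best = l; p = 3; }
      Fr[j] = best; Pr[j] = (signed char) p;
    }
  }
  std::vector<int> ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int p = ptr[i * W + j];
    ops.push_back(p);
    if (p == 1) { --i; --j; } else if (p == 2) { --i; } else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = F[m * W + n], _["path"] = wrap(ops));
}

// Global alignment with affine gaps; a gap of length k costs open + k * ext.
// colw scales the cost (and, via a pre-scaled S, the reward) of consuming
// column j of sequence b -- used for profile alignment where sparsely
// occupied columns are cheap to skip; pass all-ones for plain Gotoh.
// [[Rcpp::export]]
List gotoh_core(NumericMatrix S, double open, double ext, NumericVector colw) {
  const int m = S.nrow(), n = S.ncol();
  const double *s = REAL(S);
  const double *w = REAL(colw);
  const size_t W = n + 1;
  // state matrices: M diag, X up-gap (consumes a), Y left-gap (consumes b);
  // pointer codes give the predecessor state (0 = M, 1 = X, 2 = Y)
  std::vector<double> M((m + 1) * W, NEG_INF), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  std::vector<signed char> pM((m + 1) * W), pX((m + 1) * W), pY((m + 1) * W);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    double fromM = M[(i - 1) * W] - (open + ext);
    double fromX = X[(i - 1) * W] - ext;
    if (fromM >= fromX) { X[i * W] = fromM; pX[i * W] = 0; }
    else { X[i * W] = fromX; pX[i * W] = 1; }
  }
  for (int j = 1; j <= n; ++j) {
    double wj = w[j - 1];
    double fromM = M[j - 1] - (open + ext) * wj;
    double fromY = Y[j - 1] - ext * wj;
    if (fromM >= fromY) { Y[j] = fromM; pY[j] = 0; }
    else { Y[j] = fromY; pY[j] = 2; }
  }
  for (int i = 1; i <= m; ++i) {
    const double *Sp = s + (i - 1);
    double *Mr = &M[i * W], *Xr = &X[i * W], *Yr = &Y[i * W];
    double *Mp = &M[(i - 1) * W], *Xp = &X[(i - 1) * W], *Yp = &Y[(i - 1) * W];
    signed char *pMr = &pM[i * W], *pXr = &pX[i * W], *pYr = &pY[i * W];
    for (int j = 1; j <= n; ++j) {
      double wj = w[j - 1];
      // M from best of M/X/Y at (i-1, j-1); state order M > X > Y on ties
      double best = Mp[j - 1]; int p = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; p = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; p = 2; }
      Mr[j] = best + Sp[(size_t)(j - 1) * m]; pMr[j] = (signed char) p;
      // X: gap in b (vertical); switching from Y opens a new gap
      best = Mp[j] - (open + ext); p = 0;
      if (Xp[j] - ext > best) { best = Xp[j] - ext; p = 1; }
      if (Yp[j] - (open + ext) > best) { best = Yp[j] - (open + ext); p = 2; }
      Xr[j] = best; pXr[j] = (signed char) p;
      // Y: gap in a (horizontal), column-weighted
      best = Mr[j - 1] - (open + ext) * wj; p = 0;
      if (Xr[j - 1] - (open + ext) * wj > best) { best = Xr[j - 1] - (open + ext) * wj; p = 1; }
      if (Yr[j - 1] - ext * wj > best) { best = Yr[j - 1] - ext * wj; p = 2; }
      Yr[j] = best; pYr[j] = (signed char) p;
    }
  }
  double score = M[m * W + n]; int state = 0;
  if (X[m * W + n] > score) { score = X[m * W + n]; state = 1; }
  if (Y[m * W + n] > score) { score = Y[m * W + n]; state = 2; }
  std::vector<int> ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    size_t at = i * W + j;
    if (state == 0) { ops.push_back(1); state = pM[at]; --i; --j; }
    else if (state == 1) { ops.push_back(2); state = pX[at]; --i; }
    else { ops.push_back(3); state = pY[at]; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["path"] = wrap(ops));
}

// Local alignment with affine gaps (linear when open = 0). Returns the
// best-scoring local path and its 1-based aligned spans (end exclusive on
// the R side); an all-negative S yields score 0 and an empty path.
// [[Rcpp::export]]
List sw_core(NumericMatrix S, double open, double ext) {
  const int m = S.nrow(), n = S.ncol();
  const double *s = REAL(S);
  const size_t W = n + 1;
  std::vector<double> H((m + 1) * W, 0.0), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  // pH codes: 0 local start, 1 diag-from-H, 2 from X, 3 from Y;
  // pX/pY: 0 opened from H, 1 extended
  std::vector<signed char> pH((m + 1) * W), pX((m + 1) * W), pY((m + 1) * W);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const double *Sp = s + (i - 1);
    double *Hr = &H[i * W], *Hp = &H[(i - 1) * W];
    double *Xr = &X[i * W], *Xp = &X[(i - 1) * W], *Yr = &Y[i * W];
    signed char *pHr = &pH[i * W], *pXr = &pX[i * W], *pYr = &pY[i * W];
    for (int j = 1; j <= n; ++j) {
      double x = Hp[j] - (open + ext);
      if (Xp[j] - ext > x) { x = Xp[j] - ext; pXr[j] = 1; } else { pXr[j] = 0; }
      Xr[j] = x;
      double y = Hr[j - 1] - (open + ext);
      if (Yr[j - 1] - ext > y) { y = Yr[j - 1] - ext; pYr[j] = 1; } else { pYr[j] = 0; }
      Yr[j] = y;
      double hv = Hp[j - 1] + Sp[(size_t)(j - 1) * m]; int p = 1;
      if (x > hv) { hv = x; p = 2; }
      if (y > hv) { hv = y; p = 3; }
      if (hv <= 0.0) { hv = 0.0; p = 0; }
      Hr[j] = hv; pHr[j] = (signed char) p;
      if (hv > best) { best = hv; bi = i; bj = j; }
    }
  }
  std::vector<int> ops;
  int i = bi, j = bj, state = 0;  // 0 = H
  while (i > 0 && j > 0) {
    size_t at = i * W + j;
    if (state == 0) {
      int p = pH[at];
      if (p == 0) break;
      if (p == 1) { ops.push_back(1); --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(2); int p = pX[at]; --i; if (p == 0) state = 0;
    } else {
      ops.push_back(3); int p = pY[at]; --j; if (p == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["path"] = wrap(ops),
                      _["start_a"] = i + 1, _["end_a"] = bi,
                      _["start_b"] = j + 1, _["end_b"] = bj);
}

// Longest common subsequence; a and b are integer-coded. The returned path
// spans both full sequences; diagonal ops occur only at matched positions.
// [[Rcpp::export]]
List lcs_core(IntegerVector a, IntegerVector b) {
  const int m = a.size(), n = b.size();
  const size_t W = n + 1;
  std::vector<int> L((m + 1) * W, 0);
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      if (a[i - 1] == b[j - 1]) L[i * W + j] = L[(i - 1) * W + j - 1] + 1;
      else L[i * W + j] = std::max(L[(i - 1) * W + j], L[i * W + j - 1]);
    }
  std::vector<int> ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && a[i - 1] == b[j - 1] &&
        L[i * W + j] == L[(i - 1) * W + j - 1] + 1) {
      ops.push_back(1); --i; --j;
    } else if (i > 0 && L[i * W + j] == L[(i - 1) * W + j]) {
      ops.push_back(2); --i;
    } else {
      ops.push_back(3); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = (double) L[m * W + n], _["path"] = wrap(ops));
}
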