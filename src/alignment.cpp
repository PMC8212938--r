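#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed column-score matrix.
// A gap of length L costs gap_open + (L - 1) * gap_extend (both negative).
// Traceback ties are resolved diagonal > up (consume row) > left (consume col),
// and on equal state scores M > X > Y, so the path is fully deterministic.
//
// Working on a score matrix (rather than sequences) lets the same kernel drive
// sequence-sequence and profile-profile alignment.
//
// Returns list(score, moves) with moves coded 1 = diagonal, 2 = up, 3 = left.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List nw_affine_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) stop("nw_affine_cpp requires non-empty score matrix");
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  // traceback: predecessor state 0 = M, 1 = X, 2 = Y
  std::vector<signed char> tM((n + 1) * w, -1), tX((n + 1) * w, -1),
      tY((n + 1) * w, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = gap_open + (i - 1) * gap_extend;
    tX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * w + j, d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
                l = i * w + (j - 1);
      // M: consume both
      double a = M[d], b = X[d], c = Y[d];
      if (a >= b && a >= c) { M[ij] = S(i - 1, j - 1) + a; tM[ij] = 0; }
      else if (b >= c)      { M[ij] = S(i - 1, j - 1) + b; tM[ij] = 1; }
      else                  { M[ij] = S(i - 1, j - 1) + c; tM[ij] = 2; }
      // X: consume row i (gap in the column sequence), "up"
      a = M[u] + gap_open; b = X[u] + gap_extend; c = Y[u] + gap_open;
      if (a >= b && a >= c) { X[ij] = a; tX[ij] = 0; }
      else if (b >= c)      { X[ij] = b; tX[ij] = 1; }
      else                  { X[ij] = c; tX[ij] = 2; }
      // Y: consume column j, "left"
      a = M[l] + gap_open; b = X[l] + gap_open; c = Y[l] + gap_extend;
      if (a >= b && a >= c) { Y[ij] = a; tY[ij] = 0; }
      else if (b >= c)      { Y[ij] = b; tY[ij] = 1; }
      else                  { Y[ij] = c; tY[ij] = 2; }
    }
  }

  const int endi = n * w + m;
  int state;
  double score;
  if (M[endi] >= X[endi] && M[endi] >= Y[endi]) { state = 0; score = M[endi]; }
  else if (X[endi] >= Y[endi])                  { state = 1; score = X[endi]; }
  else                                          { state = 2; score = Y[endi]; }

  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * w + j;
    if (state == 0)      { moves.push_back(1); state = tM[ij]; --i; --j; }
    else if (state == 1) { moves.push_back(2); state = tX[ij]; --i; }
    else                 { moves.push_back(3); state = tY[ij]; --j; }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}

// Exhaustive enumeration of every global alignment (lattice path with an
// affine-gap memory of the previous move). Exponential; used only as an
// independent oracle on short sequences.
static double enum_rec(int i, int j, int last, const NumericMatrix& S,
                       double go, double ge) {
  const int n = S.nrow(), m = S.ncol();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double v = S(i, j) + enum_rec(i + 1, j + 1, 0, S, go, ge);
    if (v > best) best = v;
  }
  if (i < n) {
    double v = (last == 1 ? ge : go) + enum_rec(i + 1, j, 1, S, go, ge);
    if (v > best) best = v;
  }
  if (j < m) {
    double v = (last == 2 ? ge : go) + enum_rec(i, j + 1, 2, S, go, ge);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double enum_align_score_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  if (S.nrow() > 10 || S.ncol() > 10)
    stop("enumeration oracle is limited to sequences of length <= 10");
  return enum_rec(0, 0, 0, S, gap_open, gap_extend);
}

// Pairwise-deletion distances from an integer-coded alignment matrix
// (rows = sequences, 0 = gap). Returns mismatch counts and comparable-column
// counts; the R side turns these into p or Poisson distances.
// [[Rcpp::export]]
List aln_pdist_cpp(IntegerMatrix A) {
  const int n = A.nrow(), L = A.ncol();
  IntegerMatrix comp(n, n), mism(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int c = 0, mm = 0;
      for (int l = 0; l < L; ++l) {
        const int a = A(i, l), b = A(j, l);
        if (a > 0 && b > 0) {
          ++c;
          if (a != b) ++mm;
        }
      }
      comp(i, j) = comp(j, i) = c;
      mism(i, j) = mism(j, i) = mm;
    }
  }
  return List::create(_["comparable"] = comp, _["mismatches"] = mism);
}

// Column residue frequencies of an integer-coded alignment (codes 1..K,
// 0 = gap). Rows of the result are columns; gaps contribute no mass but do
// count in the denominator, so profile dot products equal mean-of-pairs
// substitution scores with gap pairs scored 0.
// [[Rcpp::export]]
NumericMatrix profile_freq_cpp(IntegerMatrix A, int K) {
  const int n = A.nrow(), L = A.ncol();
  NumericMatrix F(L, K);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      const int a = A(i, l);
      if (a > 0) F(l, a - 1) += 1.0;
    }
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k) F(l, k) /= n;
  return F;
}
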