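#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over integer-coded
// residues with an arbitrary substitution matrix.  A gap run of length k
// scores gap_open + (k - 1) * gap_extend (the opening cost covers the first
// gapped residue).  States: M = match/mismatch, X = gap in b (consumes a,
// "up"), Y = gap in a (consumes b, "left").  Tie-breaking on traceback
// prefers diagonal over up over left, which the state preference M > X > Y
// encodes both at cell level and at state-predecessor level.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  // DP matrices, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: predecessor state per cell/state; 0=M,1=X,2=Y,3=start/stop
  std::vector<unsigned char> tM((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tX((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tY((n + 1) * (m + 1), 3);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
      tX[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[idx(0, j)] = gap_open + (j - 1) * gap_extend;
      tY[idx(0, j)] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[idx(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) M[idx(0, j)] = 0.0;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = mat(a[i - 1] - 1, b[j - 1] - 1);
      // M: consume a[i], b[j]
      {
        double vM = M[idx(i - 1, j - 1)], vX = X[idx(i - 1, j - 1)],
               vY = Y[idx(i - 1, j - 1)];
        double v = vM; unsigned char t = 0;
        if (vX > v) { v = vX; t = 1; }
        if (vY > v) { v = vY; t = 2; }
        v += s;
        if (local && v <= 0.0) { v = 0.0; t = 3; }
        if (v > NEG_INF || local) { M[idx(i, j)] = v; tM[idx(i, j)] = t; }
        if (local && v > best) { best = v; best_i = i; best_j = j; }
      }
      // X: gap in b (consume a[i])
      {
        double vM = M[idx(i - 1, j)] + gap_open;
        double vX = X[idx(i - 1, j)] + gap_extend;
        double vY = Y[idx(i - 1, j)] + gap_open;
        double v = vM; unsigned char t = 0;
        if (vX > v) { v = vX; t = 1; }
        if (vY > v) { v = vY; t = 2; }
        X[idx(i, j)] = v; tX[idx(i, j)] = t;
      }
      // Y: gap in a (consume b[j])
      {
        double vM = M[idx(i, j - 1)] + gap_open;
        double vX = X[idx(i, j - 1)] + gap_open;
        double vY = Y[idx(i, j - 1)] + gap_extend;
        double v = vM; unsigned char t = 0;
        if (vX > v) { v = vX; t = 1; }
        if (vY > v) { v = vY; t = 2; }
        Y[idx(i, j)] = v; tY[idx(i, j)] = t;
      }
    }
  }

  double score;
  int i, j, state;
  if (local) {
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0, _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
    score = best; i = best_i; j = best_j; state = 0;
  } else {
    const double vM = M[idx(n, m)], vX = X[idx(n, m)], vY = Y[idx(n, m)];
    state = 0; score = vM;
    if (vX > score) { score = vX; state = 1; }
    if (vY > score) { score = vY; state = 2; }
    i = n; j = m;
  }

  // traceback; emit aligned index vectors (0 = gap)
  std::vector<int> ai, bi;
  int a_end = local ? i : n, b_end = local ? j : m;
  while (i > 0 || j > 0) {
    if (local && state == 0 && M[idx(i, j)] == 0.0 && tM[idx(i, j)] == 3)
      break;
    unsigned char t;
    if (state == 0) {
      if (i == 0 && j == 0) break;
      t = tM[idx(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      if (local && t == 3) break;
    } else if (state == 1) {
      t = tX[idx(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
    } else {
      t = tY[idx(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
    }
    state = t;
    if (local && state == 3) break;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  int a_start = 0, b_start = 0;
  for (size_t k = 0; k < ai.size(); ++k)
    if (ai[k] > 0) { a_start = ai[k]; break; }
  for (size_t k = 0; k < bi.size(); ++k)
    if (bi[k] > 0) { b_start = bi[k]; break; }
  if (!local) { a_start = n > 0 ? 1 : 0; b_start = m > 0 ? 1 : 0; }

  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()),
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}
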