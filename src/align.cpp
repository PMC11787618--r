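#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over integer-encoded
// sequences (1-based indices into the substitution matrix; the encoding is
// done in R). Penalties are positive: a gap of length L costs
// gap_open + L * gap_extend, i.e. the first gap residue costs
// gap_open + gap_extend and each further residue gap_extend.
//
// Traceback is deterministic: move preference diagonal > up (gap in b) >
// left (gap in a); for local alignments the end cell is the maximal-scoring
// cell with the lexicographically smallest (end_i, end_j).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct DP {
  int n, m;
  std::vector<double> M, X, Y; // X: gap in b (vertical/up), Y: gap in a (left)
  DP(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG_INF),
    X((n_ + 1) * (m_ + 1), NEG_INF),
    Y((n_ + 1) * (m_ + 1), NEG_INF) {}
  inline int at(int i, int j) const { return i * (m + 1) + j; }
};

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend,
                     bool local, bool end_gap_free) {
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_extend; // cost of first gap residue
  DP dp(n, m);

  dp.M[dp.at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    dp.X[dp.at(i, 0)] = local ? NEG_INF
                              : (end_gap_free ? 0.0 : -(gap_open + gap_extend * i));
  for (int j = 1; j <= m; ++j)
    dp.Y[dp.at(0, j)] = local ? NEG_INF
                              : (end_gap_free ? 0.0 : -(gap_open + gap_extend * j));
  if (local)
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j)
        if (i == 0 || j == 0) dp.M[dp.at(i, j)] = 0.0;

  double best = 0.0; int bi = -1, bj = -1; // local end cell
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = dp.at(i, j), d = dp.at(i - 1, j - 1),
                u = dp.at(i - 1, j), l = dp.at(i, j - 1);
      double prev = dp.M[d];
      if (dp.X[d] > prev) prev = dp.X[d];
      if (dp.Y[d] > prev) prev = dp.Y[d];
      if (local && prev < 0.0) prev = 0.0;
      dp.M[c] = (prev == NEG_INF) ? NEG_INF
                                  : prev + S(a[i - 1] - 1, b[j - 1] - 1);
      double xo = (dp.M[u] == NEG_INF) ? NEG_INF : dp.M[u] - gi;
      double xe = (dp.X[u] == NEG_INF) ? NEG_INF : dp.X[u] - gap_extend;
      dp.X[c] = xo >= xe ? xo : xe;
      double yo = (dp.M[l] == NEG_INF) ? NEG_INF : dp.M[l] - gi;
      double ye = (dp.Y[l] == NEG_INF) ? NEG_INF : dp.Y[l] - gap_extend;
      dp.Y[c] = yo >= ye ? yo : ye;
      if (local && dp.M[c] > best) { best = dp.M[c]; bi = i; bj = j; }
    }
  }

  std::vector<int> ali_a, ali_b; // 0 = gap
  double score;
  int i, j, a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  char state;

  if (local) {
    score = best;
    if (bi < 0) { // no positive-scoring cell: empty alignment, SW floor
      return List::create(_["score"] = 0.0,
                          _["ali_a"] = IntegerVector(0),
                          _["ali_b"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
    i = bi; j = bj; a_end = bi; b_end = bj; state = 'M';
    while (true) {
      if (state == 'M') {
        ali_a.push_back(a[i - 1]); ali_b.push_back(b[j - 1]);
        const int d = dp.at(i - 1, j - 1);
        double prev = dp.M[dp.at(i, j)] - S(a[i - 1] - 1, b[j - 1] - 1);
        --i; --j;
        if (prev <= 1e-9) break; // predecessor was the 0 floor: start here
        if (std::abs(dp.M[d] - prev) < 1e-9) state = 'M';
        else if (std::abs(dp.X[d] - prev) < 1e-9) state = 'X';
        else state = 'Y';
        if (i == 0 || j == 0) break;
      } else if (state == 'X') {
        ali_a.push_back(a[i - 1]); ali_b.push_back(0);
        const int u = dp.at(i - 1, j);
        double cur = dp.X[dp.at(i, j)];
        --i;
        if (std::abs(dp.M[u] - gi - cur) < 1e-9) state = 'M';
        else state = 'X';
      } else {
        ali_a.push_back(0); ali_b.push_back(b[j - 1]);
        const int l = dp.at(i, j - 1);
        double cur = dp.Y[dp.at(i, j)];
        --j;
        if (std::abs(dp.M[l] - gi - cur) < 1e-9) state = 'M';
        else state = 'Y';
      }
    }
    a_start = i + 1; b_start = j + 1;
  } else {
    const int c = dp.at(n, m);
    double endM = dp.M[c], endX = dp.X[c], endY = dp.Y[c];
    if (end_gap_free) {
      // free end gaps: best over last row and column, then pad
      double bestv = NEG_INF; int ei = n, ej = m;
      for (int ii = 0; ii <= n; ++ii) {
        double v = std::max(dp.M[dp.at(ii, m)], std::max(dp.X[dp.at(ii, m)], dp.Y[dp.at(ii, m)]));
        if (v > bestv) { bestv = v; ei = ii; ej = m; }
      }
      for (int jj = 0; jj <= m; ++jj) {
        double v = std::max(dp.M[dp.at(n, jj)], std::max(dp.X[dp.at(n, jj)], dp.Y[dp.at(n, jj)]));
        if (v > bestv) { bestv = v; ei = n; ej = jj; }
      }
      score = bestv;
      for (int ii = n; ii > ei; --ii) { ali_a.push_back(a[ii - 1]); ali_b.push_back(0); }
      for (int jj = m; jj > ej; --jj) { ali_a.push_back(0); ali_b.push_back(b[jj - 1]); }
      i = ei; j = ej;
      const int cc = dp.at(i, j);
      if (dp.M[cc] >= dp.X[cc] && dp.M[cc] >= dp.Y[cc]) state = 'M';
      else if (dp.X[cc] >= dp.Y[cc]) state = 'X';
      else state = 'Y';
    } else {
      score = std::max(endM, std::max(endX, endY));
      i = n; j = m;
      if (endM >= endX && endM >= endY) state = 'M';
      else if (endX >= endY) state = 'X';
      else state = 'Y';
    }
    while (i > 0 || j > 0) {
      if (i == 0) { ali_a.push_back(0); ali_b.push_back(b[j - 1]); --j; continue; }
      if (j == 0) { ali_a.push_back(a[i - 1]); ali_b.push_back(0); --i; continue; }
      if (state == 'M') {
        ali_a.push_back(a[i - 1]); ali_b.push_back(b[j - 1]);
        const int d = dp.at(i - 1, j - 1);
        double prev = dp.M[dp.at(i, j)] - S(a[i - 1] - 1, b[j - 1] - 1);
        --i; --j;
        if (std::abs(dp.M[d] - prev) < 1e-9) state = 'M';
        else if (std::abs(dp.X[d] - prev) < 1e-9) state = 'X';
        else state = 'Y';
      } else if (state == 'X') {
        ali_a.push_back(a[i - 1]); ali_b.push_back(0);
        const int u = dp.at(i - 1, j);
        double cur = dp.X[dp.at(i, j)];
        --i;
        if ((end_gap_free && i == 0) || std::abs(dp.M[u] - gi - cur) < 1e-9) state = 'M';
        else state = 'X';
      } else {
        ali_a.push_back(0); ali_b.push_back(b[j - 1]);
        const int l = dp.at(i, j - 1);
        double cur = dp.Y[dp.at(i, j)];
        --j;
        if ((end_gap_free && j == 0) || std::abs(dp.M[l] - gi - cur) < 1e-9) state = 'M';
        else state = 'Y';
      }
    }
    a_start = n > 0 ? 1 : 0; a_end = n; b_start = m > 0 ? 1 : 0; b_end = m;
  }

  std::reverse(ali_a.begin(), ali_a.end());
  std::reverse(ali_b.begin(), ali_b.end());
  return List::create(_["score"] = score,
                      _["ali_a"] = wrap(ali_a), _["ali_b"] = wrap(ali_b),
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Score-only Smith-Waterman against many subjects (rolling rows); the fast
// path of the reciprocal-best-hit search.
// [[Rcpp::export(name = ".sw_score_multi_cpp")]]
NumericVector sw_score_multi_cpp(IntegerVector a, List bs, NumericMatrix S,
                                 double gap_open, double gap_extend) {
  const int n = a.size(), nb = bs.size();
  const double gi = gap_open + gap_extend;
  NumericVector out(nb);
  for (int k = 0; k < nb; ++k) {
    IntegerVector b = bs[k];
    const int m = b.size();
    std::vector<double> M0(m + 1, 0.0), X0(m + 1, NEG_INF), Y0(m + 1, NEG_INF);
    std::vector<double> M1(m + 1), X1(m + 1), Y1(m + 1);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      M1[0] = 0.0; X1[0] = NEG_INF; Y1[0] = NEG_INF;
      const double* srow = &S(a[i - 1] - 1, 0);
      const int srn = S.nrow();
      for (int j = 1; j <= m; ++j) {
        double prev = M0[j - 1];
        if (X0[j - 1] > prev) prev = X0[j - 1];
        if (Y0[j - 1] > prev) prev = Y0[j - 1];
        if (prev < 0.0) prev = 0.0;
        M1[j] = prev + srow[(b[j - 1] - 1) * srn];
        double xo = M0[j] - gi, xe = X0[j] - gap_extend;
        X1[j] = xo >= xe ? xo : xe;
        double yo = M1[j - 1] - gi, ye = Y1[j - 1] - gap_extend;
        Y1[j] = yo >= ye ? yo : ye;
        if (M1[j] > best) best = M1[j];
      }
      std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }
    out[k] = best;
  }
  return out;
}
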