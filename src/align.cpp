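#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap alignment kernels.  Sequences arrive as 1-based integer codes
// into the rows/columns of the substitution matrix S.  Gap costs follow the
// d/e convention: the first residue of a gap costs gap_open, every further
// residue gap_extend (so gap_open == gap_extend is a linear penalty).

static const double NEG_INF = -1e30;

// ---------------------------------------------------------------- local ----

// Smith-Waterman / Gotoh with full traceback.  Deterministic tie-breaks:
// best cell = first strict maximum in (i, j) scan order; traceback prefers
// diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List sw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // full matrices: desk scale (<= ~2000 aa) keeps this cheap
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, 0.0)),
      X(n + 1, std::vector<double>(m + 1, NEG_INF)),
      Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = M[i - 1][j - 1];
      if (X[i - 1][j - 1] > diag) diag = X[i - 1][j - 1];
      if (Y[i - 1][j - 1] > diag) diag = Y[i - 1][j - 1];
      if (diag < 0.0) diag = 0.0;
      M[i][j] = diag + S(a[i - 1] - 1, b[j - 1] - 1);
      double xo = M[i - 1][j] - gap_open, xe = X[i - 1][j] - gap_extend;
      X[i][j] = xo >= xe ? xo : xe;
      double yo = M[i][j - 1] - gap_open, ye = Y[i][j - 1] - gap_extend;
      Y[i][j] = yo >= ye ? yo : ye;
      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) in state M until the running score hits 0
  int i = bi, j = bj, state = 0; // 0 = M, 1 = X (up), 2 = Y (left)
  int n_ident = 0, aln_len = 0;
  int a_end = bi, b_end = bj, a_start = bi + 1, b_start = bj + 1;
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0, _["n_ident"] = 0,
                        _["aln_len"] = 0);
  }
  while (i > 0 && j > 0) {
    if (state == 0) {
      double here = M[i][j];
      double prev = here - S(a[i - 1] - 1, b[j - 1] - 1);
      ++aln_len;
      if (a[i - 1] == b[j - 1]) ++n_ident;
      a_start = i; b_start = j;
      --i; --j;
      if (prev <= 1e-9) break; // local alignment start
      // prefer diagonal, then up, then left
      if (std::abs(M[i][j] - prev) < 1e-9) state = 0;
      else if (std::abs(X[i][j] - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in b, consume a[i]
      double here = X[i][j];
      ++aln_len;
      --i;
      if (std::abs(M[i][j] - gap_open - here) < 1e-9 &&
          M[i][j] - gap_open >= X[i][j] - gap_extend) state = 0;
      else state = 1;
    } else { // gap in a, consume b[j]
      double here = Y[i][j];
      ++aln_len;
      --j;
      if (std::abs(M[i][j] - gap_open - here) < 1e-9 &&
          M[i][j] - gap_open >= Y[i][j] - gap_extend) state = 0;
      else state = 2;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end, _["n_ident"] = n_ident,
                      _["aln_len"] = aln_len);
}

// Score-only SW for one pair; raw-pointer rolling rows, O(m) memory.
// `Sflat` is the substitution matrix in row-major order (na x na),
// sequences are 0-based codes.
static double sw_score_one(const std::vector<int>& a,
                           const std::vector<int>& b,
                           const double* Sflat, int na,
                           double go, double ge,
                           std::vector<double>& Mp, std::vector<double>& Xp,
                           std::vector<double>& Yp, std::vector<double>& Mc,
                           std::vector<double>& Xc, std::vector<double>& Yc) {
  int n = (int)a.size(), m = (int)b.size();
  Mp.assign(m + 1, 0.0); Xp.assign(m + 1, NEG_INF); Yp.assign(m + 1, NEG_INF);
  Mc.assign(m + 1, 0.0); Xc.assign(m + 1, NEG_INF); Yc.assign(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const double* Srow = Sflat + (size_t)a[i - 1] * na;
    Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double diag = Mp[j - 1];
      if (Xp[j - 1] > diag) diag = Xp[j - 1];
      if (Yp[j - 1] > diag) diag = Yp[j - 1];
      if (diag < 0.0) diag = 0.0;
      double mval = diag + Srow[b[j - 1]];
      double xo = Mp[j] - go, xe = Xp[j] - ge;
      double yo = Mc[j - 1] - go, ye = Yc[j - 1] - ge;
      Mc[j] = mval;
      Xc[j] = xo >= xe ? xo : xe;
      Yc[j] = yo >= ye ? yo : ye;
      if (mval > best) best = mval;
    }
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
  }
  return best;
}

// All-vs-all SW scores for a list of integer-coded sequences.
// Returns a symmetric numeric matrix (diagonal = self score).
// [[Rcpp::export]]
NumericMatrix sw_scores_block_cpp(List seqs, NumericMatrix S,
                                  double gap_open, double gap_extend) {
  int n = seqs.size();
  int na = S.nrow();
  // flatten S row-major for cache-friendly row lookups
  std::vector<double> Sflat((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) Sflat[(size_t)i * na + j] = S(i, j);
  std::vector<std::vector<int> > sv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    sv[i].resize(s.size());
    for (int k = 0; k < s.size(); ++k) sv[i][k] = s[k] - 1;
  }
  NumericMatrix out(n, n);
  std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = sw_score_one(sv[i], sv[j], Sflat.data(), na, gap_open,
                              gap_extend, Mp, Xp, Yp, Mc, Xc, Yc);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// SW scores for an explicit list of sequence pairs (1-based indices).
// [[Rcpp::export]]
NumericVector sw_scores_pairs_cpp(List seqs, IntegerVector pi,
                                  IntegerVector pj, NumericMatrix S,
                                  double gap_open, double gap_extend) {
  int n = seqs.size(), na = S.nrow();
  std::vector<double> Sflat((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) Sflat[(size_t)i * na + j] = S(i, j);
  std::vector<std::vector<int> > sv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    sv[i].resize(s.size());
    for (int t = 0; t < s.size(); ++t) sv[i][t] = s[t] - 1;
  }
  int m = pi.size();
  NumericVector out(m);
  std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
  for (int r = 0; r < m; ++r) {
    out[r] = sw_score_one(sv[pi[r] - 1], sv[pj[r] - 1], Sflat.data(), na,
                          gap_open, gap_extend, Mp, Xp, Yp, Mc, Xc, Yc);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// --------------------------------------------------------------- global ----

// Needleman-Wunsch / Gotoh global alignment with traceback.  Returns the
// aligned sequences as integer vectors with 0 marking a gap.
// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG_INF)),
      X(n + 1, std::vector<double>(m + 1, NEG_INF)),
      Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = -gap_open - (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = M[i - 1][j - 1];
      if (X[i - 1][j - 1] > diag) diag = X[i - 1][j - 1];
      if (Y[i - 1][j - 1] > diag) diag = Y[i - 1][j - 1];
      M[i][j] = diag + S(a[i - 1] - 1, b[j - 1] - 1);
      double xo = std::max(M[i - 1][j], Y[i - 1][j]) - gap_open;
      double xe = X[i - 1][j] - gap_extend;
      X[i][j] = xo >= xe ? xo : xe;
      double yo = std::max(M[i][j - 1], X[i][j - 1]) - gap_open;
      double ye = Y[i][j - 1] - gap_extend;
      Y[i][j] = yo >= ye ? yo : ye;
    }
  }
  double score = M[n][m];
  int state = 0;
  if (X[n][m] > score) { score = X[n][m]; state = 1; }
  if (Y[n][m] > score) { score = Y[n][m]; state = 2; }
  // traceback (prefer M, then X, then Y on ties)
  std::vector<int> ra, rb;
  int i = n, j = m;
  int n_ident = 0;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++n_ident;
      double prev = M[i][j] - S(a[i - 1] - 1, b[j - 1] - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - prev) < 1e-9) state = 0;
      else if (std::abs(X[i][j] - prev) < 1e-9) state = 1;
      else state = 2;
    } else if ((state == 1 && i > 0) || (state == 0 && j == 0) ||
               (state == 2 && j == 0)) {
      double here = (state == 1) ? X[i][j] : (i > 0 ? X[i][j] : NEG_INF);
      ra.push_back(a[i - 1]); rb.push_back(0);
      --i;
      if (i == 0 && j == 0) break;
      if (j == 0) { state = 1; continue; }
      if (std::abs(std::max(M[i][j], Y[i][j]) - gap_open - here) < 1e-9 &&
          std::max(M[i][j], Y[i][j]) - gap_open >= X[i][j] - gap_extend) {
        state = (M[i][j] >= Y[i][j]) ? 0 : 2;
      } else state = 1;
    } else { // state 2 or forced left
      double here = Y[i][j];
      ra.push_back(0); rb.push_back(b[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }
      if (std::abs(std::max(M[i][j], X[i][j]) - gap_open - here) < 1e-9 &&
          std::max(M[i][j], X[i][j]) - gap_open >= Y[i][j] - gap_extend) {
        state = (M[i][j] >= X[i][j]) ? 0 : 1;
      } else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["aln_a"] = wrap(ra),
                      _["aln_b"] = wrap(rb), _["n_ident"] = n_ident,
                      _["aln_len"] = (int)ra.size());
}

// ----------------------------------------------------------------- pssm ----

// Best ungapped window of profile P (ncol(P) residue codes, nrow(P) = W
// columns) along an integer-coded sequence.  Returns c(score, offset)
// with 1-based offset; offset 0 when the sequence is shorter than W.
// [[Rcpp::export]]
NumericVector pssm_best_window_cpp(IntegerVector s, NumericMatrix P) {
  int L = s.size(), W = P.nrow();
  if (L < W) return NumericVector::create(R_NegInf, 0);
  double best = R_NegInf;
  int best_off = 1;
  for (int o = 0; o + W <= L; ++o) {
    double sc = 0.0;
    for (int k = 0; k < W; ++k) sc += P(k, s[o + k] - 1);
    if (sc > best) { best = sc; best_off = o + 1; }
  }
  return NumericVector::create(best, best_off);
}

// Best-window scores for many (shuffled) sequences in one call.
// [[Rcpp::export]]
NumericVector pssm_null_scores_cpp(List seqs, NumericMatrix P) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    out[i] = pssm_best_window_cpp(s, P)[0];
  }
  return out;
}
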