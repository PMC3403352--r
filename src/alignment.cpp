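#include <Rcpp.h>
using namespace Rcpp;

// Affine gap model used throughout: a gap of length k costs
// gap_open + k * gap_extend (BLAST convention).

// Smith-Waterman local alignment on integer-encoded sequences (1-based codes
// into the substitution matrix). Returns score and 0-based half-open spans.
// Determinism: the traceback starts at the highest-scoring cell, ties broken
// by lowest row then lowest column; among equal-scoring moves the preference
// is diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export]]
List sw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double ninf = -1e30;
  const double gi = gap_open + gap_extend; // cost of opening (first residue)
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { E(i, j) = ninf; F(i, j) = ninf; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: alignment ending with a gap in b (consumes a_i, move "up")
      E(i, j) = std::max(H(i - 1, j) - gi, E(i - 1, j) - gap_extend);
      F(i, j) = std::max(H(i, j - 1) - gi, F(i, j - 1) - gap_extend);
      double diag = H(i - 1, j - 1) + mat(a[i - 1] - 1, b[j - 1] - 1);
      double h = std::max(0.0, std::max(diag, std::max(E(i, j), F(i, j))));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj; int state = 0; // 0 = H, 1 = E, 2 = F
  int a_end = bi, b_end = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) == 0.0) break;
      double diag = H(i - 1, j - 1) + mat(a[i - 1] - 1, b[j - 1] - 1);
      if (H(i, j) == diag) { --i; --j; }
      else if (H(i, j) == E(i, j)) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (E(i, j) == H(i - 1, j) - gi) { --i; state = 0; }
      else { --i; }
    } else {
      if (F(i, j) == H(i, j - 1) - gi) { --j; state = 0; }
      else { --j; }
    }
  }
  int a_start = i, b_start = j;
  if (best == 0.0) { a_start = a_end = 0; b_start = b_end = 0; }
  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Global (Needleman-Wunsch) alignment of two profiles given a precomputed
// column-vs-column score matrix S (n x m). End gaps are penalized like
// internal ones. Returns the aligned paths as integer vectors where 0 marks
// a gap column. Tie preference: diagonal > up > left.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double ninf = -1e30;
  const double gi = gap_open + gap_extend;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: ends with gap in profile b (consumes a); Y: gap in a (consumes b)
  M(0, 0) = 0; X(0, 0) = ninf; Y(0, 0) = ninf;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = ninf; Y(i, 0) = ninf;
    X(i, 0) = -gi - (i - 1) * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = ninf; X(0, j) = ninf;
    Y(0, j) = -gi - (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = prev + S(i - 1, j - 1);
      X(i, j) = std::max(std::max(M(i - 1, j), Y(i - 1, j)) - gi,
                         X(i - 1, j) - gap_extend);
      Y(i, j) = std::max(std::max(M(i, j - 1), X(i, j - 1)) - gi,
                         Y(i, j - 1) - gap_extend);
    }
  }
  // traceback from best end state
  std::vector<int> pa, pb;
  int i = n, j = m;
  int state;
  double em = M(n, m), ex = X(n, m), ey = Y(n, m);
  if (em >= ex && em >= ey) state = 0; else if (ex >= ey) state = 1; else state = 2;
  double score = std::max(em, std::max(ex, ey));
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j); --j; continue; }
    if (j == 0) { pa.push_back(i); pb.push_back(0); --i; continue; }
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) == prev) state = 0;
      else if (X(i, j) == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      if (X(i, j) == M(i - 1, j) - gi) { --i; state = 0; }
      else if (X(i, j) == X(i - 1, j) - gap_extend) { --i; state = 1; }
      else { --i; state = 2; }
    } else {
      pa.push_back(0); pb.push_back(j);
      if (Y(i, j) == M(i, j - 1) - gi) { --j; state = 0; }
      else if (Y(i, j) == Y(i, j - 1) - gap_extend) { --j; state = 2; }
      else { --j; state = 1; }
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

// Batched score-only Smith-Waterman: all pairs of encoded sequences in
// `qs` x `ss`. Rolling-row DP, no traceback. Returns a |qs| x |ss| matrix.
// [[Rcpp::export]]
NumericMatrix sw_scores_cpp(List qs, List ss, NumericMatrix mat,
                            double gap_open, double gap_extend) {
  const int nq = qs.size(), ns = ss.size();
  const double gi = gap_open + gap_extend;
  NumericMatrix out(nq, ns);
  for (int q = 0; q < nq; ++q) {
    IntegerVector a = qs[q];
    const int n = a.size();
    for (int s = 0; s < ns; ++s) {
      IntegerVector b = ss[s];
      const int m = b.size();
      std::vector<double> H(m + 1, 0.0), E(m + 1, -1e30);
      double best = 0.0;
      for (int i = 1; i <= n; ++i) {
        double diag = 0.0, f = -1e30;  // diag = H[i-1][j-1]
        const double* mrow = &mat(a[i - 1] - 1, 0);
        const int mstride = mat.nrow();
        for (int j = 1; j <= m; ++j) {
          E[j] = std::max(H[j] - gi, E[j] - gap_extend);
          f = std::max(H[j - 1] - gi, f - gap_extend);
          double h = diag + mrow[(b[j - 1] - 1) * mstride];
          h = std::max(0.0, std::max(h, std::max(E[j], f)));
          diag = H[j];
          H[j] = h;
          if (h > best) best = h;
        }
      }
      out(q, s) = best;
    }
  }
  return out;
}
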