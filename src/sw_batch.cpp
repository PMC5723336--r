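#include <Rcpp.h>
using namespace Rcpp;

// Batch score-only Smith-Waterman with affine gaps (a gap of length L costs
// open + L * ext). Sequences are passed pre-encoded as 0-based integer
// vectors indexing into the substitution matrix; returns the optimal local
// score for every pattern x subject pair (0 when no positive-scoring
// alignment exists). Exhaustive — no seeding heuristic — so scores are exact.
// [[Rcpp::export]]
NumericMatrix sw_score_batch_cpp(List patterns, List subjects,
                                 NumericMatrix sub, double gap_open,
                                 double gap_ext) {
  const int np = patterns.size(), ns = subjects.size();
  const double go = gap_open + gap_ext;  // cost of a length-1 gap
  NumericMatrix out(np, ns);
  std::vector<std::vector<int>> pat(np), sbj(ns);
  for (int i = 0; i < np; ++i)
    pat[i] = as<std::vector<int>>(patterns[i]);
  for (int j = 0; j < ns; ++j)
    sbj[j] = as<std::vector<int>>(subjects[j]);
  const int A = sub.nrow();
  std::vector<double> smat(A * A);
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < A; ++b) smat[a * A + b] = sub(a, b);
  for (int j = 0; j < ns; ++j) {
    const std::vector<int>& s = sbj[j];
    const int n = s.size();
    std::vector<double> H(n + 1), E(n + 1);
    for (int i = 0; i < np; ++i) {
      const std::vector<int>& q = pat[i];
      const int m = q.size();
      double best = 0.0;
      std::fill(H.begin(), H.end(), 0.0);
      std::fill(E.begin(), E.end(), -1e30);
      for (int r = 1; r <= m; ++r) {
        const double* srow = &smat[q[r - 1] * A];
        double diag = 0.0;      // H[r-1][0]
        double F = -1e30;
        double Hprev = 0.0;     // H[r][0]
        for (int c = 1; c <= n; ++c) {
          E[c] = std::max(H[c] - go, E[c] - gap_ext);
          F = std::max(Hprev - go, F - gap_ext);
          double h = diag + srow[s[c - 1]];
          if (E[c] > h) h = E[c];
          if (F > h) h = F;
          if (h < 0.0) h = 0.0;
          diag = H[c];
          H[c] = h;
          Hprev = h;
          if (h > best) best = h;
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Score and 0-based half-open intervals of the optimal local alignment of
// one pattern/subject pair (same scoring convention as above). Start cells
// are propagated through the DP; among equal-scoring end cells the first in
// row-major (pattern, subject) order wins.
// [[Rcpp::export]]
List sw_ends_cpp(IntegerVector pattern, IntegerVector subject,
                 NumericMatrix sub, double gap_open, double gap_ext) {
  const int m = pattern.size(), n = subject.size();
  const double go = gap_open + gap_ext;
  std::vector<double> H(n + 1, 0.0), E(n + 1, -1e30);
  std::vector<int> Hq(n + 1, 0), Hr(n + 1, 0), Eq(n + 1, 0), Er(n + 1, 0);
  for (int c = 0; c <= n; ++c) Hr[c] = c;  // zero state in row 0 starts at (0, c)
  double best = 0.0; int bq0 = 0, br0 = 0, bq1 = 0, br1 = 0;
  for (int r = 1; r <= m; ++r) {
    double diag = 0.0; int dq = r - 1, dr = 0;
    double F = -1e30; int Fq = 0, Fr = 0;
    double Hprev = 0.0; int Hpq = r - 1, Hpr = 0;
    for (int c = 1; c <= n; ++c) {
      // E: gap in pattern (consume subject)
      if (H[c] - go >= E[c] - gap_ext) { E[c] = H[c] - go; Eq[c] = Hq[c]; Er[c] = Hr[c]; }
      else { E[c] -= gap_ext; }
      // F: gap in subject (consume pattern)
      if (Hprev - go >= F - gap_ext) { F = Hprev - go; Fq = Hpq; Fr = Hpr; }
      else { F -= gap_ext; }
      double h = diag + sub(pattern[r - 1], subject[c - 1]);
      int hq = dq, hr = dr;
      if (E[c] > h) { h = E[c]; hq = Eq[c]; hr = Er[c]; }
      if (F > h) { h = F; hq = Fq; hr = Fr; }
      if (h < 0.0) { h = 0.0; hq = r; hr = c; }  // fresh start after (r,c)
      diag = H[c]; dq = Hq[c]; dr = Hr[c];
      H[c] = h; Hq[c] = hq; Hr[c] = hr;
      Hprev = h; Hpq = hq; Hpr = hr;
      if (h > best) { best = h; bq0 = hq; br0 = hr; bq1 = r; br1 = c; }
    }
    // reset diag bookkeeping for next row start
  }
  return List::create(Named("score") = best,
                      Named("q0") = bq0, Named("q1") = bq1,
                      Named("r0") = br0, Named("r1") = br1);
}
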