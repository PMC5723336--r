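#include <Rcpp.h>
using namespace Rcpp;

// Global-in-read / local-in-profile affine-gap alignment of a read against a
// positional profile. `s` is the C x L match-score matrix (profile column x
// read position). `del_open`/`del_ext` give the per-column cost of skipping a
// profile column (zero for all-gap columns, so they are gap-preferred).
// Insertions (read residues consuming no column) cost gap_open + gap_extend
// to open and gap_extend to extend, including leading/trailing overhang.
// Returns the best score and, for each read position, the 1-based profile
// column it occupies (0 = insertion, dropped from the registered query).
// Traceback ties prefer match over deletion over insertion, and among equal
// end scores the smallest (column, read position).
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix s, NumericVector del_open,
                       NumericVector del_ext, double gap_open,
                       double gap_extend) {
  const int C = s.nrow(), L = s.ncol();
  const double NEG = -1e30;
  // DP over columns c = 1..C (rows) and read positions j = 1..L
  NumericMatrix M(C + 1, L + 1), D(C + 1, L + 1), I(C + 1, L + 1);
  IntegerMatrix tbM(C + 1, L + 1), tbD(C + 1, L + 1), tbI(C + 1, L + 1);
  for (int c = 0; c <= C; ++c)
    for (int j = 0; j <= L; ++j) { M(c, j) = D(c, j) = I(c, j) = NEG; }
  // start states: before any column, j residues consumed as leading insertions
  for (int j = 1; j <= L; ++j) I(0, j) = -(gap_open + j * gap_extend);
  for (int c = 0; c <= C; ++c) { M(c, 0) = NEG; D(c, 0) = NEG; }
  for (int c = 1; c <= C; ++c) {
    // deletion from nothing consumed: free local start in profile, so a
    // deletion chain before the first residue is never needed; D(c,0) stays
    // unreachable and fresh starts are handled in the M recursion.
    for (int j = 1; j <= L; ++j) {
      // M: read residue j aligned to column c
      double fresh = (j == 1) ? 0.0 : NEG;  // local start in profile
      double lead = (j > 1) ? I(c - 1, j - 1) : NEG;
      // leading-insertion chain sits before the (free) unused profile prefix,
      // so it may jump to any start column
      double lead0 = (j > 1 && c > 1) ? I(0, j - 1) : NEG;
      double best = M(c - 1, j - 1); int tb = 1;
      if (D(c - 1, j - 1) > best) { best = D(c - 1, j - 1); tb = 2; }
      if (lead > best) { best = lead; tb = 3; }
      if (lead0 > best) { best = lead0; tb = 4; }
      if (fresh > best) { best = fresh; tb = 0; }
      M(c, j) = s(c - 1, j - 1) + best;
      tbM(c, j) = tb;
      // D: skip column c with j residues consumed
      double dM = M(c - 1, j) - del_open[c - 1];
      double dD = D(c - 1, j) - del_ext[c - 1];
      if (dM >= dD) { D(c, j) = dM; tbD(c, j) = 1; }
      else { D(c, j) = dD; tbD(c, j) = 2; }
      // I: residue j is an insertion after column c
      double iM = M(c, j - 1) - (gap_open + gap_extend);
      double iI = I(c, j - 1) - gap_extend;
      if (iM >= iI) { I(c, j) = iM; tbI(c, j) = 1; }
      else { I(c, j) = iI; tbI(c, j) = 2; }
    }
  }
  // best end: all L residues consumed, any column, states M or I
  double best = NEG; int bc = -1, bs = 0; // bs: 1 = M, 3 = I
  for (int c = 1; c <= C; ++c) {
    if (M(c, L) > best) { best = M(c, L); bc = c; bs = 1; }
  }
  for (int c = 0; c <= C; ++c) {
    if (I(c, L) > best) { best = I(c, L); bc = c; bs = 3; }
  }
  IntegerVector col(L, 0);
  if (bc >= 0 && best > NEG / 2) {
    int c = bc, j = L, st = bs;
    while (j > 0) {
      if (st == 1) {               // M
        col[j - 1] = c;
        int tb = tbM(c, j);
        if (tb == 1) { st = 1; --c; --j; }
        else if (tb == 2) { st = 2; --c; --j; }
        else if (tb == 3) { st = 3; --c; --j; }
        else if (tb == 4) { st = 3; c = 0; --j; }
        else { break; }            // fresh start, j was 1
      } else if (st == 2) {        // D
        int tb = tbD(c, j);
        st = tb; --c;
      } else {                     // I
        col[j - 1] = 0;
        int tb = tbI(c, j);
        st = (tb == 1) ? 1 : 3;
        --j;
      }
    }
  }
  return List::create(Named("score") = best, Named("col") = col);
}
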