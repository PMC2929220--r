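#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment, Gotoh three-state DP.
//
// Gap cost convention: a run of k gap characters costs open + extend * k
// (opening charged once, extension for every gap character including the
// first).  Scores are maximised; penalties are supplied as positive numbers.
//
// Traceback tie-break (fixed for reproducibility): prefer the match/mismatch
// state, then gap-in-a (a column consuming a residue of b only), then
// gap-in-b.

static const double NEG_INF = -1e30;

// a, b: 0-based integer-encoded sequences; submat: score matrix indexed by
// those codes.  Returns list(score, a_aligned, b_aligned) where the aligned
// vectors hold residue indices with -1 for a gap.
// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                     double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state 0 = M (a_i ~ b_j), 1 = Ia (gap in a, consumes b), 2 = Ib (gap in b)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ia((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ib((n + 1) * (m + 1), NEG_INF);
  // packed traceback: which predecessor state each cell/state came from
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pIa((n + 1) * (m + 1), -1);
  std::vector<signed char> pIb((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Ia[idx(0, j)] = -gap_open - gap_extend * j;
    pIa[idx(0, j)] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    Ib[idx(i, 0)] = -gap_open - gap_extend * i;
    pIb[idx(i, 0)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = submat(a[i - 1], b[j - 1]);
      // M: tie order M > Ia > Ib
      {
        double best = M[idx(i - 1, j - 1)];
        signed char from = 0;
        if (Ia[idx(i - 1, j - 1)] > best) { best = Ia[idx(i - 1, j - 1)]; from = 1; }
        if (Ib[idx(i - 1, j - 1)] > best) { best = Ib[idx(i - 1, j - 1)]; from = 2; }
        M[idx(i, j)] = best + s;
        pM[idx(i, j)] = from;
      }
      // Ia: consume b_j with a gap in a; open from M/Ib, extend from Ia
      {
        double open_sc = std::max(M[idx(i, j - 1)], Ib[idx(i, j - 1)]) -
                         gap_open - gap_extend;
        double ext_sc = Ia[idx(i, j - 1)] - gap_extend;
        if (open_sc >= ext_sc) {
          Ia[idx(i, j)] = open_sc;
          pIa[idx(i, j)] = (M[idx(i, j - 1)] >= Ib[idx(i, j - 1)]) ? 0 : 2;
        } else {
          Ia[idx(i, j)] = ext_sc;
          pIa[idx(i, j)] = 1;
        }
      }
      // Ib: consume a_i with a gap in b
      {
        double open_sc = std::max(M[idx(i - 1, j)], Ia[idx(i - 1, j)]) -
                         gap_open - gap_extend;
        double ext_sc = Ib[idx(i - 1, j)] - gap_extend;
        if (open_sc >= ext_sc) {
          Ib[idx(i, j)] = open_sc;
          pIb[idx(i, j)] = (M[idx(i - 1, j)] >= Ia[idx(i - 1, j)]) ? 0 : 1;
        } else {
          Ib[idx(i, j)] = ext_sc;
          pIb[idx(i, j)] = 2;
        }
      }
    }
  }

  // terminal state, tie order M > Ia > Ib
  int state = 0;
  double score = M[idx(n, m)];
  if (Ia[idx(n, m)] > score) { score = Ia[idx(n, m)]; state = 1; }
  if (Ib[idx(n, m)] > score) { score = Ib[idx(n, m)]; state = 2; }

  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char from = pM[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = from;
    } else if (state == 1) {
      signed char from = pIa[idx(i, j)];
      ra.push_back(-1); rb.push_back(b[j - 1]);
      --j; state = from;
    } else {
      signed char from = pIb[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(-1);
      --i; state = from;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["a_aligned"] = wrap(ra),
                      _["b_aligned"] = wrap(rb));
}

// Profile-profile affine alignment used by the progressive aligner.
// pa, pb: (nsym x L) residue-frequency profiles (columns sum to <= 1; the
// deficit is the gap fraction, which scores 0 against everything).
// Returns two 0/1 path vectors: per output column, whether a column of A /
// of B is consumed.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix pa, NumericMatrix pb, NumericMatrix submat,
                       double gap_open, double gap_extend) {
  const int n = pa.ncol(), m = pb.ncol(), K = submat.nrow();
  // precompute column-column scores
  NumericMatrix colsc(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int x = 0; x < K; ++x) {
        const double fx = pa(x, i);
        if (fx == 0.0) continue;
        for (int y = 0; y < K; ++y) {
          const double fy = pb(y, j);
          if (fy != 0.0) s += fx * fy * submat(x, y);
        }
      }
      colsc(i, j) = s;
    }

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ia((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ib((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pIa((n + 1) * (m + 1), -1);
  std::vector<signed char> pIb((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) { Ia[idx(0, j)] = -gap_open - gap_extend * j; pIa[idx(0, j)] = 1; }
  for (int i = 1; i <= n; ++i) { Ib[idx(i, 0)] = -gap_open - gap_extend * i; pIb[idx(i, 0)] = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = colsc(i - 1, j - 1);
      double best = M[idx(i - 1, j - 1)];
      signed char from = 0;
      if (Ia[idx(i - 1, j - 1)] > best) { best = Ia[idx(i - 1, j - 1)]; from = 1; }
      if (Ib[idx(i - 1, j - 1)] > best) { best = Ib[idx(i - 1, j - 1)]; from = 2; }
      M[idx(i, j)] = best + s;
      pM[idx(i, j)] = from;

      double open_sc = std::max(M[idx(i, j - 1)], Ib[idx(i, j - 1)]) - gap_open - gap_extend;
      double ext_sc = Ia[idx(i, j - 1)] - gap_extend;
      if (open_sc >= ext_sc) {
        Ia[idx(i, j)] = open_sc;
        pIa[idx(i, j)] = (M[idx(i, j - 1)] >= Ib[idx(i, j - 1)]) ? 0 : 2;
      } else { Ia[idx(i, j)] = ext_sc; pIa[idx(i, j)] = 1; }

      open_sc = std::max(M[idx(i - 1, j)], Ia[idx(i - 1, j)]) - gap_open - gap_extend;
      ext_sc = Ib[idx(i - 1, j)] - gap_extend;
      if (open_sc >= ext_sc) {
        Ib[idx(i, j)] = open_sc;
        pIb[idx(i, j)] = (M[idx(i - 1, j)] >= Ia[idx(i - 1, j)]) ? 0 : 1;
      } else { Ib[idx(i, j)] = ext_sc; pIb[idx(i, j)] = 2; }
    }
  }

  int state = 0;
  double score = M[idx(n, m)];
  if (Ia[idx(n, m)] > score) { score = Ia[idx(n, m)]; state = 1; }
  if (Ib[idx(n, m)] > score) { score = Ib[idx(n, m)]; state = 2; }

  std::vector<int> useA, useB;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      state = pM[idx(i, j)]; useA.push_back(1); useB.push_back(1); --i; --j;
    } else if (state == 1) {
      state = pIa[idx(i, j)]; useA.push_back(0); useB.push_back(1); --j;
    } else {
      state = pIb[idx(i, j)]; useA.push_back(1); useB.push_back(0); --i;
    }
  }
  std::reverse(useA.begin(), useA.end());
  std::reverse(useB.begin(), useB.end());
  return List::create(_["score"] = score,
                      _["use_a"] = wrap(useA),
                      _["use_b"] = wrap(useB));
}

// Exhaustive enumeration of all global alignments (test oracle; no DP reuse:
// plain depth-first walk over alignment paths, tracking the affine-gap state
// of the previous column).  Exponential; intended for sequences of length
// <= 8 only.
static double enum_best(const IntegerVector &a, const IntegerVector &b,
                        const NumericMatrix &submat, double go, double ge,
                        int i, int j, int prev) {
  const int n = a.size(), m = b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double s = submat(a[i], b[j]) +
               enum_best(a, b, submat, go, ge, i + 1, j + 1, 0);
    if (s > best) best = s;
  }
  if (j < m) { // gap in a
    double pen = (prev == 1) ? ge : go + ge;
    double s = -pen + enum_best(a, b, submat, go, ge, i, j + 1, 1);
    if (s > best) best = s;
  }
  if (i < n) { // gap in b
    double pen = (prev == 2) ? ge : go + ge;
    double s = -pen + enum_best(a, b, submat, go, ge, i + 1, j, 2);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export]]
double enumerate_align_score_cpp(IntegerVector a, IntegerVector b,
                                 NumericMatrix submat, double gap_open,
                                 double gap_extend) {
  if (a.size() > 12 || b.size() > 12)
    stop("enumeration oracle limited to length <= 12");
  return enum_best(a, b, submat, gap_open, gap_extend, 0, 0, -1);
}
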