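#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment (Gotoh affine-gap DP) used by the
// progressive aligner. Profiles are 4 x n count matrices of unambiguous
// residues (A,C,G,T) per column; N and gap characters score 0 and are simply
// absent from the counts. A gap of length k costs gap_open + k * gap_ext.
// Tie-breaking is fixed: diagonal (M) over up (X, consuming profile 1) over
// left (Y, consuming profile 2), both in state selection and traceback, so
// alignments are bit-reproducible.

static const double NEG = -1e18;

static inline int best3(double m, double x, double y, double &out) {
  // preference on ties: M (0) > X (1) > Y (2)
  if (m >= x && m >= y) { out = m; return 0; }
  if (x >= y)           { out = x; return 1; }
  out = y; return 2;
}

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix p1, NumericMatrix p2,
                       double n1, double n2,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const int m = p1.ncol(), n = p2.ncol();
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tbM(m + 1, n + 1), tbX(m + 1, n + 1), tbY(m + 1, n + 1);

  // column totals of unambiguous residues
  std::vector<double> tot1(m), tot2(n);
  for (int i = 0; i < m; ++i)
    tot1[i] = p1(0, i) + p1(1, i) + p1(2, i) + p1(3, i);
  for (int j = 0; j < n; ++j)
    tot2[j] = p2(0, j) + p2(1, j) + p2(2, j) + p2(3, j);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + i * gap_ext);
    tbX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + j * gap_ext);
    tbY(0, j) = (j == 1) ? 0 : 2;
  }

  const double denom = n1 * n2;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s_match = p1(0, i - 1) * p2(0, j - 1) + p1(1, i - 1) * p2(1, j - 1) +
                       p1(2, i - 1) * p2(2, j - 1) + p1(3, i - 1) * p2(3, j - 1);
      double s_mis = tot1[i - 1] * tot2[j - 1] - s_match;
      double s = (match * s_match + mismatch * s_mis) / denom;

      double b;
      tbM(i, j) = best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), b);
      M(i, j) = b + s;

      tbX(i, j) = best3(M(i - 1, j) - (gap_open + gap_ext),
                        X(i - 1, j) - gap_ext,
                        Y(i - 1, j) - (gap_open + gap_ext), b);
      X(i, j) = b;

      tbY(i, j) = best3(M(i, j - 1) - (gap_open + gap_ext),
                        X(i, j - 1) - (gap_open + gap_ext),
                        Y(i, j - 1) - gap_ext, b);
      Y(i, j) = b;
    }
  }

  double score;
  int state = best3(M(m, n), X(m, n), Y(m, n), score);

  std::vector<int> path1, path2;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path1.push_back(i); path2.push_back(j);
      state = tbM(i, j); --i; --j;
    } else if (state == 1) {
      path1.push_back(i); path2.push_back(0);
      state = tbX(i, j); --i;
    } else {
      path1.push_back(0); path2.push_back(j);
      state = tbY(i, j); --j;
    }
  }
  std::reverse(path1.begin(), path1.end());
  std::reverse(path2.begin(), path2.end());

  return List::create(_["path1"] = wrap(path1), _["path2"] = wrap(path2),
                      _["score"] = score);
}
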