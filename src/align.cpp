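#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps.
// Gap of length L costs gap_open + (L - 1) * gap_extend (both <= 0).
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a),
// resolved on the *recomputed* move scores so the alignment is deterministic.
//
// sub is a square substitution matrix with dimnames covering every residue
// of a and b; a and b are ungapped uppercase strings.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b, NumericMatrix sub,
                   std::vector<std::string> alphabet,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::map<char, int> idx;
  for (size_t i = 0; i < alphabet.size(); ++i) idx[alphabet[i][0]] = i;
  for (char c : a) if (!idx.count(c)) stop("unknown residue in first sequence");
  for (char c : b) if (!idx.count(c)) stop("unknown residue in second sequence");

  // M: a[i] aligned to b[j]; X: gap in b (consume a, "up"); Y: gap in a ("left").
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(idx[a[i - 1]], idx[b[j - 1]]);
      double best = std::max(M(i - 1, j - 1),
                    std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open, X(i - 1, j) + gap_extend);
      if (j < m || true)
        X(i, j) = std::max(X(i, j), Y(i - 1, j) + gap_open);
      Y(i, j) = std::max(M(i, j - 1) + gap_open, Y(i, j - 1) + gap_extend);
      Y(i, j) = std::max(Y(i, j), X(i, j - 1) + gap_open);
    }
  }

  double score = std::max(M(n, m), std::max(X(n, m), Y(n, m)));

  // Traceback: state = which matrix holds the current best, with the
  // documented preference M (diagonal) > X (up) > Y (left) on ties.
  std::string ra, rb;
  int i = n, j = m;
  char state;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 'M';
  else if (X(n, m) >= Y(n, m)) state = 'X';
  else state = 'Y';

  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 'M') {
      double s = sub(idx[a[i - 1]], idx[b[j - 1]]);
      ra += a[i - 1]; rb += b[j - 1];
      double target = M(i, j) - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - target) < eps) state = 'M';
      else if (std::abs(X(i, j) - target) < eps) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      ra += a[i - 1]; rb += '-';
      double here = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - here) < eps) state = 'M';
      else if (std::abs(X(i, j) + gap_extend - here) < eps) state = 'X';
      else state = 'Y';
    } else {
      ra += '-'; rb += b[j - 1];
      double here = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - here) < eps) state = 'M';
      else if (std::abs(Y(i, j) + gap_extend - here) < eps) state = 'Y';
      else state = 'X';
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
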