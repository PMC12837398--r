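#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment path between two profiles, affine
// gaps (Gotoh). `s` is the precomputed column-vs-column score matrix
// (rows = profile A columns, cols = profile B columns). Gap of length L
// costs open + (L-1)*ext. Returns moves from the start of the alignment:
// 0 = consume a column of both profiles, 1 = A only (gap in B), 2 = B only.
// [[Rcpp::export(name = ".nw_path")]]
IntegerVector nw_path(NumericMatrix s, double open, double ext) {
  const int m = s.nrow(), n = s.ncol();
  const double NEG = -1e30;
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // traceback: which matrix each cell's best predecessor lived in (0/1/2)
  IntegerMatrix tM(m + 1, n + 1), tX(m + 1, n + 1), tY(m + 1, n + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(open + (i - 1) * ext); tX(i, 0) = 1;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(open + (j - 1) * ext); tY(0, j) = 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      int t = 0; double best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      M(i, j) = best + s(i - 1, j - 1); tM(i, j) = t;

      a = M(i - 1, j) - open; b = X(i - 1, j) - ext; c = Y(i - 1, j) - open;
      t = 0; best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      X(i, j) = best; tX(i, j) = t;

      a = M(i, j - 1) - open; b = X(i, j - 1) - open; c = Y(i, j - 1) - ext;
      t = 0; best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      Y(i, j) = best; tY(i, j) = t;
    }
  }
  int state = 0;
  double best = M(m, n);
  if (X(m, n) > best) { best = X(m, n); state = 1; }
  if (Y(m, n) > best) { best = Y(m, n); state = 2; }

  std::vector<int> rev;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0)      { rev.push_back(0); state = tM(i, j); --i; --j; }
    else if (state == 1) { rev.push_back(1); state = tX(i, j); --i; }
    else                 { rev.push_back(2); state = tY(i, j); --j; }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}
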