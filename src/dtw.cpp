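#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with squared-difference local cost and step set
// {(1,0),(0,1),(1,1)}. Ties in the DP minimum are broken toward the
// diagonal step, which keeps the warping path as short as possible
// (aligned length between n and n + m - 1). Returns the optimal path as a
// 2-column matrix of 1-based indices into x and y.
// [[Rcpp::export]]
IntegerMatrix dtw_path(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n < 1 || m < 1) stop("dtw_path needs non-empty inputs");
  std::vector<double> D((size_t)n * m);
  std::vector<unsigned char> from((size_t)n * m); // 0=diag,1=up(i-1),2=left(j-1)
  auto at = [m](int i, int j) { return (size_t)i * m + j; };
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = x[i] - y[j];
      d *= d;
      if (i == 0 && j == 0) {
        D[at(i, j)] = d;
        from[at(i, j)] = 0;
      } else if (i == 0) {
        D[at(i, j)] = d + D[at(i, j - 1)];
        from[at(i, j)] = 2;
      } else if (j == 0) {
        D[at(i, j)] = d + D[at(i - 1, j)];
        from[at(i, j)] = 1;
      } else {
        double diag = D[at(i - 1, j - 1)];
        double up = D[at(i - 1, j)];
        double left = D[at(i, j - 1)];
        double best = diag;
        unsigned char arg = 0;
        if (up < best) { best = up; arg = 1; }
        if (left < best) { best = left; arg = 2; }
        D[at(i, j)] = d + best;
        from[at(i, j)] = arg;
      }
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    unsigned char f = from[at(i, j)];
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}
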