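#include <Rcpp.h>
using namespace Rcpp;

// Pointwise distance between row i of x and row j of y: Euclidean norm of the
// difference (absolute difference in the univariate case).
static inline double rowdist(const NumericMatrix& x, const NumericMatrix& y,
                             int i, int j) {
  double s = 0.0;
  for (int c = 0; c < x.ncol(); ++c) {
    double d = x(i, c) - y(j, c);
    s += d * d;
  }
  return std::sqrt(s);
}

// Unconstrained DTW cost with steps {(i-1,j-1),(i-1,j),(i,j-1)}, rolling rows.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix x, NumericMatrix y) {
  const int n = x.nrow(), m = y.nrow();
  std::vector<double> prev(m), cur(m);
  prev[0] = rowdist(x, y, 0, 0);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + rowdist(x, y, 0, j);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + rowdist(x, y, i, 0);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + rowdist(x, y, i, j);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Full DP with backtracking. Ties prefer the diagonal step, then (i-1,j).
// [[Rcpp::export]]
List dtw_path_cpp(NumericMatrix x, NumericMatrix y) {
  const int n = x.nrow(), m = y.nrow();
  NumericMatrix D(n, m);
  D(0, 0) = rowdist(x, y, 0, 0);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + rowdist(x, y, 0, j);
  for (int i = 1; i < n; ++i) {
    D(i, 0) = D(i - 1, 0) + rowdist(x, y, i, 0);
    for (int j = 1; j < m; ++j) {
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = best + rowdist(x, y, i, j);
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
      if (dd <= du && dd <= dl) { --i; --j; }
      else if (du <= dl) { --i; }
      else { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    path(k, 0) = pi[k];
    path(k, 1) = pj[k];
  }
  return List::create(_["distance"] = D(n - 1, m - 1), _["path"] = path);
}
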