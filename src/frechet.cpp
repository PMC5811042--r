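#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two polylines given as point
// sequences (x, y).  Dynamic programme over all monotone couplings:
//   ca(i,j) = max(d(a_i, b_j), min(ca(i-1,j), ca(i-1,j-1), ca(i,j-1)))
// with Euclidean point distance in the (age, value) plane.

static double ptdist(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return std::sqrt(dx * dx + dy * dy);
}

// [[Rcpp::export]]
double dfrechet_cpp(NumericVector ax, NumericVector ay,
                    NumericVector bx, NumericVector by) {
  int n = ax.size(), m = bx.size();
  if (n == 0 || m == 0) stop("empty curve");
  std::vector<double> prev(m), cur(m);
  prev[0] = ptdist(ax[0], ay[0], bx[0], by[0]);
  for (int j = 1; j < m; ++j)
    prev[j] = std::max(prev[j - 1], ptdist(ax[0], ay[0], bx[j], by[j]));
  for (int i = 1; i < n; ++i) {
    cur[0] = std::max(prev[0], ptdist(ax[i], ay[i], bx[0], by[0]));
    for (int j = 1; j < m; ++j) {
      double reach = std::min(std::min(prev[j], prev[j - 1]), cur[j - 1]);
      cur[j] = std::max(reach, ptdist(ax[i], ay[i], bx[j], by[j]));
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Distances from every row-curve of `curves` (values on a shared grid)
// to every row-curve of `centers`.
// [[Rcpp::export]]
NumericMatrix frechet_cross_cpp(NumericMatrix curves, NumericMatrix centers,
                                NumericVector grid) {
  int n = curves.nrow(), k = centers.nrow();
  NumericMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    NumericVector ci = curves(i, _);
    for (int j = 0; j < k; ++j) {
      NumericVector cj = centers(j, _);
      out(i, j) = dfrechet_cpp(grid, ci, grid, cj);
    }
  }
  return out;
}
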