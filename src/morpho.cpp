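#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum pairwise Euclidean distance between points (n x 3 matrix, um).
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Caliper (projected) width of a point cloud along each unit direction:
// max - min of the scalar projections. dirs is m x 3.
// [[Rcpp::export]]
NumericVector caliper_widths_cpp(NumericMatrix pts, NumericMatrix dirs) {
  const int n = pts.nrow(), m = dirs.nrow();
  NumericVector w(m);
  for (int d = 0; d < m; ++d) {
    const double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double s = pts(i, 0) * ux + pts(i, 1) * uy + pts(i, 2) * uz;
      if (s < lo) lo = s;
      if (s > hi) hi = s;
    }
    w[d] = hi - lo;
  }
  return w;
}
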