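#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate triangle-kernel contributions of a point set onto a regular grid.
//
// Grid convention: row 1 is the northernmost row; cell (r, c) has its centre at
//   x = x0 + (c - 0.5) * res
//   y = y0 + (nrow - r + 0.5) * res
// with (x0, y0) the grid's southwest corner. Each point adds K(d) = 1 - d/h for
// d < h (exact cell-centre distances; points are never binned to cells first).
// Only cells within one bandwidth of a point are visited, so cost is
// O(n_points * (2h/res)^2) rather than O(n_points * n_cells).
//
// [[Rcpp::export]]
NumericMatrix kde_accumulate(int nrow, int ncol,
                             double x0, double y0, double res, double h,
                             NumericVector px, NumericVector py) {
  NumericMatrix out(nrow, ncol);
  if (h <= 0.0 || res <= 0.0)
    stop("bandwidth and resolution must be positive");
  const int n = px.size();
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    // candidate column range: cells whose centre x lies in (x - h, x + h)
    int cmin = (int) std::floor((x - h - x0) / res + 0.5) + 1;
    int cmax = (int) std::ceil ((x + h - x0) / res + 0.5) - 1;
    if (cmin < 1) cmin = 1;
    if (cmax > ncol) cmax = ncol;
    // candidate row range (row index decreases as y increases)
    int rmin = (int) std::floor(nrow - (y + h - y0) / res + 0.5) + 1;
    int rmax = (int) std::ceil (nrow - (y - h - y0) / res + 0.5) - 1;
    if (rmin < 1) rmin = 1;
    if (rmax > nrow) rmax = nrow;
    for (int r = rmin; r <= rmax; ++r) {
      const double yc = y0 + (nrow - r + 0.5) * res;
      const double dy = yc - y;
      for (int c = cmin; c <= cmax; ++c) {
        const double xc = x0 + (c - 0.5) * res;
        const double dx = xc - x;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < h) out(r - 1, c - 1) += 1.0 - d / h;
      }
    }
  }
  return out;
}
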