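#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All point pairs strictly closer than `threshold` (cell-list fixed-radius
// search; exact, not approximate). Returns a 3-column matrix
// (i, j, distance) with i < j, 1-based.
// [[Rcpp::export]]
NumericMatrix edges_within_cpp(NumericMatrix points, double threshold) {
  const int n = points.nrow();
  const double t2 = threshold * threshold;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], points(i, k));
      hi[k] = std::max(hi[k], points(i, k));
    }
  const double cell = std::max(threshold, 1e-9);
  int gdim[3];
  for (int k = 0; k < 3; ++k)
    gdim[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell + 1e-9));
  std::vector<std::vector<int>> grid((size_t)gdim[0] * gdim[1] * gdim[2]);
  auto cell_idx = [&](int i, int* c) {
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)std::floor((points(i, k) - lo[k]) / cell);
      if (c[k] < 0) c[k] = 0;
      if (c[k] >= gdim[k]) c[k] = gdim[k] - 1;
    }
  };
  for (int i = 0; i < n; ++i) {
    int c[3];
    cell_idx(i, c);
    grid[c[0] + (size_t)gdim[0] * (c[1] + (size_t)gdim[1] * c[2])].push_back(i);
  }
  std::vector<double> ei, ej, ed;
  for (int i = 0; i < n; ++i) {
    int c[3];
    cell_idx(i, c);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          const int cy = c[0] + dy, cx = c[1] + dx, cz = c[2] + dz;
          if (cy < 0 || cy >= gdim[0] || cx < 0 || cx >= gdim[1] || cz < 0 ||
              cz >= gdim[2]) continue;
          for (int j : grid[cy + (size_t)gdim[0] * (cx + (size_t)gdim[1] * cz)]) {
            if (j <= i) continue;
            const double ddx = points(i, 0) - points(j, 0);
            const double ddy = points(i, 1) - points(j, 1);
            const double ddz = points(i, 2) - points(j, 2);
            const double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (d2 < t2) {
              ei.push_back(i + 1);
              ej.push_back(j + 1);
              ed.push_back(std::sqrt(d2));
            }
          }
        }
  }
  NumericMatrix out((int)ei.size(), 3);
  for (size_t r = 0; r < ei.size(); ++r) {
    out((int)r, 0) = ei[r];
    out((int)r, 1) = ej[r];
    out((int)r, 2) = ed[r];
  }
  colnames(out) = CharacterVector::create("from", "to", "weight");
  return out;
}
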