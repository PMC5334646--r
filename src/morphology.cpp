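#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Shared indexing convention: dim = c(ny, nx, nz), linear = y + ny*(x + nx*z).

struct Grid {
  int ny, nx, nz;
  Grid(IntegerVector d) : ny(d[0]), nx(d[1]), nz(d[2]) {}
  size_t size() const { return (size_t)ny * nx * nz; }
  inline size_t idx(int y, int x, int z) const {
    return y + (size_t)ny * (x + (size_t)nx * z);
  }
  inline void coords(size_t i, int& y, int& x, int& z) const {
    y = (int)(i % ny); i /= ny; x = (int)(i % nx); z = (int)(i / nx);
  }
};

static void neighbor_offsets(int connectivity,
                             std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        const int manhattan = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        off.push_back({dy, dx, dz});
      }
}

// Connected-component labeling of a logical mask (6- or 26-connectivity).
// Labels 1..n in scan order of the first voxel encountered (deterministic).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  IntegerVector labels(mask.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < g.size(); ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int y, x, z; g.coords(cur, y, x, z);
      for (auto& o : off) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
          continue;
        const size_t j = g.idx(yy, xx, zz);
        if (mask[j] && labels[j] == 0) { labels[j] = next; stack.push_back(j); }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_objects") = next;
  return labels;
}

// Binary dilation with a digital ball structuring element of given radius.
// [[Rcpp::export]]
LogicalVector dilate_ball_cpp(LogicalVector mask, IntegerVector dims,
                              double radius) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  const int r = (int)std::floor(radius);
  const double r2 = radius * radius;
  for (int dz = -r; dz <= r; ++dz)
    for (int dx = -r; dx <= r; ++dx)
      for (int dy = -r; dy <= r; ++dy)
        if (dy * dy + dx * dx + dz * dz <= r2)
          off.push_back({dy, dx, dz});
  LogicalVector out(mask.size(), false);
  for (size_t i = 0; i < g.size(); ++i) {
    if (!mask[i]) continue;
    int y, x, z; g.coords(i, y, x, z);
    for (auto& o : off) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      out[g.idx(yy, xx, zz)] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask required), hybrid raster/anti-raster + FIFO queue
// (Vincent 1993). Used for the h-maxima transform.
// [[Rcpp::export]]
NumericVector reconstruct_dilation_cpp(NumericVector marker, NumericVector mask,
                                       IntegerVector dims, int connectivity) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  std::vector<std::array<int,3>> fwd, bwd;
  for (auto& o : off) {
    // raster order: earlier linear index = smaller (z, x, y) lexicographic
    if (o[2] < 0 || (o[2] == 0 && (o[1] < 0 || (o[1] == 0 && o[0] < 0))))
      fwd.push_back(o);
    else
      bwd.push_back(o);
  }
  std::vector<double> J(marker.begin(), marker.end());
  const double* I = REAL(mask);

  // forward scan
  for (size_t i = 0; i < g.size(); ++i) {
    int y, x, z; g.coords(i, y, x, z);
    double m = J[i];
    for (auto& o : fwd) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      m = std::max(m, J[g.idx(yy, xx, zz)]);
    }
    J[i] = std::min(m, I[i]);
  }
  // backward scan + queue seeding
  std::queue<size_t> q;
  for (size_t i = g.size(); i-- > 0; ) {
    int y, x, z; g.coords(i, y, x, z);
    double m = J[i];
    for (auto& o : bwd) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      m = std::max(m, J[g.idx(yy, xx, zz)]);
    }
    J[i] = std::min(m, I[i]);
    for (auto& o : bwd) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      const size_t j = g.idx(yy, xx, zz);
      if (J[j] < J[i] && J[j] < I[j]) { q.push(i); break; }
    }
  }
  while (!q.empty()) {
    const size_t i = q.front(); q.pop();
    int y, x, z; g.coords(i, y, x, z);
    for (auto& o : off) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      const size_t j = g.idx(yy, xx, zz);
      if (J[j] < J[i] && I[j] != J[j]) {
        J[j] = std::min(J[i], I[j]);
        q.push(j);
      }
    }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dims;
  return out;
}

// Regional maxima: plateaus of constant value with no strictly greater
// neighbor. Returns a logical mask.
// [[Rcpp::export]]
LogicalVector regional_maxima_cpp(NumericVector img, IntegerVector dims,
                                  int connectivity) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  // 0 = unknown, 1 = maximum, 2 = not maximum
  std::vector<unsigned char> state(g.size(), 0);
  std::vector<size_t> stack, plateau;
  for (size_t i = 0; i < g.size(); ++i) {
    if (state[i] != 0) continue;
    const double v = img[i];
    bool is_max = true;
    plateau.clear();
    stack.clear();
    stack.push_back(i);
    state[i] = 1;
    plateau.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back(); stack.pop_back();
      int y, x, z; g.coords(cur, y, x, z);
      for (auto& o : off) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
          continue;
        const size_t j = g.idx(yy, xx, zz);
        if (img[j] > v) { is_max = false; continue; }
        if (img[j] == v && state[j] == 0) {
          state[j] = 1;
          stack.push_back(j);
          plateau.push_back(j);
        }
      }
    }
    if (!is_max)
      for (size_t p : plateau) state[p] = 2;
  }
  LogicalVector out(img.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = (state[i] == 1);
  out.attr("dim") = dims;
  return out;
}

// Marker-controlled immersion watershed (Meyer's flooding) of `f`
// (flooded in ascending intensity) from integer seed labels. Voxels where
// basins meet become watershed lines (label 0). Deterministic: the priority
// queue is ordered by (intensity, insertion counter).
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector f, IntegerVector seeds,
                            IntegerVector dims, int connectivity) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);

  struct QItem {
    double value; size_t counter; size_t idx;
    bool operator>(const QItem& other) const {
      if (value != other.value) return value > other.value;
      return counter > other.counter;
    }
  };
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem>> pq;

  IntegerVector labels = clone(seeds);
  std::vector<unsigned char> queued(g.size(), 0);
  const unsigned char WSLINE = 2;
  std::vector<unsigned char> state(g.size(), 0); // 0 unset, 1 labeled, 2 line
  size_t counter = 0;

  for (size_t i = 0; i < g.size(); ++i)
    if (labels[i] > 0) { state[i] = 1; queued[i] = 1; }
  for (size_t i = 0; i < g.size(); ++i) {
    if (labels[i] <= 0) continue;
    int y, x, z; g.coords(i, y, x, z);
    for (auto& o : off) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      const size_t j = g.idx(yy, xx, zz);
      if (!queued[j]) { queued[j] = 1; pq.push({f[j], counter++, j}); }
    }
  }

  while (!pq.empty()) {
    const size_t i = pq.top().idx; pq.pop();
    if (state[i] != 0) continue;
    int y, x, z; g.coords(i, y, x, z);
    int lab = 0;
    bool conflict = false;
    for (auto& o : off) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
        continue;
      const size_t j = g.idx(yy, xx, zz);
      if (state[j] == 1) {
        if (lab == 0) lab = labels[j];
        else if (labels[j] != lab) conflict = true;
      }
    }
    if (conflict || lab == 0) {
      state[i] = WSLINE;
      labels[i] = 0;
    } else {
      state[i] = 1;
      labels[i] = lab;
      for (auto& o : off) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 || zz >= g.nz)
          continue;
        const size_t j = g.idx(yy, xx, zz);
        if (!queued[j]) { queued[j] = 1; pq.push({f[j], counter++, j}); }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Per-label voxel statistics used by feature extraction: one pass collecting
// volume, centroid sums, intensity stats and surface voxel counts
// (6-neighbor background).
// [[Rcpp::export]]
List label_stats_cpp(IntegerVector labels, NumericVector img,
                     IntegerVector dims, int n_labels) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(6, off);
  std::vector<double> vol(n_labels, 0), sy(n_labels, 0), sx(n_labels, 0),
      sz(n_labels, 0), wy(n_labels, 0), wx(n_labels, 0), wz(n_labels, 0),
      wsum(n_labels, 0), isum(n_labels, 0), isum2(n_labels, 0),
      imin(n_labels, R_PosInf), imax(n_labels, R_NegInf), surf(n_labels, 0);
  std::vector<int> y0(n_labels, INT_MAX), y1(n_labels, -1),
      x0(n_labels, INT_MAX), x1(n_labels, -1), z0(n_labels, INT_MAX),
      z1(n_labels, -1);
  for (size_t i = 0; i < g.size(); ++i) {
    const int lab = labels[i];
    if (lab <= 0) continue;
    const int k = lab - 1;
    int y, x, z; g.coords(i, y, x, z);
    const double v = img[i];
    vol[k] += 1; sy[k] += y; sx[k] += x; sz[k] += z;
    wy[k] += v * y; wx[k] += v * x; wz[k] += v * z; wsum[k] += v;
    isum[k] += v; isum2[k] += v * v;
    imin[k] = std::min(imin[k], v); imax[k] = std::max(imax[k], v);
    y0[k] = std::min(y0[k], y); y1[k] = std::max(y1[k], y);
    x0[k] = std::min(x0[k], x); x1[k] = std::max(x1[k], x);
    z0[k] = std::min(z0[k], z); z1[k] = std::max(z1[k], z);
    bool is_surface = false;
    for (auto& o : off) {
      const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx || zz < 0 ||
          zz >= g.nz) { is_surface = true; break; }
      if (labels[g.idx(yy, xx, zz)] != lab) { is_surface = true; break; }
    }
    if (is_surface) surf[k] += 1;
  }
  return List::create(
      _["volume"] = vol, _["sum_y"] = sy, _["sum_x"] = sx, _["sum_z"] = sz,
      _["wsum_y"] = wy, _["wsum_x"] = wx, _["wsum_z"] = wz,
      _["wsum"] = wsum, _["int_sum"] = isum, _["int_sum2"] = isum2,
      _["int_min"] = imin, _["int_max"] = imax, _["surface"] = surf,
      _["y_min"] = y0, _["y_max"] = y1, _["x_min"] = x0, _["x_max"] = x1,
      _["z_min"] = z0, _["z_max"] = z1);
}

// Per-label second moments and centroid distance statistics (second pass,
// needs centroids from label_stats_cpp).
// [[Rcpp::export]]
List label_moments_cpp(IntegerVector labels, IntegerVector dims,
                       NumericMatrix centroids) {
  Grid g(dims);
  const int n_labels = centroids.nrow();
  std::vector<double> cxx(n_labels, 0), cyy(n_labels, 0), czz(n_labels, 0),
      cxy(n_labels, 0), cxz(n_labels, 0), cyz(n_labels, 0),
      dsum(n_labels, 0), dmin(n_labels, R_PosInf), dmax(n_labels, 0),
      vol(n_labels, 0);
  for (size_t i = 0; i < g.size(); ++i) {
    const int lab = labels[i];
    if (lab <= 0) continue;
    const int k = lab - 1;
    int y, x, z; g.coords(i, y, x, z);
    const double dx = x - centroids(k, 0), dy = y - centroids(k, 1),
                 dz = z - centroids(k, 2);
    cxx[k] += dx * dx; cyy[k] += dy * dy; czz[k] += dz * dz;
    cxy[k] += dx * dy; cxz[k] += dx * dz; cyz[k] += dy * dz;
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    dsum[k] += d; dmin[k] = std::min(dmin[k], d); dmax[k] = std::max(dmax[k], d);
    vol[k] += 1;
  }
  return List::create(_["cxx"] = cxx, _["cyy"] = cyy, _["czz"] = czz,
                      _["cxy"] = cxy, _["cxz"] = cxz, _["cyz"] = cyz,
                      _["dist_sum"] = dsum, _["dist_min"] = dmin,
                      _["dist_max"] = dmax, _["volume"] = vol);
}

// Projection extents of each label's voxels onto its principal axes.
// axes: 3x3 matrices stacked row-wise per label (9 columns).
// [[Rcpp::export]]
NumericMatrix label_extents_cpp(IntegerVector labels, IntegerVector dims,
                                NumericMatrix centroids, NumericMatrix axes) {
  Grid g(dims);
  const int n_labels = centroids.nrow();
  NumericMatrix lo(n_labels, 3), hi(n_labels, 3);
  std::fill(lo.begin(), lo.end(), R_PosInf);
  std::fill(hi.begin(), hi.end(), R_NegInf);
  for (size_t i = 0; i < g.size(); ++i) {
    const int lab = labels[i];
    if (lab <= 0) continue;
    const int k = lab - 1;
    int y, x, z; g.coords(i, y, x, z);
    const double dx = x - centroids(k, 0), dy = y - centroids(k, 1),
                 dz = z - centroids(k, 2);
    for (int a = 0; a < 3; ++a) {
      const double p = dx * axes(k, 3 * a) + dy * axes(k, 3 * a + 1) +
                       dz * axes(k, 3 * a + 2);
      lo(k, a) = std::min(lo(k, a), p);
      hi(k, a) = std::max(hi(k, a), p);
    }
  }
  NumericMatrix ext(n_labels, 3);
  for (int k = 0; k < n_labels; ++k)
    for (int a = 0; a < 3; ++a)
      ext(k, a) = (hi(k, a) >= lo(k, a)) ? hi(k, a) - lo(k, a) : 0.0;
  return ext;
}
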