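#include <Rcpp.h>
using namespace Rcpp;

// Arrays are stored R-style with dim = c(ny, nx, nz):
//   linear index = y + ny * (x + nx * z), all 0-based here.
// Mirror (reflect) boundary handling throughout: index -1 maps to 0,
// index n maps to n-1 (scipy "reflect" / symmetric padding).

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// Convolve along one axis (0 = y, 1 = x, 2 = z) with an odd-length kernel.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int ny, int nx, int nz, int axis,
                      const NumericVector& kernel) {
  const int klen = kernel.size();
  const int kr = (klen - 1) / 2;
  const int n_axis = (axis == 0) ? ny : (axis == 1) ? nx : nz;

  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const int pos = (axis == 0) ? y : (axis == 1) ? x : z;
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          const int p = reflect_idx(pos + k - kr, n_axis);
          int yy = y, xx = x, zz = z;
          if (axis == 0) yy = p; else if (axis == 1) xx = p; else zz = p;
          acc += kernel[k] * in[yy + (size_t)ny * (xx + (size_t)nx * zz)];
        }
        out[y + (size_t)ny * (x + (size_t)nx * z)] = acc;
      }
    }
  }
}

// Separable 3D filter; each of ky, kx, kz may be NULL to skip that axis.
// [[Rcpp::export]]
NumericVector separable_filter_cpp(NumericVector arr, IntegerVector dims,
                                   Nullable<NumericVector> ky,
                                   Nullable<NumericVector> kx,
                                   Nullable<NumericVector> kz) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());
  if (ky.isNotNull()) { conv_axis(a, b, ny, nx, nz, 0, ky.get()); a.swap(b); }
  if (kx.isNotNull()) { conv_axis(a, b, ny, nx, nz, 1, kx.get()); a.swap(b); }
  if (kz.isNotNull()) { conv_axis(a, b, ny, nx, nz, 2, kz.get()); a.swap(b); }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Voxel-wise maximum of two arrays, in place on the first (used for the
// running maximum over LoG scales).
// [[Rcpp::export]]
NumericVector pmax_inplace_cpp(NumericVector acc, NumericVector other) {
  const R_xlen_t n = acc.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (other[i] > acc[i]) acc[i] = other[i];
  return acc;
}

// Block-mean downscale by integer factor along all axes (local mean
// resampling; anti-aliasing by construction).
// [[Rcpp::export]]
NumericVector block_mean_cpp(NumericVector arr, IntegerVector dims, int block) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int oy = ny / block, ox = nx / block, oz = nz / block;
  NumericVector out((size_t)oy * ox * oz);
  for (int z = 0; z < oz; ++z)
    for (int x = 0; x < ox; ++x)
      for (int y = 0; y < oy; ++y) {
        double acc = 0.0;
        for (int dz = 0; dz < block; ++dz)
          for (int dx = 0; dx < block; ++dx)
            for (int dy = 0; dy < block; ++dy)
              acc += arr[(y * block + dy) +
                         (size_t)ny * ((x * block + dx) +
                                       (size_t)nx * (z * block + dz))];
        out[y + (size_t)oy * (x + (size_t)ox * z)] =
          acc / ((double)block * block * block);
      }
  out.attr("dim") = IntegerVector::create(oy, ox, oz);
  return out;
}

// Linear interpolation along the plane (z) axis onto `nz_out` planes whose
// positions in input-plane units are given by `zpos` (0-based, fractional).
// [[Rcpp::export]]
NumericVector interp_planes_cpp(NumericVector arr, IntegerVector dims,
                                NumericVector zpos) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int nz_out = zpos.size();
  NumericVector out((size_t)ny * nx * nz_out);
  for (int zo = 0; zo < nz_out; ++zo) {
    double p = zpos[zo];
    if (p < 0) p = 0;
    if (p > nz - 1) p = nz - 1;
    const int z0 = (int)std::floor(p);
    const int z1 = std::min(z0 + 1, nz - 1);
    const double w1 = p - z0, w0 = 1.0 - w1;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        out[y + (size_t)ny * (x + (size_t)nx * zo)] =
          w0 * arr[y + (size_t)ny * (x + (size_t)nx * z0)] +
          w1 * arr[y + (size_t)ny * (x + (size_t)nx * z1)];
  }
  out.attr("dim") = IntegerVector::create(ny, nx, nz_out);
  return out;
}
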