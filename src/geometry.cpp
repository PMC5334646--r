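#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Incremental 3D Delaunay triangulation (Bowyer-Watson with a super-
// tetrahedron, visibility-walk point location and BFS cavity search).
// Double-precision predicates with relative tolerances; callers jitter
// degenerate (gridded/cospherical) inputs, as documented.
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];   // vertex indices
  int nb[4];  // nb[f] = tet sharing the face opposite v[f], -1 if none
  bool alive;
};

static inline double orient3d(const double* pa, const double* pb,
                              const double* pc, const double* pd) {
  const double adx = pa[0] - pd[0], ady = pa[1] - pd[1], adz = pa[2] - pd[2];
  const double bdx = pb[0] - pd[0], bdy = pb[1] - pd[1], bdz = pb[2] - pd[2];
  const double cdx = pc[0] - pd[0], cdy = pc[1] - pd[1], cdz = pc[2] - pd[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// > 0 when pe lies inside the circumsphere of positively oriented
// (pa, pb, pc, pd); magnitude estimate returned via `perm` for tolerancing.
static inline double insphere(const double* pa, const double* pb,
                              const double* pc, const double* pd,
                              const double* pe, double& perm) {
  const double aex = pa[0] - pe[0], aey = pa[1] - pe[1], aez = pa[2] - pe[2];
  const double bex = pb[0] - pe[0], bey = pb[1] - pe[1], bez = pb[2] - pe[2];
  const double cex = pc[0] - pe[0], cey = pc[1] - pe[1], cez = pc[2] - pe[2];
  const double dex = pd[0] - pe[0], dey = pd[1] - pe[1], dez = pd[2] - pe[2];
  const double alift = aex * aex + aey * aey + aez * aez;
  const double blift = bex * bex + bey * bey + bez * bez;
  const double clift = cex * cex + cey * cey + cez * cez;
  const double dlift = dex * dex + dey * dey + dez * dez;
  const double ab = aex * bey - bex * aey, ac = aex * cey - cex * aey;
  const double ad = aex * dey - dex * aey, bc = bex * cey - cex * bey;
  const double bd = bex * dey - dex * bey, cd = cex * dey - dex * cey;
  const double abc = aez * bc - bez * ac + cez * ab;
  const double abd = aez * bd - bez * ad + dez * ab;
  const double acd = aez * cd - cez * ad + dez * ac;
  const double bcd = bez * cd - cez * bd + dez * bc;
  perm = std::fabs(alift * bcd) + std::fabs(blift * acd) +
         std::fabs(clift * abd) + std::fabs(dlift * abc);
  return (dlift * abc - clift * abd) + (blift * acd - alift * bcd);
}

class Delaunay3 {
public:
  std::vector<std::array<double,3>> pts; // input points then 4 super vertices
  std::vector<Tet> tets;
  int n_input;
  int last_tet = 0;

  const double* P(int i) const { return pts[i].data(); }

  void init_super(const NumericMatrix& input) {
    n_input = input.nrow();
    pts.resize(n_input + 4);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n_input; ++i)
      for (int k = 0; k < 3; ++k) {
        pts[i][k] = input(i, k);
        lo[k] = std::min(lo[k], pts[i][k]);
        hi[k] = std::max(hi[k], pts[i][k]);
      }
    double c[3], span = 1.0;
    for (int k = 0; k < 3; ++k) {
      c[k] = 0.5 * (lo[k] + hi[k]);
      span = std::max(span, hi[k] - lo[k]);
    }
    const double s = 60.0 * span;  // inscribed sphere radius s/3 >> span
    const double sv[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 3; ++k)
        pts[n_input + j][k] = c[k] + s * sv[j][k];
    Tet t0;
    t0.v[0] = n_input; t0.v[1] = n_input + 1;
    t0.v[2] = n_input + 2; t0.v[3] = n_input + 3;
    if (orient3d(P(t0.v[0]), P(t0.v[1]), P(t0.v[2]), P(t0.v[3])) < 0)
      std::swap(t0.v[2], t0.v[3]);
    t0.nb[0] = t0.nb[1] = t0.nb[2] = t0.nb[3] = -1;
    t0.alive = true;
    tets.push_back(t0);
  }

  bool in_sphere(int t, int p) const {
    double perm;
    const Tet& T = tets[t];
    const double det =
        insphere(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3]), P(p), perm);
    return det > 1e-12 * perm;
  }

  // visibility walk; returns a tet containing p (or -1 on failure)
  int locate(int p) {
    int t = last_tet;
    if (t < 0 || t >= (int)tets.size() || !tets[t].alive) {
      t = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive) { t = i; break; }
      if (t < 0) return -1;
    }
    const size_t max_steps = 4 * tets.size() + 64;
    for (size_t step = 0; step < max_steps; ++step) {
      const Tet& T = tets[t];
      int move_to = -1;
      for (int f = 0; f < 4; ++f) {
        // replace vertex f by p; negative orientation => p beyond face f
        const double* q[4];
        for (int j = 0; j < 4; ++j) q[j] = P(T.v[j]);
        q[f] = P(p);
        if (orient3d(q[0], q[1], q[2], q[3]) < 0) {
          if (T.nb[f] >= 0) { move_to = T.nb[f]; break; }
        }
      }
      if (move_to < 0) return t;
      t = move_to;
    }
    // walk cycled (near-degenerate); fall back to exhaustive insphere scan
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && in_sphere(i, p)) return i;
    return -1;
  }

  void insert(int p) {
    const int t0 = locate(p);
    if (t0 < 0) stop("Delaunay point location failed (degenerate input?)");
    // cavity: BFS over tets whose circumsphere contains p
    std::vector<int> cavity;
    std::vector<char> in_cavity(tets.size(), 0);
    std::vector<int> stack{t0};
    if (!in_sphere(t0, p)) {
      // containing tet must be in the cavity; force it
    }
    in_cavity[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        const int nb = tets[t].nb[f];
        if (nb >= 0 && !in_cavity[nb] && in_sphere(nb, p)) {
          in_cavity[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces -> new tets
    struct BFace { int a, b, c, outside, out_face; };
    std::vector<BFace> faces;
    for (int t : cavity) {
      for (int f = 0; f < 4; ++f) {
        const int nb = tets[t].nb[f];
        if (nb >= 0 && in_cavity[nb]) continue;
        int fv[3], k = 0;
        for (int j = 0; j < 4; ++j)
          if (j != f) fv[k++] = tets[t].v[j];
        int out_face = -1;
        if (nb >= 0) {
          for (int j = 0; j < 4; ++j)
            if (tets[nb].nb[j] == t) { out_face = j; break; }
        }
        faces.push_back({fv[0], fv[1], fv[2], nb, out_face});
      }
    }
    for (int t : cavity) tets[t].alive = false;

    std::map<std::pair<int,int>, std::pair<int,int>> edge_map; // edge -> (tet, face)
    std::vector<int> created;
    for (auto& F : faces) {
      int a = F.a, b = F.b, c = F.c;
      if (orient3d(P(p), P(a), P(b), P(c)) < 0) std::swap(b, c);
      Tet nt;
      nt.v[0] = p; nt.v[1] = a; nt.v[2] = b; nt.v[3] = c;
      nt.nb[0] = F.outside; // face opposite p is the old boundary face
      nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      nt.alive = true;
      const int ti = (int)tets.size();
      tets.push_back(nt);
      created.push_back(ti);
      if (F.outside >= 0 && F.out_face >= 0) tets[F.outside].nb[F.out_face] = ti;
      // stitch faces containing p: opposite vertex is one of a/b/c,
      // keyed by the remaining boundary edge
      const int vv[4] = {p, a, b, c};
      for (int f = 1; f < 4; ++f) {
        int e[2], k = 0;
        for (int j = 1; j < 4; ++j)
          if (j != f) e[k++] = vv[j];
        const std::pair<int,int> key(std::min(e[0], e[1]), std::max(e[0], e[1]));
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = {ti, f};
        } else {
          tets[ti].nb[f] = it->second.first;
          tets[it->second.first].nb[it->second.second] = ti;
          edge_map.erase(it);
        }
      }
    }
    if (!created.empty()) last_tet = created.back();
  }
};

// [[Rcpp::export]]
IntegerMatrix delaunay3d_cpp(NumericMatrix points) {
  if (points.nrow() < 4) stop("need at least 4 points");
  Delaunay3 D;
  D.init_super(points);
  for (int i = 0; i < points.nrow(); ++i) D.insert(i);
  std::vector<std::array<int,4>> keep;
  for (auto& t : D.tets) {
    if (!t.alive) continue;
    bool super = false;
    for (int j = 0; j < 4; ++j)
      if (t.v[j] >= D.n_input) { super = true; break; }
    // internal orientation convention is the mirror of det[b-a;c-a;d-a] > 0;
    // swap the last two vertices so emitted tets have positive volume
    if (!super) keep.push_back({t.v[0], t.v[1], t.v[3], t.v[2]});
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int j = 0; j < 4; ++j) out((int)i, j) = keep[i][j] + 1; // 1-based
  return out;
}

// Circumcenter/radius and signed volume of each tetrahedron.
// [[Rcpp::export]]
List tet_circum_cpp(NumericMatrix points, IntegerMatrix tets) {
  const int n = tets.nrow();
  NumericVector radius(n), volume(n);
  NumericMatrix center(n, 3);
  for (int i = 0; i < n; ++i) {
    double a[3], b[3], c[3], d[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = points(tets(i, 0) - 1, k);
      b[k] = points(tets(i, 1) - 1, k) - a[k];
      c[k] = points(tets(i, 2) - 1, k) - a[k];
      d[k] = points(tets(i, 3) - 1, k) - a[k];
    }
    const double det =
        b[0] * (c[1] * d[2] - c[2] * d[1]) -
        b[1] * (c[0] * d[2] - c[2] * d[0]) +
        b[2] * (c[0] * d[1] - c[1] * d[0]);
    volume[i] = det / 6.0;
    const double bb = b[0]*b[0] + b[1]*b[1] + b[2]*b[2];
    const double cc = c[0]*c[0] + c[1]*c[1] + c[2]*c[2];
    const double dd = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (std::fabs(det) < 1e-300) {
      radius[i] = R_PosInf;
      for (int k = 0; k < 3; ++k) center(i, k) = NA_REAL;
      continue;
    }
    // circumcenter relative to a: solves 2 M x = (bb, cc, dd)
    const double ux = (bb * (c[1] * d[2] - c[2] * d[1]) -
                       cc * (b[1] * d[2] - b[2] * d[1]) +
                       dd * (b[1] * c[2] - b[2] * c[1])) / (2.0 * det);
    const double uy = -(bb * (c[0] * d[2] - c[2] * d[0]) -
                        cc * (b[0] * d[2] - b[2] * d[0]) +
                        dd * (b[0] * c[2] - b[2] * c[0])) / (2.0 * det);
    const double uz = (bb * (c[0] * d[1] - c[1] * d[0]) -
                       cc * (b[0] * d[1] - b[1] * d[0]) +
                       dd * (b[0] * c[1] - b[1] * c[0])) / (2.0 * det);
    radius[i] = std::sqrt(ux * ux + uy * uy + uz * uz);
    center(i, 0) = a[0] + ux;
    center(i, 1) = a[1] + uy;
    center(i, 2) = a[2] + uz;
  }
  return List::create(_["radius"] = radius, _["volume"] = volume,
                      _["center"] = center);
}

// ---------------------------------------------------------------------------
// Point-to-triangle-mesh distance (Ericson's closest-point-on-triangle).
// ---------------------------------------------------------------------------

static double point_triangle_dist2(const double* p, const double* a,
                                   const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  auto dist2_to = [&](double qx, double qy, double qz) {
    const double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
    return dx*dx + dy*dy + dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2_to(a[0], a[1], a[2]);
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2_to(b[0], b[1], b[2]);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    return dist2_to(a[0] + v*ab[0], a[1] + v*ab[1], a[2] + v*ab[2]);
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2_to(c[0], c[1], c[2]);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    return dist2_to(a[0] + w*ac[0], a[1] + w*ac[1], a[2] + w*ac[2]);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2_to(b[0] + w*(c[0]-b[0]), b[1] + w*(c[1]-b[1]),
                    b[2] + w*(c[2]-b[2]));
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  return dist2_to(a[0] + ab[0]*v + ac[0]*w, a[1] + ab[1]*v + ac[1]*w,
                  a[2] + ab[2]*v + ac[2]*w);
}

// Minimum Euclidean distance from each query point to a triangle mesh.
// [[Rcpp::export]]
NumericVector point_mesh_dist_cpp(NumericMatrix query, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  if (nf == 0) stop("empty mesh");
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double p[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double a[3] = {verts(faces(f,0)-1, 0), verts(faces(f,0)-1, 1),
                           verts(faces(f,0)-1, 2)};
      const double b[3] = {verts(faces(f,1)-1, 0), verts(faces(f,1)-1, 1),
                           verts(faces(f,1)-1, 2)};
      const double c[3] = {verts(faces(f,2)-1, 0), verts(faces(f,2)-1, 1),
                           verts(faces(f,2)-1, 2)};
      const double d2 = point_triangle_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random cell position (RCP) sampler: points uniform in an alpha-shape solid
// (tetrahedron picked proportional to volume, then uniform barycentric
// coordinates), rejected until all pairwise distances >= min_dist.
// Uses R's RNG so set.seed() controls reproducibility.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix rcp_pack_cpp(NumericMatrix verts, IntegerMatrix tets,
                           NumericVector cum_vol, int n, double min_dist,
                           int max_attempts) {
  RNGScope scope;
  const double total = cum_vol[cum_vol.size() - 1];
  const double md2 = min_dist * min_dist;
  NumericMatrix out(n, 3);
  // spatial hash grid of accepted points, cell size = min_dist
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < verts.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], verts(i, k));
      hi[k] = std::max(hi[k], verts(i, k));
    }
  const double cell = std::max(min_dist, 1e-9);
  int gdim[3];
  for (int k = 0; k < 3; ++k)
    gdim[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell));
  std::vector<std::vector<int>> grid((size_t)gdim[0] * gdim[1] * gdim[2]);
  auto cell_of = [&](const double* p, int* c) {
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)std::floor((p[k] - lo[k]) / cell);
      if (c[k] < 0) c[k] = 0;
      if (c[k] >= gdim[k]) c[k] = gdim[k] - 1;
    }
  };
  for (int i = 0; i < n; ++i) {
    int attempts = 0;
    for (;;) {
      if (++attempts > max_attempts)
        stop("sphere packing infeasible after %d rejections (placed %d of %d)",
             max_attempts, i, n);
      // pick tetrahedron proportional to volume
      const double u = unif_rand() * total;
      int t = (int)(std::lower_bound(cum_vol.begin(), cum_vol.end(), u) -
                    cum_vol.begin());
      if (t >= tets.nrow()) t = tets.nrow() - 1;
      // uniform barycentric sample (fold method)
      double s = unif_rand(), tt = unif_rand(), uu = unif_rand();
      if (s + tt > 1) { s = 1 - s; tt = 1 - tt; }
      if (tt + uu > 1) { const double tmp = uu; uu = 1 - s - tt; tt = 1 - tmp; }
      else if (s + tt + uu > 1) { const double tmp = uu; uu = s + tt + uu - 1; s = 1 - tt - tmp; }
      const double a4 = 1 - s - tt - uu;
      double p[3];
      for (int k = 0; k < 3; ++k)
        p[k] = a4 * verts(tets(t, 0) - 1, k) + s * verts(tets(t, 1) - 1, k) +
               tt * verts(tets(t, 2) - 1, k) + uu * verts(tets(t, 3) - 1, k);
      // non-overlap check against neighbors in the hash grid
      int c[3];
      cell_of(p, c);
      bool ok = true;
      for (int dz = -1; dz <= 1 && ok; ++dz)
        for (int dx = -1; dx <= 1 && ok; ++dx)
          for (int dy = -1; dy <= 1 && ok; ++dy) {
            const int cy = c[0] + dy, cx = c[1] + dx, cz = c[2] + dz;
            if (cy < 0 || cy >= gdim[0] || cx < 0 || cx >= gdim[1] ||
                cz < 0 || cz >= gdim[2]) continue;
            for (int j : grid[cy + (size_t)gdim[0] * (cx + (size_t)gdim[1] * cz)]) {
              const double ddx = p[0] - out(j, 0), ddy = p[1] - out(j, 1),
                           ddz = p[2] - out(j, 2);
              if (ddx*ddx + ddy*ddy + ddz*ddz < md2) { ok = false; break; }
            }
          }
      if (!ok) continue;
      out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
      grid[c[0] + (size_t)gdim[0] * (c[1] + (size_t)gdim[1] * c[2])].push_back(i);
      break;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sphere rasterizer for the synthetic phantom generator: each nucleus is a
// solid ball with a radial intensity falloff; intensities combine by max.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector render_nuclei_cpp(IntegerVector dims, NumericMatrix centers,
                                NumericVector radii, NumericVector peak,
                                double falloff) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  NumericVector out((size_t)ny * nx * nz, 0.0);
  for (int i = 0; i < centers.nrow(); ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    const double r = radii[i], r2 = r * r;
    const int x0 = std::max(0, (int)std::floor(cx - r)),
              x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    const int y0 = std::max(0, (int)std::floor(cy - r)),
              y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    const int z0 = std::max(0, (int)std::floor(cz - r)),
              z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    for (int z = z0; z <= z1; ++z)
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          const double dx = x - cx, dy = y - cy, dz = z - cz;
          const double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 > r2) continue;
          const double v = peak[i] * (1.0 - falloff * (d2 / r2));
          double& o = out[y + (size_t)ny * (x + (size_t)nx * z)];
          if (v > o) o = v;
        }
  }
  out.attr("dim") = dims;
  return out;
}

// Count of voxels inside a rasterized ball (oracle helper for tests lives in
// R; this renderer is also used to build reference label volumes).
// [[Rcpp::export]]
IntegerVector render_labels_cpp(IntegerVector dims, NumericMatrix centers,
                                NumericVector radii) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector out((size_t)ny * nx * nz, 0);
  // nearer center wins where balls overlap
  std::vector<double> best((size_t)ny * nx * nz, R_PosInf);
  for (int i = 0; i < centers.nrow(); ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    const double r = radii[i], r2 = r * r;
    const int x0 = std::max(0, (int)std::floor(cx - r)),
              x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    const int y0 = std::max(0, (int)std::floor(cy - r)),
              y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    const int z0 = std::max(0, (int)std::floor(cz - r)),
              z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    for (int z = z0; z <= z1; ++z)
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          const double dx = x - cx, dy = y - cy, dz = z - cz;
          const double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 > r2) continue;
          const size_t idx = y + (size_t)ny * (x + (size_t)nx * z);
          if (d2 < best[idx]) { best[idx] = d2; out[idx] = i + 1; }
        }
  }
  out.attr("dim") = dims;
  return out;
}
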