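// Low-level geometry kernels: parity voxelization, grid-accelerated ray
// casting, voxel boundary surfacing, 3D squared Euclidean distance transform,
// flood fill, single-linkage point clustering, nearest-neighbour and
// point-to-surface queries. All distances in mm, masks are column-major
// logical arrays matching R's array layout.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const double kColEps = 1.6180339887e-7; // irrational nudge against edge ties

// ---------------------------------------------------------------------------
// Parity voxelization along one axis.
//
// Voxel (i,j,k) (0-based) centre = origin + (idx + 0.5) * pitch per axis.
// For each column perpendicular to `axis`, triangle crossings are collected
// via 2D barycentric inclusion of the column point in the projected triangle;
// voxel centres between odd/even crossing pairs are inside. Degenerate
// (edge-on) triangles project to zero area and are skipped; for watertight
// meshes the remaining crossings have even parity almost surely (column
// points are nudged off lattice-aligned edges).
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, IntegerVector dims,
                           double pitch, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox, false);

  // u, v span the column plane; a is the casting axis
  int a = axis, u = (axis + 1) % 3, v = (axis + 2) % 3;
  int ndim[3] = {nx, ny, nz};
  const int nu = ndim[u], nv = ndim[v], na = ndim[a];
  const double ou = origin[u], ov = origin[v], oa = origin[a];

  std::vector<std::vector<double>> cols((size_t)nu * nv);

  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    const double au_ = V(i0, u), av_ = V(i0, v), aa_ = V(i0, a);
    const double bu_ = V(i1, u), bv_ = V(i1, v), ba_ = V(i1, a);
    const double cu_ = V(i2, u), cv_ = V(i2, v), ca_ = V(i2, a);

    const double d1u = bu_ - au_, d1v = bv_ - av_;
    const double d2u = cu_ - au_, d2v = cv_ - av_;
    const double det = d1u * d2v - d1v * d2u;
    if (std::fabs(det) < 1e-12) continue; // edge-on: measure-zero column set

    const double minu = std::min(au_, std::min(bu_, cu_));
    const double maxu = std::max(au_, std::max(bu_, cu_));
    const double minv = std::min(av_, std::min(bv_, cv_));
    const double maxv = std::max(av_, std::max(bv_, cv_));

    int iu0 = (int)std::floor((minu - ou) / pitch - 0.5);
    int iu1 = (int)std::ceil((maxu - ou) / pitch - 0.5);
    int iv0 = (int)std::floor((minv - ov) / pitch - 0.5);
    int iv1 = (int)std::ceil((maxv - ov) / pitch - 0.5);
    iu0 = std::max(iu0, 0); iu1 = std::min(iu1, nu - 1);
    iv0 = std::max(iv0, 0); iv1 = std::min(iv1, nv - 1);

    for (int iu = iu0; iu <= iu1; ++iu) {
      const double pu = ou + (iu + 0.5) * pitch + kColEps * pitch;
      for (int iv = iv0; iv <= iv1; ++iv) {
        const double pv = ov + (iv + 0.5) * pitch + kColEps * pitch * 0.7320508;
        const double ru = pu - au_, rv = pv - av_;
        const double b1 = (ru * d2v - rv * d2u) / det;
        const double b2 = (d1u * rv - d1v * ru) / det;
        if (b1 < 0.0 || b2 < 0.0 || b1 + b2 > 1.0) continue;
        const double cross = aa_ + b1 * (ba_ - aa_) + b2 * (ca_ - aa_);
        cols[(size_t)iu * nv + iv].push_back(cross);
      }
    }
  }

  // strides in the column-major (nx, ny, nz) array
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int iu = 0; iu < nu; ++iu) {
    for (int iv = 0; iv < nv; ++iv) {
      std::vector<double>& cr = cols[(size_t)iu * nv + iv];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      const size_t npair = cr.size() / 2; // odd leftovers ignored (grazing)
      for (size_t p = 0; p < npair; ++p) {
        const double z0 = cr[2 * p], z1 = cr[2 * p + 1];
        int k0 = (int)std::ceil((z0 - oa) / pitch - 0.5);
        int k1 = (int)std::floor((z1 - oa) / pitch - 0.5);
        k0 = std::max(k0, 0); k1 = std::min(k1, na - 1);
        for (int k = k0; k <= k1; ++k) {
          R_xlen_t idx = (R_xlen_t)iu * stride[u] + (R_xlen_t)iv * stride[v] +
                         (R_xlen_t)k * stride[a];
          out[idx] = true;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Uniform-grid (Amanatides & Woo) accelerated ray casting.

// uniform triangle grid in compressed (CSR) layout: offsets into one flat
// index array, cheap to build and scan even at fine resolutions
struct TriGrid {
  int nc[3];
  double lo[3], cell[3];
  std::vector<int> offset;   // ncell + 1
  std::vector<int> items;    // triangle ids
  size_t cell_index(int i, int j, int k) const {
    return (size_t)i + (size_t)nc[0] * ((size_t)j + (size_t)nc[1] * k);
  }
};

static void build_tri_grid(const NumericMatrix& V, const IntegerMatrix& F,
                           TriGrid& g) {
  const int nf = F.nrow();
  double hi[3];
  for (int d = 0; d < 3; ++d) {
    g.lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      g.lo[d] = std::min(g.lo[d], V(i, d));
      hi[d] = std::max(hi[d], V(i, d));
    }
  int n = (int)std::ceil(std::cbrt(std::max(2.0 * nf, 1.0)));
  n = std::min(std::max(n, 1), 160);
  for (int d = 0; d < 3; ++d) {
    double ext = std::max(hi[d] - g.lo[d], 1e-9);
    g.lo[d] -= 1e-6 * ext + 1e-9;
    ext *= (1.0 + 2e-6); ext += 2e-9;
    g.nc[d] = n;
    g.cell[d] = ext / n;
  }
  const size_t ncell = (size_t)g.nc[0] * g.nc[1] * g.nc[2];
  std::vector<int> c0s(3 * nf), c1s(3 * nf);
  std::vector<int> counts(ncell + 1, 0);
  for (int f = 0; f < nf; ++f) {
    for (int d = 0; d < 3; ++d) {
      double a = V(F(f, 0) - 1, d), b = V(F(f, 1) - 1, d), c = V(F(f, 2) - 1, d);
      double tlo = std::min(a, std::min(b, c)), thi = std::max(a, std::max(b, c));
      c0s[3 * f + d] = std::min(std::max((int)((tlo - g.lo[d]) / g.cell[d]), 0),
                                g.nc[d] - 1);
      c1s[3 * f + d] = std::min(std::max((int)((thi - g.lo[d]) / g.cell[d]), 0),
                                g.nc[d] - 1);
    }
    for (int i = c0s[3 * f]; i <= c1s[3 * f]; ++i)
      for (int j = c0s[3 * f + 1]; j <= c1s[3 * f + 1]; ++j)
        for (int k = c0s[3 * f + 2]; k <= c1s[3 * f + 2]; ++k)
          ++counts[g.cell_index(i, j, k)];
  }
  g.offset.resize(ncell + 1);
  g.offset[0] = 0;
  for (size_t c = 0; c < ncell; ++c) g.offset[c + 1] = g.offset[c] + counts[c];
  g.items.resize(g.offset[ncell]);
  std::vector<int> cursor(g.offset.begin(), g.offset.end() - 1);
  for (int f = 0; f < nf; ++f)
    for (int i = c0s[3 * f]; i <= c1s[3 * f]; ++i)
      for (int j = c0s[3 * f + 1]; j <= c1s[3 * f + 1]; ++j)
        for (int k = c0s[3 * f + 2]; k <= c1s[3 * f + 2]; ++k)
          g.items[cursor[g.cell_index(i, j, k)]++] = f;
}

static inline bool moller_trumbore(const double* o, const double* dir,
                                   const double* a, const double* b,
                                   const double* c, double& t) {
  double e1[3], e2[3], p[3], q[3], s[3];
  for (int d = 0; d < 3; ++d) { e1[d] = b[d] - a[d]; e2[d] = c[d] - a[d]; }
  p[0] = dir[1] * e2[2] - dir[2] * e2[1];
  p[1] = dir[2] * e2[0] - dir[0] * e2[2];
  p[2] = dir[0] * e2[1] - dir[1] * e2[0];
  const double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < 1e-14) return false;
  const double inv = 1.0 / det;
  for (int d = 0; d < 3; ++d) s[d] = o[d] - a[d];
  const double uu = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (uu < -1e-10 || uu > 1.0 + 1e-10) return false;
  q[0] = s[1] * e1[2] - s[2] * e1[1];
  q[1] = s[2] * e1[0] - s[0] * e1[2];
  q[2] = s[0] * e1[1] - s[1] * e1[0];
  const double vv = (dir[0] * q[0] + dir[1] * q[1] + dir[2] * q[2]) * inv;
  if (vv < -1e-10 || uu + vv > 1.0 + 1e-10) return false;
  t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return t > 1e-9;
}

// Cast rays from per-ray origins along unit directions; returns all hits with
// 0 < t <= tmax as (ray index, t), duplicates within tol merged per ray.
// [[Rcpp::export]]
List cpp_ray_cast(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                  NumericMatrix dirs, double tmax, double dedup_tol = 1e-6) {
  TriGrid g;
  build_tri_grid(V, F, g);
  const int nray = dirs.nrow();
  std::vector<int> stamp(F.nrow(), -1);
  std::vector<double> out_t;
  std::vector<int> out_ray;
  std::vector<double> hits;

  for (int r = 0; r < nray; ++r) {
    double o[3] = {origins(origins.nrow() == 1 ? 0 : r, 0),
                   origins(origins.nrow() == 1 ? 0 : r, 1),
                   origins(origins.nrow() == 1 ? 0 : r, 2)};
    double dir[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    hits.clear();

    // clip ray to grid bounds
    double t0 = 0.0, t1 = tmax;
    bool miss = false;
    for (int d = 0; d < 3; ++d) {
      const double hi = g.lo[d] + g.nc[d] * g.cell[d];
      if (std::fabs(dir[d]) < 1e-15) {
        if (o[d] < g.lo[d] || o[d] > hi) { miss = true; break; }
      } else {
        double ta = (g.lo[d] - o[d]) / dir[d], tb = (hi - o[d]) / dir[d];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        if (t0 > t1) { miss = true; break; }
      }
    }
    if (!miss) {
      double p[3];
      for (int d = 0; d < 3; ++d) p[d] = o[d] + (t0 + 1e-12) * dir[d];
      int ci[3], step[3];
      double tMax[3], tDelta[3];
      for (int d = 0; d < 3; ++d) {
        ci[d] = std::min(std::max((int)((p[d] - g.lo[d]) / g.cell[d]), 0), g.nc[d] - 1);
        if (dir[d] > 1e-15) {
          step[d] = 1;
          tMax[d] = (g.lo[d] + (ci[d] + 1) * g.cell[d] - o[d]) / dir[d];
          tDelta[d] = g.cell[d] / dir[d];
        } else if (dir[d] < -1e-15) {
          step[d] = -1;
          tMax[d] = (g.lo[d] + ci[d] * g.cell[d] - o[d]) / dir[d];
          tDelta[d] = -g.cell[d] / dir[d];
        } else {
          step[d] = 0;
          tMax[d] = std::numeric_limits<double>::infinity();
          tDelta[d] = std::numeric_limits<double>::infinity();
        }
      }
      while (true) {
        const size_t cidx = g.cell_index(ci[0], ci[1], ci[2]);
        for (int bi = g.offset[cidx]; bi < g.offset[cidx + 1]; ++bi) {
          const int f = g.items[bi];
          if (stamp[f] == r) continue;
          stamp[f] = r;
          const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
          double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
          double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
          double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
          double t;
          if (moller_trumbore(o, dir, a, b, c, t) && t <= tmax) hits.push_back(t);
        }
        int ax = 0;
        if (tMax[1] < tMax[ax]) ax = 1;
        if (tMax[2] < tMax[ax]) ax = 2;
        if (tMax[ax] > t1) break;
        ci[ax] += step[ax];
        if (ci[ax] < 0 || ci[ax] >= g.nc[ax]) break;
        tMax[ax] += tDelta[ax];
      }
    }
    std::sort(hits.begin(), hits.end());
    double last = -1e18;
    for (double t : hits) {
      if (t - last < dedup_tol) continue;
      last = t;
      out_ray.push_back(r + 1);
      out_t.push_back(t);
    }
  }
  return List::create(_["ray"] = wrap(out_ray), _["t"] = wrap(out_t));
}

// ---------------------------------------------------------------------------
// Repair diagonal edge contacts in a voxel mask: where two voxels meet only
// along an edge (their two common orthogonal neighbours empty), the boundary
// surface would carry a non-manifold edge; fill one common neighbour. Repeats
// until stable (filling is monotone, so this terminates).
// [[Rcpp::export]]
LogicalVector cpp_fix_diagonal_edges(LogicalVector mask_in, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask = clone(mask_in);
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  bool changed = true;
  while (changed) {
    changed = false;
    // edges along z: 2x2 neighbourhood in (x, y)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j + 1 < ny; ++j)
        for (int i = 0; i + 1 < nx; ++i) {
          bool a = mask[idx(i, j, k)], b = mask[idx(i + 1, j + 1, k)];
          bool c = mask[idx(i + 1, j, k)], d = mask[idx(i, j + 1, k)];
          if (a && b && !c && !d) { mask[idx(i + 1, j, k)] = true; changed = true; }
          else if (c && d && !a && !b) { mask[idx(i, j, k)] = true; changed = true; }
        }
    // edges along y: 2x2 in (x, z)
    for (int k = 0; k + 1 < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i + 1 < nx; ++i) {
          bool a = mask[idx(i, j, k)], b = mask[idx(i + 1, j, k + 1)];
          bool c = mask[idx(i + 1, j, k)], d = mask[idx(i, j, k + 1)];
          if (a && b && !c && !d) { mask[idx(i + 1, j, k)] = true; changed = true; }
          else if (c && d && !a && !b) { mask[idx(i, j, k)] = true; changed = true; }
        }
    // edges along x: 2x2 in (y, z)
    for (int k = 0; k + 1 < nz; ++k)
      for (int j = 0; j + 1 < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          bool a = mask[idx(i, j, k)], b = mask[idx(i, j + 1, k + 1)];
          bool c = mask[idx(i, j + 1, k)], d = mask[idx(i, j, k + 1)];
          if (a && b && !c && !d) { mask[idx(i, j + 1, k)] = true; changed = true; }
          else if (c && d && !a && !b) { mask[idx(i, j, k)] = true; changed = true; }
        }
  }
  mask.attr("dim") = dims;
  return mask;
}

// ---------------------------------------------------------------------------
// Boundary-face surfacing of a voxel mask (watertight, outward-oriented).
// [[Rcpp::export]]
List cpp_voxel_surface(LogicalVector mask, IntegerVector dims,
                       NumericVector origin, double pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<int64_t, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  const int64_t sx = 1, sy = (int64_t)(nx + 1), sz = (int64_t)(nx + 1) * (ny + 1);

  auto corner = [&](int i, int j, int k) -> int {
    int64_t key = i * sx + j * sy + k * sz;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid.emplace(key, id);
    vx.push_back(origin[0] + i * pitch);
    vy.push_back(origin[1] + j * pitch);
    vz.push_back(origin[2] + k * pitch);
    return id;
  };
  auto quad = [&](int a, int b, int c, int d) {
    fa.push_back(a + 1); fb.push_back(b + 1); fc.push_back(c + 1);
    fa.push_back(a + 1); fb.push_back(c + 1); fc.push_back(d + 1);
  };
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)];
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        if (!at(i + 1, j, k)) // +x face, CCW from +x
          quad(corner(i + 1, j, k), corner(i + 1, j + 1, k),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j, k + 1));
        if (!at(i - 1, j, k)) // -x face
          quad(corner(i, j, k), corner(i, j, k + 1),
               corner(i, j + 1, k + 1), corner(i, j + 1, k));
        if (!at(i, j + 1, k)) // +y face
          quad(corner(i, j + 1, k), corner(i, j + 1, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j + 1, k));
        if (!at(i, j - 1, k)) // -y face
          quad(corner(i, j, k), corner(i + 1, j, k),
               corner(i + 1, j, k + 1), corner(i, j, k + 1));
        if (!at(i, j, k + 1)) // +z face
          quad(corner(i, j, k + 1), corner(i + 1, j, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i, j + 1, k + 1));
        if (!at(i, j, k - 1)) // -z face
          quad(corner(i, j, k), corner(i, j + 1, k),
               corner(i + 1, j + 1, k), corner(i + 1, j, k));
      }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  const int nf = (int)fa.size();
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = fa[i]; F(i, 1) = fb[i]; F(i, 2) = fc[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Squared EDT (Felzenszwalb & Huttenlocher), distance to nearest TRUE voxel,
// in voxel units squared; multiply by pitch^2 in R.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      edt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      edt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  // z pass
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * sz];
      edt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * sz] = d[k];
    }
  D.attr("dim") = dims;
  return D;
}

// ---------------------------------------------------------------------------
// Background voxels 6-connected to the grid boundary (for cavity filling).
// [[Rcpp::export]]
LogicalVector cpp_outside_background(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<R_xlen_t> stack;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!mask[id] && !out[id]) { out[id] = true; stack.push_back(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { push(i, j, 0); push(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { push(i, 0, k); push(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { push(0, j, k); push(nx - 1, j, k); }
  while (!stack.empty()) {
    R_xlen_t id = stack.back(); stack.pop_back();
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((R_xlen_t)nx * ny));
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Label 6-connected components of a voxel mask (0 = background, 1..n labels).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t id = stack.back(); stack.pop_back();
      int i = (int)(id % nx), j = (int)((id / nx) % ny),
          k = (int)(id / ((R_xlen_t)nx * ny));
      auto visit = [&](int ii, int jj, int kk) {
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          return;
        R_xlen_t v = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
        if (mask[v] && lab[v] == 0) { lab[v] = next; stack.push_back(v); }
      };
      visit(i - 1, j, k); visit(i + 1, j, k);
      visit(i, j - 1, k); visit(i, j + 1, k);
      visit(i, j, k - 1); visit(i, j, k + 1);
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Single-linkage clustering: connected components of the graph linking points
// closer than `radius`, via spatial hashing + union-find.
struct UnionFind {
  std::vector<int> p;
  UnionFind(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// [[Rcpp::export]]
IntegerVector cpp_cluster_points(NumericMatrix P, double radius) {
  const int n = P.nrow();
  IntegerVector lab(n);
  if (n == 0) return lab;
  const double cell = radius;
  std::unordered_map<int64_t, std::vector<int>> hash;
  auto key = [&](int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  };
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(P(i, 0) / cell);
    cy[i] = (int)std::floor(P(i, 1) / cell);
    cz[i] = (int)std::floor(P(i, 2) / cell);
    hash[key(cx[i], cy[i], cz[i])].push_back(i);
  }
  UnionFind uf(n);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = hash.find(key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == hash.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            const double ddx = P(i, 0) - P(j, 0), ddy = P(i, 1) - P(j, 1),
                         ddz = P(i, 2) - P(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) uf.unite(i, j);
          }
        }
  }
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared distance from a point to a triangle, with the closest point
// written to `out` (Ericson's region decomposition).
static double point_tri_dist2(const double* p, const double* a, const double* b,
                              const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) { ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d]; }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2to = [&](double wx, double wy, double wz) {
    out[0] = wx; out[1] = wy; out[2] = wz;
    const double dx = p[0] - wx, dy = p[1] - wy, dz = p[2] - wz;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2to(a[0], a[1], a[2]);
  double bp[3];
  for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2to(b[0], b[1], b[2]);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    return dist2to(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3];
  for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2to(c[0], c[1], c[2]);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    return dist2to(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2to(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                   b[2] + w * (c[2] - b[2]));
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  return dist2to(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                 a[2] + ab[2] * v + ac[2] * w);
}

// ---------------------------------------------------------------------------
// Bounding-volume hierarchy over triangles for closest-point queries:
// best-first descent with axis-aligned-box distance pruning stays fast for
// query points far from the surface, where uniform grids degrade.
struct BvhNode {
  double lo[3], hi[3];
  int left, right;    // children, or -1 for leaf
  int begin, end;     // triangle range in `order` for leaves
};

struct TriBvh {
  std::vector<BvhNode> nodes;
  std::vector<int> order;
};

static void bvh_build_node(const std::vector<double>& cx,
                           const std::vector<double>& cy,
                           const std::vector<double>& cz,
                           const std::vector<double>& tlo,
                           const std::vector<double>& thi, TriBvh& bvh,
                           int begin, int end, int node_id) {
  BvhNode& nd = bvh.nodes[node_id];
  for (int d = 0; d < 3; ++d) {
    nd.lo[d] = std::numeric_limits<double>::infinity();
    nd.hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = begin; i < end; ++i) {
    const int f = bvh.order[i];
    for (int d = 0; d < 3; ++d) {
      nd.lo[d] = std::min(nd.lo[d], tlo[3 * f + d]);
      nd.hi[d] = std::max(nd.hi[d], thi[3 * f + d]);
    }
  }
  if (end - begin <= 8) {
    nd.left = nd.right = -1;
    nd.begin = begin; nd.end = end;
    return;
  }
  int axis = 0;
  double ext = nd.hi[0] - nd.lo[0];
  for (int d = 1; d < 3; ++d)
    if (nd.hi[d] - nd.lo[d] > ext) { ext = nd.hi[d] - nd.lo[d]; axis = d; }
  const std::vector<double>& cc = axis == 0 ? cx : (axis == 1 ? cy : cz);
  int mid = (begin + end) / 2;
  std::nth_element(bvh.order.begin() + begin, bvh.order.begin() + mid,
                   bvh.order.begin() + end,
                   [&](int a, int b) { return cc[a] < cc[b]; });
  // note: push_back may reallocate, so never touch `nd` afterwards
  const int l = (int)bvh.nodes.size();
  const int r = l + 1;
  bvh.nodes.push_back(BvhNode());
  bvh.nodes.push_back(BvhNode());
  bvh.nodes[node_id].begin = bvh.nodes[node_id].end = -1;
  bvh.nodes[node_id].left = l;
  bvh.nodes[node_id].right = r;
  bvh_build_node(cx, cy, cz, tlo, thi, bvh, begin, mid, l);
  bvh_build_node(cx, cy, cz, tlo, thi, bvh, mid, end, r);
}

static void build_tri_bvh(const NumericMatrix& V, const IntegerMatrix& F,
                          TriBvh& bvh) {
  const int nf = F.nrow();
  std::vector<double> cx(nf), cy(nf), cz(nf), tlo(3 * nf), thi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int d = 0; d < 3; ++d) {
      double a = V(F(f, 0) - 1, d), b = V(F(f, 1) - 1, d),
             c = V(F(f, 2) - 1, d);
      tlo[3 * f + d] = std::min(a, std::min(b, c));
      thi[3 * f + d] = std::max(a, std::max(b, c));
    }
    cx[f] = (tlo[3 * f] + thi[3 * f]) / 2;
    cy[f] = (tlo[3 * f + 1] + thi[3 * f + 1]) / 2;
    cz[f] = (tlo[3 * f + 2] + thi[3 * f + 2]) / 2;
  }
  bvh.order.resize(nf);
  for (int f = 0; f < nf; ++f) bvh.order[f] = f;
  bvh.nodes.clear();
  bvh.nodes.reserve(2 * nf / 8 + 16);
  bvh.nodes.push_back(BvhNode());
  if (nf > 0) bvh_build_node(cx, cy, cz, tlo, thi, bvh, 0, nf, 0);
}

static inline double box_dist2(const BvhNode& nd, const double* p) {
  double s = 0;
  for (int d = 0; d < 3; ++d) {
    double v = 0;
    if (p[d] < nd.lo[d]) v = nd.lo[d] - p[d];
    else if (p[d] > nd.hi[d]) v = p[d] - nd.hi[d];
    s += v * v;
  }
  return s;
}

// Closest surface point and distance for each query point.
static List point_mesh_closest_impl(const NumericMatrix& Q,
                                    const NumericMatrix& V,
                                    const IntegerMatrix& F, const TriBvh& bvh) {
  const int nq = Q.nrow();
  NumericVector out(nq);
  NumericMatrix CP(nq, 3);
  std::vector<std::pair<double, int>> stack;
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    double bestpt[3] = {0, 0, 0};
    double best = std::numeric_limits<double>::infinity();
    if (bvh.order.empty()) { out[q] = best; continue; }
    stack.clear();
    stack.emplace_back(box_dist2(bvh.nodes[0], p), 0);
    while (!stack.empty()) {
      auto top = stack.back();
      stack.pop_back();
      if (top.first >= best) continue;
      const BvhNode& nd = bvh.nodes[top.second];
      if (nd.left < 0) {
        for (int i = nd.begin; i < nd.end; ++i) {
          const int f = bvh.order[i];
          const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
          double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
          double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
          double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
          double pt[3];
          double d2 = point_tri_dist2(p, a, b, c, pt);
          if (d2 < best) {
            best = d2;
            bestpt[0] = pt[0]; bestpt[1] = pt[1]; bestpt[2] = pt[2];
          }
        }
      } else {
        double dl = box_dist2(bvh.nodes[nd.left], p);
        double dr = box_dist2(bvh.nodes[nd.right], p);
        // push the farther child first so the nearer is explored next
        if (dl < dr) {
          if (dr < best) stack.emplace_back(dr, nd.right);
          if (dl < best) stack.emplace_back(dl, nd.left);
        } else {
          if (dl < best) stack.emplace_back(dl, nd.left);
          if (dr < best) stack.emplace_back(dr, nd.right);
        }
      }
    }
    out[q] = std::sqrt(best);
    CP(q, 0) = bestpt[0]; CP(q, 1) = bestpt[1]; CP(q, 2) = bestpt[2];
  }
  return List::create(_["distance"] = out, _["point"] = CP);
}

// [[Rcpp::export]]
List cpp_point_mesh_closest(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  TriBvh bvh;
  build_tri_bvh(V, F, bvh);
  return point_mesh_closest_impl(Q, V, F, bvh);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  List res = cpp_point_mesh_closest(Q, V, F);
  return res["distance"];
}

// Persistent acceleration structure for repeated closest-point queries
// against one mesh (the hierarchy build dominates one-shot query cost).
struct MeshGridHandle {
  NumericMatrix V;
  IntegerMatrix F;
  TriBvh bvh;
};

// [[Rcpp::export]]
SEXP cpp_mesh_grid_build(NumericMatrix V, IntegerMatrix F) {
  MeshGridHandle* h = new MeshGridHandle{V, F, TriBvh()};
  build_tri_bvh(h->V, h->F, h->bvh);
  return XPtr<MeshGridHandle>(h, true);
}

// [[Rcpp::export]]
List cpp_mesh_grid_closest(SEXP handle, NumericMatrix Q) {
  XPtr<MeshGridHandle> h(handle);
  return point_mesh_closest_impl(Q, h->V, h->F, h->bvh);
}

// ---------------------------------------------------------------------------
// Count mask voxels falling in each acetabular region (dominant-axis sectors
// truncated at their radial extents, medial-wall cylinder, excision ball).
// Returns counts: superior, anterior, posterior, medial_wall, ball.
// [[Rcpp::export]]
NumericVector cpp_region_counts(LogicalVector mask, IntegerVector dims,
                                NumericVector origin, double pitch,
                                NumericVector hjc, NumericVector sup_ax,
                                NumericVector ant_ax, NumericVector pol_ax,
                                double radius, NumericVector factors,
                                double medial_len, double ball_factor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double n_sup = 0, n_ant = 0, n_post = 0, n_med = 0, n_ball = 0;
  const double r_sup = factors[0] * radius, r_ant = factors[1] * radius,
               r_post = factors[2] * radius, r_med = factors[3] * radius,
               r_ball = ball_factor * radius, z_med = medial_len * radius;
  R_xlen_t id = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + (k + 0.5) * pitch - hjc[2];
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + (j + 0.5) * pitch - hjc[1];
      for (int i = 0; i < nx; ++i, ++id) {
        if (!mask[id]) continue;
        const double x = origin[0] + (i + 0.5) * pitch - hjc[0];
        const double su = x * sup_ax[0] + y * sup_ax[1] + z * sup_ax[2];
        const double an = x * ant_ax[0] + y * ant_ax[1] + z * ant_ax[2];
        const double po = x * pol_ax[0] + y * pol_ax[1] + z * pol_ax[2];
        const double rho2 = x * x + y * y + z * z;
        if (su >= std::fabs(an) && su > 0 && rho2 <= r_sup * r_sup) ++n_sup;
        if (an >= std::fabs(su) && an > 0 && rho2 <= r_ant * r_ant) ++n_ant;
        if (-an >= std::fabs(su) && an < 0 && rho2 <= r_post * r_post) ++n_post;
        const double lat2 = rho2 - po * po;
        if (lat2 <= r_med * r_med && po <= 0 && po >= -z_med) ++n_med;
        if (rho2 <= r_ball * r_ball) ++n_ball;
      }
    }
  }
  return NumericVector::create(_["superior"] = n_sup, _["anterior"] = n_ant,
                               _["posterior"] = n_post, _["medial_wall"] = n_med,
                               _["ball"] = n_ball);
}

// ---------------------------------------------------------------------------
// Number of connected components of a triangulation (vertex connectivity).
// [[Rcpp::export]]
int cpp_mesh_components(int nv, IntegerMatrix F) {
  UnionFind uf(nv);
  for (int f = 0; f < F.nrow(); ++f) {
    uf.unite(F(f, 0) - 1, F(f, 1) - 1);
    uf.unite(F(f, 1) - 1, F(f, 2) - 1);
  }
  std::vector<bool> seen(nv, false);
  std::vector<bool> used(nv, false);
  for (int f = 0; f < F.nrow(); ++f)
    for (int d = 0; d < 3; ++d) used[F(f, d) - 1] = true;
  int n = 0;
  for (int i = 0; i < nv; ++i) {
    if (!used[i]) continue;
    int r = uf.find(i);
    if (!seen[r]) { seen[r] = true; ++n; }
  }
  return n;
}
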