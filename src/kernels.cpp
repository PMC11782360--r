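#include <Rcpp.h>
#include <queue>
#include <map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// Interpolation at fractional (1-based) voxel indices.
// order 1: trilinear; order 3: Catmull-Rom cubic convolution.
// Samples outside the grid are clamped to the nearest edge voxel.
// ---------------------------------------------------------------------------

static double catmull_w(double t, int i) {
  // weight of sample i in {-1,0,1,2} for fractional offset t in [0,1)
  double w;
  switch (i) {
  case 0: w = ((-t + 2.0) * t - 1.0) * t * 0.5; break;           // sample -1
  case 1: w = ((3.0 * t - 5.0) * t * t + 2.0) * 0.5; break;      // sample 0
  case 2: w = (((-3.0 * t + 4.0) * t + 1.0) * t) * 0.5; break;   // sample 1
  default: w = ((t - 1.0) * t * t) * 0.5; break;                 // sample 2
  }
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector data, IntegerVector dims,
                         NumericMatrix idx, int order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double fx = idx(p, 0) - 1.0, fy = idx(p, 1) - 1.0, fz = idx(p, 2) - 1.0;
    if (order == 1) {
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
      double tx = fx - x0, ty = fy - y0, tz = fz - z0;
      double acc = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            int xi = clampi(x0 + dx, 0, nx - 1);
            int yi = clampi(y0 + dy, 0, ny - 1);
            int zi = clampi(z0 + dz, 0, nz - 1);
            double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) * (dz ? tz : 1 - tz);
            acc += w * data[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          }
      out[p] = acc;
    } else {
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
      double tx = fx - x0, ty = fy - y0, tz = fz - z0;
      double acc = 0.0;
      for (int dz = 0; dz < 4; ++dz) {
        double wz = catmull_w(tz, dz);
        int zi = clampi(z0 - 1 + dz, 0, nz - 1);
        for (int dy = 0; dy < 4; ++dy) {
          double wy = catmull_w(ty, dy);
          int yi = clampi(y0 - 1 + dy, 0, ny - 1);
          for (int dx = 0; dx < 4; ++dx) {
            double wx = catmull_w(tx, dx);
            int xi = clampi(x0 - 1 + dx, 0, nx - 1);
            acc += wx * wy * wz * data[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          }
        }
      }
      out[p] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector data, NumericMatrix idx) {
  IntegerVector dims = data.attr("dim");
  return cpp_interp(data, dims, idx, 1);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// lower envelope of parabolas), anisotropic spacing. Returns, for every
// voxel, the Euclidean distance (mm) to the nearest zero voxel of `mask`.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double diff = xq - v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(NumericVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of Inf keeps the parabola intersections
  // finite when a whole scan line is foreground
  const double BIG = 1e20;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = mask[i] != 0 ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zC = 0; zC < nz; ++zC)
    for (int yC = 0; yC < ny; ++yC) {
      R_xlen_t base = (R_xlen_t)nx * (yC + (R_xlen_t)ny * zC);
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] > 0) any = true; }
      if (!any) continue;
      dt1d(f, d, spacing[0], nx, v, z);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int zC = 0; zC < nz; ++zC)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zC)];
      dt1d(f, d, spacing[1], ny, v, z);
      for (int y = 0; y < ny; ++y) g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zC)] = d[y];
    }
  // pass along z
  for (int yC = 0; yC < ny; ++yC)
    for (int x = 0; x < nx; ++x) {
      for (int zc = 0; zc < nz; ++zc) f[zc] = g[x + (R_xlen_t)nx * (yC + (R_xlen_t)ny * zc)];
      dt1d(f, d, spacing[2], nz, v, z);
      for (int zc = 0; zc < nz; ++zc)
        g[x + (R_xlen_t)nx * (yC + (R_xlen_t)ny * zc)] = std::sqrt(d[zc]);
    }

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Fast marching solver for |grad T| F = 1 restricted to the domain F > 0.
// T(source) = 0. Second-order upwind differences are used where two accepted
// neighbours line up along an axis, and voxels within a small ball of the
// source are initialized with the exact local solution, which removes most
// of the O(h) point-source error. Unreached/outside voxels get +Inf.
// ---------------------------------------------------------------------------

struct HeapNode {
  double t;
  R_xlen_t idx;
  bool operator<(const HeapNode& o) const { return t > o.t; } // min-heap
};

// [[Rcpp::export]]
NumericVector cpp_fast_march(NumericVector speed, IntegerVector dims,
                             NumericVector spacing, IntegerVector source) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector T(ntot, INF);
  std::vector<char> state(ntot, 0); // 0 far, 1 trial, 2 accepted
  std::priority_queue<HeapNode> heap;

  const double h[3] = {spacing[0], spacing[1], spacing[2]};

  for (int s = 0; s < source.size(); ++s) {
    R_xlen_t i = source[s] - 1; // 1-based from R
    if (i < 0 || i >= ntot || speed[i] <= 0) continue;
    int sx = (int)(i % nx);
    int sy = (int)((i / nx) % ny);
    int sz = (int)(i / ((R_xlen_t)nx * ny));
    // exact initialization ball (radius 3 voxels) at the local source speed
    const int R = 3;
    for (int dz = -R; dz <= R; ++dz)
      for (int dy = -R; dy <= R; ++dy)
        for (int dx = -R; dx <= R; ++dx) {
          int xn = sx + dx, yn = sy + dy, zn = sz + dz;
          if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
            continue;
          R_xlen_t j = xn + (R_xlen_t)nx * (yn + (R_xlen_t)ny * zn);
          if (speed[j] <= 0) continue;
          double dist = std::sqrt(dx * h[0] * dx * h[0] + dy * h[1] * dy * h[1] +
                                  dz * h[2] * dz * h[2]);
          // harmonic-mean speed between source and voxel approximates the
          // integral of slowness along the straight ray
          double f = 2.0 / (1.0 / speed[i] + 1.0 / speed[j]);
          double t0 = dist / f;
          if (t0 < T[j]) {
            T[j] = t0;
            state[j] = 1;
            heap.push({t0, j});
          }
        }
  }

  while (!heap.empty()) {
    HeapNode nd = heap.top(); heap.pop();
    if (state[nd.idx] == 2 || nd.t > T[nd.idx]) continue;
    state[nd.idx] = 2;
    int x = (int)(nd.idx % nx);
    int y = (int)((nd.idx / nx) % ny);
    int zc = (int)(nd.idx / ((R_xlen_t)nx * ny));
    const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int q = 0; q < 6; ++q) {
      int xn = x + nb[q][0], yn = y + nb[q][1], zn = zc + nb[q][2];
      if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
      R_xlen_t j = xn + (R_xlen_t)nx * (yn + (R_xlen_t)ny * zn);
      if (state[j] == 2 || speed[j] <= 0) continue;
      // upwind data per axis: first- or second-order one-sided difference
      // term  alpha * (t - a)^2  with alpha = (c/h)^2
      double a[3], alpha[3];
      int na = 0;
      int xyz[3] = {xn, yn, zn};
      for (int ax = 0; ax < 3; ++ax) {
        double besta = INF, bestalpha = 0;
        for (int dir = -1; dir <= 1; dir += 2) {
          int c[3] = {xyz[0], xyz[1], xyz[2]};
          c[ax] += dir;
          if (c[ax] < 0 || c[ax] >= dims[ax]) continue;
          R_xlen_t k1 = c[0] + (R_xlen_t)nx * (c[1] + (R_xlen_t)ny * c[2]);
          if (state[k1] != 2) continue;
          double t1 = T[k1];
          // try second order with the next voxel in the same direction
          int c2[3] = {c[0], c[1], c[2]};
          c2[ax] += dir;
          bool second = false;
          double t2 = 0;
          if (c2[ax] >= 0 && c2[ax] < dims[ax]) {
            R_xlen_t k2 = c2[0] + (R_xlen_t)nx * (c2[1] + (R_xlen_t)ny * c2[2]);
            if (state[k2] == 2 && T[k2] <= t1) { second = true; t2 = T[k2]; }
          }
          double acand, alphacand;
          if (second) {
            acand = (4.0 * t1 - t2) / 3.0;
            alphacand = 9.0 / (4.0 * h[ax] * h[ax]);
          } else {
            acand = t1;
            alphacand = 1.0 / (h[ax] * h[ax]);
          }
          if (acand < besta) { besta = acand; bestalpha = alphacand; }
        }
        if (besta < INF) { a[na] = besta; alpha[na] = bestalpha; ++na; }
      }
      if (na == 0) continue;
      // solve sum_i alpha_i (t - a_i)^2 = 1/F^2, dropping terms with t <= a_i
      double rhs = 1.0 / (speed[j] * speed[j]);
      for (int u = 0; u < na; ++u)
        for (int w = u + 1; w < na; ++w)
          if (a[w] < a[u]) { std::swap(a[u], a[w]); std::swap(alpha[u], alpha[w]); }
      double tnew = INF;
      for (int m = na; m >= 1; --m) {
        double A = 0, B = 0, C = -rhs;
        for (int u = 0; u < m; ++u) {
          A += alpha[u];
          B += -2.0 * a[u] * alpha[u];
          C += a[u] * a[u] * alpha[u];
        }
        double disc = B * B - 4 * A * C;
        if (disc < 0) continue;
        double t = (-B + std::sqrt(disc)) / (2 * A);
        if (m == 1 || t >= a[m - 1]) { tnew = t; break; }
      }
      if (tnew < T[j]) {
        T[j] = tnew;
        state[j] = 1;
        heap.push({tnew, j});
      }
    }
  }
  T.attr("dim") = dims;
  return T;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary volume, 26- or 6-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), zc = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1) continue;
            int xn = x + dx, yn = y + dy, zn = zc + dz;
            if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
            R_xlen_t j = xn + (R_xlen_t)nx * (yn + (R_xlen_t)ny * zn);
            if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by tetrahedral decomposition of each grid cell
// (Kuhn 6-tetrahedra subdivision along the main diagonal, which tiles space
// consistently across cell faces). Vertices lie on grid edges at the linear
// interpolation of the iso level; shared edges are deduplicated so the
// triangle soup is a manifold with boundary where the field is cut by the
// volume faces.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_isosurface(NumericVector data, IntegerVector dims,
                    NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // corner offsets of the unit cube, standard ordering
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // Kuhn subdivision around the 0-6 diagonal
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  std::map<std::pair<R_xlen_t,R_xlen_t>, int> edge_vertex;
  std::vector<double> verts;     // x,y,z triples
  std::vector<int> tris;         // 1-based vertex ids

  auto lin = [&](int x, int y, int zc) -> R_xlen_t {
    return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zc);
  };
  auto vertex_on_edge = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    auto key = std::make_pair(a, b);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = data[a], vb = data[b];
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int ax = (int)(a % nx), ay = (int)((a / nx) % ny), az = (int)(a / ((R_xlen_t)nx * ny));
    int bx = (int)(b % nx), by = (int)((b / nx) % ny), bz = (int)(b / ((R_xlen_t)nx * ny));
    double px = origin[0] + (ax + t * (bx - ax)) * spacing[0];
    double py = origin[1] + (ay + t * (by - ay)) * spacing[1];
    double pz = origin[2] + (az + t * (bz - az)) * spacing[2];
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    int id = (int)(verts.size() / 3); // 1-based
    edge_vertex[key] = id;
    return id;
  };

  for (int zc = 0; zc < nz - 1; ++zc)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        R_xlen_t cid[8];
        double cval[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          cid[c] = lin(x + corner[c][0], y + corner[c][1], zc + corner[c][2]);
          cval[c] = data[cid[c]];
          if (cval[c] >= iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int ti[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cval[ti[c]] >= iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // find the lone vertex
            bool lone_in = (nin == 1);
            int lone = -1;
            for (int c = 0; c < 4; ++c) if (in[c] == lone_in) { lone = c; break; }
            int vids[3]; int k = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == lone) continue;
              vids[k++] = vertex_on_edge(cid[ti[lone]], cid[ti[c]]);
            }
            tris.push_back(vids[0]); tris.push_back(vids[1]); tris.push_back(vids[2]);
          } else {
            // two in, two out: quad
            int inn[2], outt[2]; int ki = 0, ko = 0;
            for (int c = 0; c < 4; ++c) { if (in[c]) inn[ki++] = c; else outt[ko++] = c; }
            int e00 = vertex_on_edge(cid[ti[inn[0]]], cid[ti[outt[0]]]);
            int e01 = vertex_on_edge(cid[ti[inn[0]]], cid[ti[outt[1]]]);
            int e10 = vertex_on_edge(cid[ti[inn[1]]], cid[ti[outt[0]]]);
            int e11 = vertex_on_edge(cid[ti[inn[1]]], cid[ti[outt[1]]]);
            tris.push_back(e00); tris.push_back(e01); tris.push_back(e11);
            tris.push_back(e00); tris.push_back(e11); tris.push_back(e10);
          }
        }
      }

  R_xlen_t nv = (R_xlen_t)(verts.size() / 3), nt = (R_xlen_t)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (R_xlen_t i = 0; i < nv; ++i) {
    V(i, 0) = verts[3 * i]; V(i, 1) = verts[3 * i + 1]; V(i, 2) = verts[3 * i + 2];
  }
  IntegerMatrix Tri(nt, 3);
  for (R_xlen_t i = 0; i < nt; ++i) {
    Tri(i, 0) = tris[3 * i]; Tri(i, 1) = tris[3 * i + 1]; Tri(i, 2) = tris[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tri);
}
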