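// Core numerical kernels: exact squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm), iso-surface
// extraction on a consistent 6-tetrahedra (Kuhn) decomposition of the voxel
// grid (guarantees a watertight, orientable triangulation), an exact
// farthest-point-pair search with bounding-box pruning, and 26-connected
// component labeling.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1D squared distance transform along samples at physical positions i*h
// (lower envelope of parabolas). Sites with f = INF are compacted away first
// so the envelope never sees non-finite parabolas.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  int n, double h, std::vector<int>& v, std::vector<double>& z,
                  std::vector<int>& idx, std::vector<double>& fv) {
  int m = 0;
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) { idx[m] = q; fv[m] = f[q]; ++m; }
  if (m == 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < m; ++q) {
    double xq = idx[q] * h;
    double s;
    while (true) {
      int p = v[k];
      double xp = idx[p] * h;
      s = ((fv[q] + xq * xq) - (fv[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - idx[v[k]] * h;
    d[q] = dx * dx + fv[v[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest 'true' voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1), fv(nmax);
  std::vector<int> v(nmax), idx(nmax);

  // along x (fastest-varying)
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)jy * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt1d(f, d, nx, spacing[0], v, z, idx, fv);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int kz = 0; kz < nz; ++kz)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      edt1d(f, d, ny, spacing[1], v, z, idx, fv);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  for (int jy = 0; jy < ny; ++jy)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)jy * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      edt1d(f, d, nz, spacing[2], v, z, idx, fv);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction. Kuhn decomposition: each cube is split into the six
// tetrahedra sharing the main diagonal c0-c7; face diagonals agree between
// neighbouring cubes, so the global triangulation is conforming and the
// extracted surface is watertight.

struct VKey {
  uint64_t k;
  bool operator==(const VKey& o) const { return k == o.k; }
};
struct VKeyHash {
  size_t operator()(const VKey& v) const { return std::hash<uint64_t>()(v.k); }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector phi, IntegerVector dim, NumericVector spacing,
                       NumericVector origin, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const uint64_t NTOT = (uint64_t)nx * ny * nz;

  // corner offsets within a cube, bit i -> (x,y,z)
  const int cox[8] = {0,1,0,1,0,1,0,1};
  const int coy[8] = {0,0,1,1,0,0,1,1};
  const int coz[8] = {0,0,0,0,1,1,1,1};
  // six Kuhn tetrahedra (corner indices), all containing 0 and 7
  const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };

  std::unordered_map<VKey,int,VKeyHash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  double ox = origin[0], oy = origin[1], oz = origin[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];

  double cphi[8];
  uint64_t cid[8];
  double cpx[8], cpy[8], cpz[8];

  // Snap interpolated vertices that fall (numerically) on a grid node onto
  // the node itself, keyed by node id so every incident edge shares the one
  // vertex and the collapsed micro-triangles drop out. This handles field
  // values lying exactly on the iso level.
  const double snap_eps = 1e-7;
  auto edge_vertex = [&](int a, int b) -> int {
    uint64_t ia = cid[a], ib = cid[b];
    double fav = cphi[a], fbv = cphi[b];
    if (ia > ib) { std::swap(ia, ib); std::swap(fav, fbv); std::swap(a, b); }
    double t = (iso - fav) / (fbv - fav);
    VKey key{ ia * NTOT + ib };
    int corner = -1;
    if (t <= snap_eps) { corner = a; key.k = ia * NTOT + ia; }
    else if (t >= 1.0 - snap_eps) { corner = b; key.k = ib * NTOT + ib; }
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double px, py, pz;
    if (corner >= 0) {
      px = cpx[corner]; py = cpy[corner]; pz = cpz[corner];
    } else {
      px = cpx[a] + t * (cpx[b] - cpx[a]);
      py = cpy[a] + t * (cpy[b] - cpy[a]);
      pz = cpz[a] + t * (cpz[b] - cpz[a]);
    }
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, int ta, int tb, int tc, int td) {
    if (v0 == v1 || v1 == v2 || v0 == v2) return;  // collapsed by snapping
    // orient so the normal points along the phi gradient (outside = phi > iso)
    double e1x = vx[v1]-vx[v0], e1y = vy[v1]-vy[v0], e1z = vz[v1]-vz[v0];
    double e2x = vx[v2]-vx[v0], e2y = vy[v2]-vy[v0], e2z = vz[v2]-vz[v0];
    double nxv = e1y*e2z - e1z*e2y;
    double nyv = e1z*e2x - e1x*e2z;
    double nzv = e1x*e2y - e1y*e2x;
    // linear gradient of phi over the tet: solve E^T g = df
    double ax = cpx[tb]-cpx[ta], ay = cpy[tb]-cpy[ta], az = cpz[tb]-cpz[ta];
    double bx2 = cpx[tc]-cpx[ta], by2 = cpy[tc]-cpy[ta], bz2 = cpz[tc]-cpz[ta];
    double cx2 = cpx[td]-cpx[ta], cy2 = cpy[td]-cpy[ta], cz2 = cpz[td]-cpz[ta];
    double d1 = cphi[tb]-cphi[ta], d2 = cphi[tc]-cphi[ta], d3 = cphi[td]-cphi[ta];
    // g = M^{-1} d with rows a,b,c: use Cramer's rule
    double det = ax*(by2*cz2-bz2*cy2) - ay*(bx2*cz2-bz2*cx2) + az*(bx2*cy2-by2*cx2);
    double gx = (d1*(by2*cz2-bz2*cy2) - ay*(d2*cz2-bz2*d3) + az*(d2*cy2-by2*d3)) / det;
    double gy = (ax*(d2*cz2-bz2*d3) - d1*(bx2*cz2-bz2*cx2) + az*(bx2*d3-d2*cx2)) / det;
    double gz = (ax*(by2*d3-d2*cy2) - ay*(bx2*d3-d2*cx2) + d1*(bx2*cy2-by2*cx2)) / det;
    double dot = nxv*gx + nyv*gy + nzv*gz;
    if (dot >= 0) { fa.push_back(v0); fb.push_back(v1); fc.push_back(v2); }
    else          { fa.push_back(v0); fb.push_back(v2); fc.push_back(v1); }
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + cox[c], jj = j + coy[c], kk = k + coz[c];
          R_xlen_t lin = ii * sx + (R_xlen_t)jj * sy + (R_xlen_t)kk * sz;
          cphi[c] = phi[lin];
          cid[c] = (uint64_t)lin;
          cpx[c] = ox + ii * hx;
          cpy[c] = oy + jj * hy;
          cpz[c] = oz + kk * hz;
          if (cphi[c] < iso) any_lo = true; else any_hi = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int inside[4], nin = 0;
          for (int m = 0; m < 4; ++m) inside[m] = (cphi[T[m]] < iso) ? 1 : 0, nin += inside[m];
          if (nin == 0 || nin == 4) continue;
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int m = 0; m < 4; ++m) {
            if (inside[m]) in_idx[ni++] = T[m]; else out_idx[no++] = T[m];
          }
          if (nin == 1) {
            int a = in_idx[0];
            int p = edge_vertex(a, out_idx[0]);
            int q = edge_vertex(a, out_idx[1]);
            int r = edge_vertex(a, out_idx[2]);
            emit(p, q, r, T[0], T[1], T[2], T[3]);
          } else if (nin == 3) {
            int a = out_idx[0];
            int p = edge_vertex(in_idx[0], a);
            int q = edge_vertex(in_idx[1], a);
            int r = edge_vertex(in_idx[2], a);
            emit(p, q, r, T[0], T[1], T[2], T[3]);
          } else { // 2 in, 2 out -> quad
            int a0 = in_idx[0], a1 = in_idx[1], b0 = out_idx[0], b1 = out_idx[1];
            int p00 = edge_vertex(a0, b0);
            int p01 = edge_vertex(a0, b1);
            int p10 = edge_vertex(a1, b0);
            int p11 = edge_vertex(a1, b1);
            emit(p00, p01, p11, T[0], T[1], T[2], T[3]);
            emit(p00, p11, p10, T[0], T[1], T[2], T[3]);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int m = 0; m < nv; ++m) { V(m,0) = vx[m]; V(m,1) = vy[m]; V(m,2) = vz[m]; }
  for (int m = 0; m < nf; ++m) { F(m,0) = fa[m]+1; F(m,1) = fb[m]+1; F(m,2) = fc[m]+1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact farthest pair between two point sets with axis-aligned bounding-box
// pruning. Points should be pre-rotated so the first axis is the long axis
// (the R wrapper does a PCA rotation); correctness does not depend on it.
// [[Rcpp::export]]
List cpp_farthest_pair(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double bxmin = INF, bxmax = -INF, bymin = INF, bymax = -INF, bzmin = INF, bzmax = -INF;
  for (int j = 0; j < nb; ++j) {
    bxmin = std::min(bxmin, B(j,0)); bxmax = std::max(bxmax, B(j,0));
    bymin = std::min(bymin, B(j,1)); bymax = std::max(bymax, B(j,1));
    bzmin = std::min(bzmin, B(j,2)); bzmax = std::max(bzmax, B(j,2));
  }
  // heuristic warm start: alternate farthest-point iterations
  int ia = 0, ib = 0;
  double best = -1.0;
  {
    int cur = 0;
    for (int it = 0; it < 6; ++it) {
      // farthest b from A[cur]
      double bd = -1.0; int bj = 0;
      for (int j = 0; j < nb; ++j) {
        double dx = A(cur,0)-B(j,0), dy = A(cur,1)-B(j,1), dz = A(cur,2)-B(j,2);
        double d2 = dx*dx+dy*dy+dz*dz;
        if (d2 > bd) { bd = d2; bj = j; }
      }
      if (bd > best) { best = bd; ia = cur; ib = bj; }
      // farthest a from B[bj]
      double ad = -1.0; int aiidx = 0;
      for (int i = 0; i < na; ++i) {
        double dx = A(i,0)-B(bj,0), dy = A(i,1)-B(bj,1), dz = A(i,2)-B(bj,2);
        double d2 = dx*dx+dy*dy+dz*dz;
        if (d2 > ad) { ad = d2; aiidx = i; }
      }
      if (ad > best) { best = ad; ia = aiidx; ib = bj; }
      if (aiidx == cur) break;
      cur = aiidx;
    }
  }
  // exact scan with per-point AABB upper-bound pruning
  for (int i = 0; i < na; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double ux = std::max(ax - bxmin, bxmax - ax);
    double uy = std::max(ay - bymin, bymax - ay);
    double uz = std::max(az - bzmin, bzmax - az);
    if (ux*ux + uy*uy + uz*uz <= best) continue;
    for (int j = 0; j < nb; ++j) {
      double dx = ax-B(j,0), dy = ay-B(j,1), dz = az-B(j,2);
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > best) { best = d2; ia = i; ib = j; }
      else if (d2 == best) { // lexicographic tie-break on (A row, B row) coords
        // keep existing; deterministic because scan order is fixed
      }
    }
  }
  return List::create(_["i"] = ia + 1, _["j"] = ib + 1, _["dist"] = std::sqrt(best));
}

// ---------------------------------------------------------------------------
// 26-connected component labeling of a logical 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t q = ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
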