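// 3D image morphology primitives: exact anisotropic Euclidean distance
// transform, connected-component labelling, topology-preserving thinning,
// and trilinear affine resampling.  Grids use R's column-major layout,
// linear index = x + nx*(y + ny*z).
#include <Rcpp.h>
#include <array>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Felzenszwalb-Huttenlocher 1D squared distance transform with sample step.
// f: input squared distances at positions i*step; d: output.
static void dt1d(const double* f, double* d, int n, double step,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF && f[v[k]] == INF) { // both empty: keep rightmost finite
      if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    }
    double xq = q * step, s;
    for (;;) {
      double xv = v[k] * step;
      if (f[q] == INF) { s = INF; }
      else if (f[v[k]] == INF) { s = -INF; }
      else s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) { k--; } else break;
    }
    if (s == INF) continue;          // parabola never wins
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * step;
    d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance (in mm) from each foreground voxel to the nearest
// background voxel center.  Voxels outside the grid count as background, so
// the volume is padded by one background layer before the transform.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  std::vector<double> g((size_t)px * py * pz, 0.0);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t src = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        size_t dst = (size_t)(x + 1) + px * ((size_t)(y + 1) + (size_t)py * (z + 1));
        g[dst] = mask[src] ? INF : 0.0;
      }
  int nmax = std::max(px, std::max(py, pz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zbuf(nmax + 1);
  // x pass
  for (int z = 0; z < pz; z++)
    for (int y = 0; y < py; y++) {
      size_t base = px * ((size_t)y + (size_t)py * z);
      for (int x = 0; x < px; x++) f[x] = g[base + x];
      dt1d(f.data(), d.data(), px, spacing[0], v, zbuf);
      for (int x = 0; x < px; x++) g[base + x] = d[x];
    }
  // y pass
  for (int z = 0; z < pz; z++)
    for (int x = 0; x < px; x++) {
      for (int y = 0; y < py; y++) f[y] = g[(size_t)x + px * ((size_t)y + (size_t)py * z)];
      dt1d(f.data(), d.data(), py, spacing[1], v, zbuf);
      for (int y = 0; y < py; y++) g[(size_t)x + px * ((size_t)y + (size_t)py * z)] = d[y];
    }
  // z pass
  for (int y = 0; y < py; y++)
    for (int x = 0; x < px; x++) {
      for (int z = 0; z < pz; z++) f[z] = g[(size_t)x + px * ((size_t)y + (size_t)py * z)];
      dt1d(f.data(), d.data(), pz, spacing[2], v, zbuf);
      for (int z = 0; z < pz; z++) g[(size_t)x + px * ((size_t)y + (size_t)py * z)] = d[z];
    }
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t src = (size_t)(x + 1) + px * ((size_t)(y + 1) + (size_t)py * (z + 1));
        size_t dst = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        out[dst] = std::sqrt(g[src]);
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)n);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        size_t j = (size_t)xx + nx * ((size_t)yy + (size_t)ny * zz);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test (Bertrand & Malandain): a foreground voxel is simple iff
// (a) its 26-neighborhood contains exactly one 26-connected foreground
// component, and (b) its 18-neighborhood contains exactly one 6-connected
// background component that is 6-adjacent to the voxel.
namespace {

inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// number of 26-connected fg components among the 26 neighbors (center removed)
int count_fg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comps++;
    std::vector<int> st{i};
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
            int j = xx + 3 * (yy + 3 * zz);
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  return comps;
}

// number of 6-connected bg components within N18 that touch a face neighbor
int count_bg_components(const bool nb[27]) {
  // N18 positions: manhattan distance from center 1 or 2 excluding corners
  bool in18[27];
  for (int i = 0; i < 27; i++) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
    in18[i] = (manh >= 1 && manh <= 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
    if (manh != 1 || nb[i] || seen[i]) continue;  // grow only from face nbrs
    comps++;
    std::vector<int> st{i};
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int px = c % 3, py = (c / 3) % 3, pz = c / 9;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto& f : face) {
        int xx = px + f[0], yy = py + f[1], zz = pz + f[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int j = xx + 3 * (yy + 3 * zz);
        if (j == 13 || seen[j] || !in18[j] || nb[j]) continue;
        seen[j] = true;
        st.push_back(j);
      }
    }
  }
  return comps;
}

struct Grid {
  const uint8_t* v;
  int nx, ny, nz;
  bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return v[(size_t)x + nx * ((size_t)y + (size_t)ny * z)] != 0;
  }
};

void neighborhood(const Grid& g, int x, int y, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++)
        nb[nb_index(dx, dy, dz)] = g.at(x + dx, y + dy, z + dz);
}

bool is_simple(const Grid& g, int x, int y, int z) {
  bool nb[27];
  neighborhood(g, x, y, z, nb);
  nb[13] = false; // center removed for fg component count
  if (count_fg_components(nb) != 1) return false;
  if (count_bg_components(nb) != 1) return false;
  return true;
}

int fg_neighbors(const Grid& g, int x, int y, int z) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        if (g.at(x + dx, y + dy, z + dz)) cnt++;
      }
  return cnt;
}

} // namespace

// Sequential topology-preserving curve thinning.  Border points (per the six
// face directions) that are simple and not curve endpoints are deleted in
// increasing distance-transform order, with re-checking before each deletion,
// until no change occurs.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim,
                              NumericVector edt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<uint8_t> vol(n);
  for (size_t i = 0; i < n; i++) vol[i] = mask[i] ? 1 : 0;
  Grid g{vol.data(), nx, ny, nz};
  const int dir[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  std::vector<std::pair<double, size_t>> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (size_t i = 0; i < n; i++) {
        if (!vol[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
        if (g.at(x + dir[d][0], y + dir[d][1], z + dir[d][2])) continue; // not border in d
        if (fg_neighbors(g, x, y, z) <= 1) continue;                     // endpoint
        if (!is_simple(g, x, y, z)) continue;
        cand.push_back({edt[i], i});
      }
      std::stable_sort(cand.begin(), cand.end(),
                       [](const std::pair<double, size_t>& a,
                          const std::pair<double, size_t>& b) {
                         return a.first < b.first;
                       });
      for (auto& c : cand) {
        size_t i = c.second;
        int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
        if (fg_neighbors(g, x, y, z) <= 1) continue;
        if (!is_simple(g, x, y, z)) continue;
        vol[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; i++) out[i] = vol[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear affine resampling: output(p) = input(R^-1 (p - c) + c - t) with c
// the volume center (0-based voxel units), t an integer-or-real translation in
// voxels, rotmat the forward rotation matrix.  Out-of-field voxels take fill.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim,
                                  NumericMatrix rotinv, NumericVector trans,
                                  double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double px = x - cx, py = y - cy, pz = z - cz;
        double sx = rotinv(0,0)*px + rotinv(0,1)*py + rotinv(0,2)*pz + cx - trans[0];
        double sy = rotinv(1,0)*px + rotinv(1,1)*py + rotinv(1,2)*pz + cy - trans[1];
        double sz = rotinv(2,0)*px + rotinv(2,1)*py + rotinv(2,2)*pz + cz - trans[2];
        size_t di = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
        if (x0 < -1 || y0 < -1 || z0 < -1 || x0 >= nx || y0 >= ny || z0 >= nz) {
          out[di] = fill;
          continue;
        }
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int k = 0; k <= 1; k++)
          for (int j = 0; j <= 1; j++)
            for (int i = 0; i <= 1; i++) {
              int xx = x0 + i, yy = y0 + j, zz = z0 + k;
              double w = (i ? fx : 1 - fx) * (j ? fy : 1 - fy) * (k ? fz : 1 - fz);
              double val;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                val = fill;
              else
                val = vol[(size_t)xx + nx * ((size_t)yy + (size_t)ny * zz)];
              acc += w * val;
            }
        out[di] = acc;
      }
  out.attr("dim") = dim;
  return out;
}
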