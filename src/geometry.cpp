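#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Voxel geometry kernels shared by the featurisation operators.
// All arrays arrive as flat vectors in R's column-major order with an
// explicit dims attribute; results are reshaped on the R side.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected-component labelling of a binary 3D mask.
// connectivity: 6 (face) or 26 (face/edge/vertex). Labels are 1..n in
// first-encounter order (scan order = column-major), 0 for background.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back((int)start);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int z = v / (nx * ny);
      int rem = v - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            int w = idx3(xx, yy, zz, nx, ny);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher),
// sample spacing s; f holds squared distances on input, overwritten.
static void dt1d(std::vector<double> &f, double s, int n,
                 std::vector<double> &d, std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;           // no parabola at q
    while (true) {
      if (f[v[k]] == INF) {              // replace an infinite vertex
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; break; }
        --k;
        continue;
      }
      double sI = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
                  (2.0 * s * (q - v[k]));
      if (sI <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sI;
      z[k + 1] = INF;
      break;
    }
  }
  if (f[v[0]] == INF) {                  // whole line empty
    for (int q = 0; q < n; ++q) d[q] = INF;
  } else {
    k = 0;
    for (int q = 0; q < n; ++q) {
      while (z[k + 1] < s * q) ++k;
      double dq = s * (q - v[k]);
      d[q] = dq * dq + f[v[k]];
    }
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance transform of a binary mask: for voxels
// where mask is TRUE, squared distance (in physical units given spacing)
// to the nearest FALSE voxel centre; 0 elsewhere. If the mask covers the
// whole volume the result is Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      for (int xx = 0; xx < nx; ++xx) f[xx] = g[idx3(xx, yy, zz, nx, ny)];
      dt1d(f, spacing[0], nx, d, v, z);
      for (int xx = 0; xx < nx; ++xx) g[idx3(xx, yy, zz, nx, ny)] = f[xx];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      for (int yy = 0; yy < ny; ++yy) f[yy] = g[idx3(xx, yy, zz, nx, ny)];
      dt1d(f, spacing[1], ny, d, v, z);
      for (int yy = 0; yy < ny; ++yy) g[idx3(xx, yy, zz, nx, ny)] = f[yy];
    }
  // z pass
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      for (int zz = 0; zz < nz; ++zz) f[zz] = g[idx3(xx, yy, zz, nx, ny)];
      dt1d(f, spacing[2], nz, d, v, z);
      for (int zz = 0; zz < nz; ++zz) g[idx3(xx, yy, zz, nx, ny)] = f[zz];
    }
  return g;
}
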