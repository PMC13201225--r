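#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact 1D squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) with physical sample spacing w.
// f: input squared distances along the line, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  // Parabolas at infinite height never form the envelope once any finite
  // sample exists, so they are simply skipped (all-INF lines stay INF).
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  // intersections are stored in index units
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double fv = f[v[k]];
    if (fv == INF) d[q] = INF;
    else {
      double dq = w * (q - v[k]);
      d[q] = dq * dq + fv;
    }
  }
}

// Exact Euclidean distance transform on an anisotropic 3D grid.
// mask: integer array (non-zero = source voxels), dims = c(nx, ny, nz),
// spacing in physical units per voxel along x, y, z.
// Returns physical distance from every voxel to the nearest source voxel.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] != 0 ? 0.0 : INF;

  // pass along x (stride 1)
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) f[i] = g[base + i];
        dt1d(f, d, nx, sx);
        for (int i = 0; i < nx; ++i) g[base + i] = d[i];
      }
  }
  // pass along y (stride nx)
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * ny * k;
        for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)nx * j];
        dt1d(f, d, ny, sy);
        for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)nx * j] = d[j];
      }
  }
  // pass along z (stride nx*ny)
  if (nz > 1) {
    std::vector<double> f(nz), d(nz);
    const R_xlen_t sl = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; ++k) f[k] = g[base + sl * k];
        dt1d(f, d, nz, sz);
        for (int k = 0; k < nz; ++k) g[base + sl * k] = d[k];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = g[i] == INF ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// Connected-component labeling. conn: 26 (full 3D), 6 (3D faces),
// 8 (2D full, within-slice), 4 (2D faces, within-slice). Returns integer
// labels, 0 = background.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerVector cpp_label(IntegerVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next = 0;
  const bool use_z = (conn == 26 || conn == 6);
  const bool diag = (conn == 26 || conn == 8);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int dk = use_z ? -1 : 0; dk <= (use_z ? 1 : 0); ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (!diag && (di != 0) + (dj != 0) + (dk != 0) > 1) continue;
            R_xlen_t t = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[t] != 0 && lab[t] == 0) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Zhang-Suen thinning of a 2D binary image (nx x ny matrix) to a
// 1-pixel-wide 8-connected skeleton.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  const int nx = img.nrow(), ny = img.ncol();
  std::vector<unsigned char> a((size_t)(nx + 2) * (ny + 2), 0);
  auto at = [&](int i, int j) -> unsigned char& {
    return a[(size_t)(i + 1) + (size_t)(nx + 2) * (j + 1)];
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      at(i, j) = img(i, j) ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (!at(i, j)) continue;
          // neighbours P2..P9 clockwise starting north (j-1)
          int p2 = at(i, j - 1), p3 = at(i + 1, j - 1), p4 = at(i + 1, j);
          int p5 = at(i + 1, j + 1), p6 = at(i, j + 1), p7 = at(i - 1, j + 1);
          int p8 = at(i - 1, j), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      if (!kill.empty()) changed = true;
      for (size_t q = 0; q < kill.size(); ++q)
        at(kill[q].first, kill[q].second) = 0;
    }
  }
  LogicalMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out(i, j) = at(i, j) != 0;
  return out;
}
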