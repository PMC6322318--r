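#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Voxel grids arrive as flat column-major vectors with dims (nx, ny, nz),
// matching R arrays. Discretized level 0 means "outside the ROI".

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Co-occurrence counts for one displacement; symmetric accumulation
// (both voxel orders), only pairs with both voxels in the ROI.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector lv, IntegerVector dims,
                              IntegerVector offset, int nlevels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int dx = offset[0], dy = offset[1], dz = offset[2];
  NumericMatrix m(nlevels, nlevels);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lv[vidx(x, y, z, nx, ny)];
        if (a == 0) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        int b = lv[vidx(x2, y2, z2, nx, ny)];
        if (b == 0) continue;
        m(a - 1, b - 1) += 1.0;
        m(b - 1, a - 1) += 1.0;
      }
  return m;
}

// Run-length counts along one direction. Lines are walked from voxels with
// no in-grid predecessor along the direction; out-of-ROI voxels break runs.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector lv, IntegerVector dims,
                               IntegerVector dir, int nlevels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int dx = dir[0], dy = dir[1], dz = dir[2];
  int maxrun = nx + ny + nz;
  NumericMatrix m(nlevels, maxrun);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int px = x - dx, py = y - dy, pz = z - dz;
        bool has_pred = px >= 0 && px < nx && py >= 0 && py < ny &&
                        pz >= 0 && pz < nz;
        if (has_pred) continue; // not a line start
        int cur = 0, len = 0;
        int cx = x, cy = y, cz = z;
        while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
          int v = lv[vidx(cx, cy, cz, nx, ny)];
          if (v == cur && v != 0) {
            ++len;
          } else {
            if (cur != 0) m(cur - 1, len - 1) += 1.0;
            cur = v;
            len = v != 0 ? 1 : 0;
          }
          cx += dx; cy += dy; cz += dz;
        }
        if (cur != 0) m(cur - 1, len - 1) += 1.0;
      }
  return m;
}

// Size-zone counts: 26-connected zones of constant level within the ROI.
// Returns a two-column matrix (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lv, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  for (int i = 0; i < n; ++i) {
    if (lv[i] == 0 || seen[i]) continue;
    int level = lv[i];
    int size = 0;
    std::deque<int> q;
    q.push_back(i);
    seen[i] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop_front();
      ++size;
      int cz = c / (nx * ny), cy = (c / nx) % ny, cx = c % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int j = vidx(x2, y2, z2, nx, ny);
            if (!seen[j] && lv[j] == level) { seen[j] = 1; q.push_back(j); }
          }
    }
    zl.push_back(level);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) { out(k, 0) = zl[k]; out(k, 1) = zs[k]; }
  return out;
}

// 6-connected component labels of a binary mask (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  const int steps[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    std::deque<int> q;
    q.push_back(i);
    lab[i] = next;
    while (!q.empty()) {
      int c = q.front(); q.pop_front();
      int cz = c / (nx * ny), cy = (c / nx) % ny, cx = c % nx;
      for (int s = 0; s < 6; ++s) {
        int x2 = cx + steps[s][0], y2 = cy + steps[s][1], z2 = cz + steps[s][2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        int j = vidx(x2, y2, z2, nx, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push_back(j); }
      }
    }
  }
  return lab;
}

// Largest pairwise Euclidean distance among points (rows, physical units).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = pts(i, k) - pts(j, k);
        s += diff * diff;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
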