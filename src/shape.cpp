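#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Surface area of the 0.5-isosurface of a binary mask by marching
// tetrahedra: each grid cell is split into six tetrahedra around the
// (0,0,0)-(1,1,1) diagonal and every boundary-crossing tetrahedron is
// triangulated with edge-interpolated vertices. The mask is treated as
// zero-padded so closed surfaces result even at the grid boundary.

struct P3 { double x, y, z; };

static inline P3 lerp05(const P3 &a, const P3 &b, double fa, double fb) {
  double t = (0.5 - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_surface_area(NumericVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, vertex numbering v0..v7
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                        {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra around the v0-v6 diagonal
  const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                          {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0.0;
  double f[8];
  P3 pos[8];
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        bool any = false, all = true;
        for (int v = 0; v < 8; ++v) {
          int cx = x + co[v][0], cy = y + co[v][1], cz = z + co[v][2];
          double val = 0.0;
          if (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz)
            val = mask[cx + nx * (cy + ny * cz)];
          f[v] = val;
          pos[v].x = cx * sx; pos[v].y = cy * sy; pos[v].z = cz * sz;
          any = any || val > 0.5;
          all = all && val > 0.5;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], out[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (f[vi[k]] > 0.5) in[nin++] = vi[k]; else out[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            P3 a = lerp05(pos[in[0]], pos[out[0]], f[in[0]], f[out[0]]);
            P3 b = lerp05(pos[in[0]], pos[out[1]], f[in[0]], f[out[1]]);
            P3 c = lerp05(pos[in[0]], pos[out[2]], f[in[0]], f[out[2]]);
            area += tri_area(a, b, c);
          } else if (nin == 3) {
            P3 a = lerp05(pos[out[0]], pos[in[0]], f[out[0]], f[in[0]]);
            P3 b = lerp05(pos[out[0]], pos[in[1]], f[out[0]], f[in[1]]);
            P3 c = lerp05(pos[out[0]], pos[in[2]], f[out[0]], f[in[2]]);
            area += tri_area(a, b, c);
          } else { // 2 in, 2 out -> quad split into two triangles
            P3 a = lerp05(pos[in[0]], pos[out[0]], f[in[0]], f[out[0]]);
            P3 b = lerp05(pos[in[0]], pos[out[1]], f[in[0]], f[out[1]]);
            P3 c = lerp05(pos[in[1]], pos[out[1]], f[in[1]], f[out[1]]);
            P3 d = lerp05(pos[in[1]], pos[out[0]], f[in[1]], f[out[0]]);
            area += tri_area(a, b, c) + tri_area(a, c, d);
          }
        }
      }
  return area;
}
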