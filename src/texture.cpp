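#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel grids arrive as flat integer vectors in R's column-major layout with
// dim = (nx, ny, nz); gray level 0 marks voxels outside the mask, 1..ng inside.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Directed co-occurrence counts at the given voxel offsets. Symmetrization
// (P + t(P)) is done on the R side.
// [[Rcpp::export]]
IntegerVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix angles, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], na = angles.nrow();
  IntegerVector out(ng * ng * na);
  for (int a = 0; a < na; ++a) {
    const int dx = angles(a, 0), dy = angles(a, 1), dz = angles(a, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          const int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          out[(li - 1) + ng * (lj - 1) + ng * ng * a]++;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, na);
  return out;
}

// Run-length counts per direction. A run is a maximal streak of equal gray
// level along the direction; out-of-mask voxels break runs.
// [[Rcpp::export]]
IntegerVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim,
                               IntegerMatrix angles, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], na = angles.nrow();
  int lmax = nx;
  if (ny > lmax) lmax = ny;
  if (nz > lmax) lmax = nz;
  IntegerVector out(ng * lmax * na);
  for (int a = 0; a < na; ++a) {
    const int dx = angles(a, 0), dy = angles(a, 1), dz = angles(a, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, nx, ny, nz) &&
              levels[idx3(xp, yp, zp, nx, ny)] == li)
            continue;  // not a run start
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (inside(xc, yc, zc, nx, ny, nz) &&
                 levels[idx3(xc, yc, zc, nx, ny)] == li) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          out[(li - 1) + ng * (len - 1) + ng * lmax * a]++;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, na);
  return out;
}

// Size zones: connected components of equal gray level under the supplied
// neighbourhood offsets (26-connectivity in 3D, 8 in-plane for single-slice
// masks). Returns one (level, size) record per zone.
// [[Rcpp::export]]
List cpp_glszm_zones(IntegerVector levels, IntegerVector dim,
                     IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], no = offsets.nrow();
  const int n = nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<int> zone_level, zone_size, stack;
  stack.reserve(256);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int v = idx3(x, y, z, nx, ny);
        const int li = levels[v];
        if (li == 0 || vis[v]) continue;
        int size = 0;
        vis[v] = 1;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          ++size;
          const int cz = cur / (nx * ny);
          const int cy = (cur - cz * nx * ny) / nx;
          const int cx = cur - cz * nx * ny - cy * nx;
          for (int o = 0; o < no; ++o) {
            const int x2 = cx + offsets(o, 0), y2 = cy + offsets(o, 1),
                      z2 = cz + offsets(o, 2);
            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
            const int w = idx3(x2, y2, z2, nx, ny);
            if (vis[w] || levels[w] != li) continue;
            vis[w] = 1;
            stack.push_back(w);
          }
        }
        zone_level.push_back(li);
        zone_size.push_back(size);
      }
  return List::create(_["level"] = wrap(zone_level),
                      _["size"] = wrap(zone_size));
}

// Dependence counts: for every masked voxel, dependence = 1 + number of masked
// neighbours sharing its gray level (exact equality, alpha = 0).
// [[Rcpp::export]]
IntegerMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim,
                              IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], no = offsets.nrow();
  IntegerMatrix out(ng, no + 1);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        int dep = 1;
        for (int o = 0; o < no; ++o) {
          const int x2 = x + offsets(o, 0), y2 = y + offsets(o, 1),
                    z2 = z + offsets(o, 2);
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          if (levels[idx3(x2, y2, z2, nx, ny)] == li) ++dep;
        }
        out(li - 1, dep - 1)++;
      }
  return out;
}

// Neighbourhood gray-tone difference accumulators: per gray level i, the count
// n_i of masked voxels with at least one masked neighbour and the sum s_i of
// |i - mean neighbour level|. Voxels without masked neighbours are excluded.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_counts(IntegerVector levels, IntegerVector dim,
                               IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], no = offsets.nrow();
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int o = 0; o < no; ++o) {
          const int x2 = x + offsets(o, 0), y2 = y + offsets(o, 1),
                    z2 = z + offsets(o, 2);
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          const int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          sum += lj;
          ++cnt;
        }
        if (cnt == 0) continue;
        out(li - 1, 0) += 1.0;
        out(li - 1, 1) += std::abs(li - sum / cnt);
      }
  return out;
}
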