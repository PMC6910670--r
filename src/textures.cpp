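#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Grey-level texture matrix accumulation for 3D quantized ROIs.
// Level arrays use 1..G inside the mask and 0 outside; all kernels treat
// level 0 as "not part of the ROI".

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// The 13 unique distance-1 directions of the 26-neighbourhood (one per
// antipodal pair, first non-zero component positive).
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, IntegerVector dims,
                              int G, IntegerMatrix dirs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix counts(G, G);
  const int nd = dirs.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        for (int d = 0; d < nd; ++d) {
          const int x2 = x + dirs(d, 0), y2 = y + dirs(d, 1),
                    z2 = z + dirs(d, 2);
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj <= 0) continue;
          // symmetric accumulation: each ordered pair counted once per
          // direction, plus its transpose
          counts(li - 1, lj - 1) += 1.0;
          counts(lj - 1, li - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerVector levels, IntegerVector dims,
                               int G, IntegerMatrix dirs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = nx;
  if (ny > maxlen) maxlen = ny;
  if (nz > maxlen) maxlen = nz;
  NumericMatrix counts(G, maxlen);
  const int nd = dirs.nrow();
  for (int d = 0; d < nd; ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li <= 0) continue;
          // run start: predecessor along -d is outside grid/ROI or differs
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == li)
            continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 &&
                 zn < nz && levels[idx3(xn, yn, zn, nx, ny)] == li) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          counts(li - 1, len - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Zones: 26-connected components of equal grey level. Returns a matrix with
// one row per zone: (level, size).
// [[Rcpp::export(name = ".glszm_zones_cpp")]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> zone_level, zone_size, stack;
  stack.reserve(256);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int i0 = idx3(x, y, z, nx, ny);
        const int li = levels[i0];
        if (li <= 0 || visited[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        visited[i0] = 1;
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          ++size;
          const int cz = i / (nx * ny);
          const int cy = (i / nx) % ny;
          const int cx = i % nx;
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dy = -1; dy <= 1; ++dy) {
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                    z2 >= nz)
                  continue;
                const int j = idx3(x2, y2, z2, nx, ny);
                if (!visited[j] && levels[j] == li) {
                  visited[j] = 1;
                  stack.push_back(j);
                }
              }
            }
          }
        }
        zone_level.push_back(li);
        zone_size.push_back(size);
      }
    }
  }
  IntegerMatrix out(zone_level.size(), 2);
  for (int k = 0; k < (int)zone_level.size(); ++k) {
    out(k, 0) = zone_level[k];
    out(k, 1) = zone_size[k];
  }
  return out;
}

// Amadasun-King accumulators: for each grey level i, n_i = number of in-ROI
// voxels of level i having at least one in-ROI 26-neighbour, and
// s_i = sum over those voxels of |i - mean(neighbour levels)|.
// [[Rcpp::export(name = ".ngtdm_stats_cpp")]]
List ngtdm_stats_cpp(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector s(G);
  NumericVector nvox(G);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          for (int dy = -1; dy <= 1; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              const int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj > 0) {
                sum += lj;
                ++cnt;
              }
            }
          }
        }
        if (cnt > 0) {
          nvox[li - 1] += 1.0;
          s[li - 1] += std::abs((double)li - sum / cnt);
        }
      }
    }
  }
  return List::create(_["n"] = nvox, _["s"] = s);
}
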