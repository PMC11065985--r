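#include <Rcpp.h>
#include <algorithm>
#include "vt_core.h"
using namespace Rcpp;

// Hildebrand-Ruegsegger local thickness: for every vessel voxel, the
// diameter of the largest inscribed sphere (fully inside the vessel set)
// that contains the voxel center. Computed as distance transform ->
// distance ridge -> sphere painting. The inscribed radius at a voxel is
// its Euclidean distance to the nearest background voxel center (outside
// the grid counts as background); a sphere of radius r centered at c
// covers voxels with |p - c| < r.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing, double range_max) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  // squared EDT to background (border = background)
  std::vector<double> f(n);
  for (long long i = 0; i < n; i++)
    f[i] = mask[i] ? std::numeric_limits<double>::infinity() : 0.0;
  vt_sqedt(f, nullptr, nx, ny, nz, sx, sy, sz);
  std::vector<float> r(n, 0.0f);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long long i = g.idx(x, y, z);
        if (!mask[i]) continue;
        double dx = sx * std::min(x + 1, nx - x);
        double dy = sy * std::min(y + 1, ny - y);
        double dz = sz * std::min(z + 1, nz - z);
        double db = std::min(dx, std::min(dy, dz));
        r[i] = (float)std::sqrt(std::min(f[i], db * db));
      }
  f.clear(); f.shrink_to_fit();

  // distance ridge: drop voxels whose inscribed sphere is contained in a
  // 26-neighbor's sphere (r_n >= r_v + |n - v|); containment chains always
  // end at a kept voxel, so painting only ridge voxels is exact.
  std::vector<long long> ridge;
  const double eps = 1e-9;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long long i = g.idx(x, y, z);
        if (!mask[i]) continue;
        bool covered = false;
        for (int c = -1; c <= 1 && !covered; c++)
          for (int b = -1; b <= 1 && !covered; b++)
            for (int a = -1; a <= 1 && !covered; a++) {
              if (a == 0 && b == 0 && c == 0) continue;
              int xx = x + a, yy = y + b, zz = z + c;
              if (!g.inside(xx, yy, zz)) continue;
              long long j = g.idx(xx, yy, zz);
              if (!mask[j]) continue;
              double step = std::sqrt(a * a * sx * sx + b * b * sy * sy +
                                      c * c * sz * sz);
              if (r[j] >= r[i] + step - eps) covered = true;
            }
        if (!covered) ridge.push_back(i);
      }

  // paint spheres, largest radius first
  std::sort(ridge.begin(), ridge.end(), [&](long long a, long long b) {
    if (r[a] != r[b]) return r[a] > r[b];
    return a < b;
  });
  std::vector<float> th(n, 0.0f);
  for (long long i : ridge) {
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / ((long long)nx * ny));
    double rv = r[i];
    double d = std::min(2.0 * rv, range_max);
    int ax = (int)std::floor(rv / sx), ay = (int)std::floor(rv / sy),
        az = (int)std::floor(rv / sz);
    double r2 = rv * rv - 1e-9;
    for (int c = std::max(0, z - az); c <= std::min(nz - 1, z + az); c++) {
      double pz = (c - z) * sz;
      for (int b = std::max(0, y - ay); b <= std::min(ny - 1, y + ay); b++) {
        double py = (b - y) * sy;
        double q = r2 - pz * pz - py * py;
        if (q < 0) continue;
        double px = std::sqrt(q) / sx;
        int lo = std::max(0, (int)std::ceil(x - px));
        int hi = std::min(nx - 1, (int)std::floor(x + px));
        long long base = g.idx(0, b, c);
        for (int a = lo; a <= hi; a++) {
          long long j = base + a;
          if (mask[j] && th[j] < d) th[j] = (float)d;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericVector out(n);
  for (long long i = 0; i < n; i++)
    out[i] = mask[i] ? (double)th[i] : NA_REAL;
  return out;
}
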