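#include <Rcpp.h>
#include <algorithm>
#include "vt_core.h"
using namespace Rcpp;

// reflect index into [0, n-1]; folds repeatedly so offsets larger than the
// axis length stay in range
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// 3x3x3 median filter, reflected borders.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  NumericVector out(g.size());
  double nb[27];
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int m = 0;
        for (int c = -1; c <= 1; c++)
          for (int b = -1; b <= 1; b++)
            for (int a = -1; a <= 1; a++)
              nb[m++] = vol[g.idx(refl(x + a, nx), refl(y + b, ny),
                                  refl(z + c, nz))];
        std::nth_element(nb, nb + 13, nb + 27);
        out[g.idx(x, y, z)] = nb[13];
      }
  return out;
}

// Separable Gaussian blur, sigma per axis in voxel units, reflected borders.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim,
                             NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; i++) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (double& v : k) v /= sum;
    int nax = dims[ax];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          double acc = 0;
          for (int i = -r; i <= r; i++) {
            int xx = x, yy = y, zz = z;
            if (ax == 0) xx = refl(x + i, nax);
            else if (ax == 1) yy = refl(y + i, nax);
            else zz = refl(z + i, nax);
            acc += k[i + r] * a[g.idx(xx, yy, zz)];
          }
          b[g.idx(x, y, z)] = acc;
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Resample onto a new grid covering the same physical extent.
// frac coordinate of new voxel i along an axis: (i + 0.5)*ratio - 0.5
// where ratio = new_spacing/old_spacing. mode: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           IntegerVector new_dim, NumericVector ratio,
                           int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = new_dim[0], my = new_dim[1], mz = new_dim[2];
  Grid3 g(nx, ny, nz), h(mx, my, mz);
  NumericVector out(h.size());
  for (int z = 0; z < mz; z++) {
    double fz = (z + 0.5) * ratio[2] - 0.5;
    for (int y = 0; y < my; y++) {
      double fy = (y + 0.5) * ratio[1] - 0.5;
      for (int x = 0; x < mx; x++) {
        double fx = (x + 0.5) * ratio[0] - 0.5;
        double v;
        if (mode == 0) {
          int ix = std::min(nx - 1, std::max(0, (int)std::lround(fx)));
          int iy = std::min(ny - 1, std::max(0, (int)std::lround(fy)));
          int iz = std::min(nz - 1, std::max(0, (int)std::lround(fz)));
          v = vol[g.idx(ix, iy, iz)];
        } else {
          double cx = std::min((double)nx - 1.0, std::max(0.0, fx));
          double cy = std::min((double)ny - 1.0, std::max(0.0, fy));
          double cz = std::min((double)nz - 1.0, std::max(0.0, fz));
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double tx = cx - x0, ty = cy - y0, tz = cz - z0;
          double c000 = vol[g.idx(x0, y0, z0)], c100 = vol[g.idx(x1, y0, z0)];
          double c010 = vol[g.idx(x0, y1, z0)], c110 = vol[g.idx(x1, y1, z0)];
          double c001 = vol[g.idx(x0, y0, z1)], c101 = vol[g.idx(x1, y0, z1)];
          double c011 = vol[g.idx(x0, y1, z1)], c111 = vol[g.idx(x1, y1, z1)];
          double c00 = c000 * (1 - tx) + c100 * tx;
          double c10 = c010 * (1 - tx) + c110 * tx;
          double c01 = c001 * (1 - tx) + c101 * tx;
          double c11 = c011 * (1 - tx) + c111 * tx;
          double c0 = c00 * (1 - ty) + c10 * ty;
          double c1 = c01 * (1 - ty) + c11 * ty;
          v = c0 * (1 - tz) + c1 * tz;
        }
        out[h.idx(x, y, z)] = v;
      }
    }
  }
  return out;
}
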