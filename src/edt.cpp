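#include <Rcpp.h>
#include <unordered_map>
#include "vt_core.h"
using namespace Rcpp;

static const double VT_INF = std::numeric_limits<double>::infinity();

// 1D lower-envelope distance transform over samples at positions i*step.
// f: squared distances in/out (length n, stride-gathered by caller).
// site: nearest-site ids carried along (may be null).
static void dt1d(std::vector<double>& f, std::vector<long long>* site,
                 int n, double step,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& fbuf, std::vector<long long>& sbuf) {
  int k = 0;
  v[0] = 0;
  z[0] = -VT_INF;
  z[1] = VT_INF;
  const double s2 = step * step;
  for (int q = 1; q < n; q++) {
    if (f[q] == VT_INF && f[v[k]] == VT_INF) { continue; }
    double s;
    while (true) {
      int p = v[k];
      // intersection of parabolas from p and q (in index units)
      if (f[p] == VT_INF) { s = -VT_INF; }
      else if (f[q] == VT_INF) { s = VT_INF; }
      else {
        s = ((f[q] - f[p]) / s2 + (double)q * q - (double)p * p) /
            (2.0 * (q - p));
      }
      if (s <= z[k]) { k--; if (k < 0) { k = 0; v[0] = q; z[0] = -VT_INF; z[1] = VT_INF; goto placed; } }
      else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = VT_INF;
    placed:;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < (double)q) j++;
    int p = v[j];
    double d = (double)(q - p) * (q - p) * s2;
    fbuf[q] = (f[p] == VT_INF) ? VT_INF : f[p] + d;
    if (site) sbuf[q] = (*site)[p];
  }
  for (int q = 0; q < n; q++) {
    f[q] = fbuf[q];
    if (site) (*site)[q] = sbuf[q];
  }
}

void vt_sqedt(std::vector<double>& f, std::vector<long long>* site,
              int nx, int ny, int nz,
              double sx, double sy, double sz) {
  Grid3 g(nx, ny, nz);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax + 1);
  std::vector<double> z(nmax + 2), line(nmax), fbuf(nmax);
  std::vector<long long> sline(nmax), sbuf(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      long long base = g.idx(0, yy, zz);
      for (int xx = 0; xx < nx; xx++) { line[xx] = f[base + xx]; if (site) sline[xx] = (*site)[base + xx]; }
      std::vector<long long>* sp = site ? &sline : nullptr;
      dt1d(line, sp, nx, sx, v, z, fbuf, sbuf);
      for (int xx = 0; xx < nx; xx++) { f[base + xx] = line[xx]; if (site) (*site)[base + xx] = sline[xx]; }
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      for (int yy = 0; yy < ny; yy++) { long long i = g.idx(xx, yy, zz); line[yy] = f[i]; if (site) sline[yy] = (*site)[i]; }
      std::vector<long long>* sp = site ? &sline : nullptr;
      dt1d(line, sp, ny, sy, v, z, fbuf, sbuf);
      for (int yy = 0; yy < ny; yy++) { long long i = g.idx(xx, yy, zz); f[i] = line[yy]; if (site) (*site)[i] = sline[yy]; }
    }
  // pass along z
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      for (int zz = 0; zz < nz; zz++) { long long i = g.idx(xx, yy, zz); line[zz] = f[i]; if (site) sline[zz] = (*site)[i]; }
      std::vector<long long>* sp = site ? &sline : nullptr;
      dt1d(line, sp, nz, sz, v, z, fbuf, sbuf);
      for (int zz = 0; zz < nz; zz++) { long long i = g.idx(xx, yy, zz); f[i] = line[zz]; if (site) (*site)[i] = sline[zz]; }
    }
}

// Distance (um) from each voxel to the nearest background voxel center.
// border_bg: treat the region outside the grid as background (distance to
// the nearest grid face measured center-to-center).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing, bool border_bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<double> f(n);
  for (long long i = 0; i < n; i++) f[i] = mask[i] ? VT_INF : 0.0;
  vt_sqedt(f, nullptr, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
  NumericVector out(n);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        long long i = g.idx(xx, yy, zz);
        double d2 = f[i];
        if (border_bg) {
          double dx = spacing[0] * std::min(xx + 1, nx - xx);
          double dy = spacing[1] * std::min(yy + 1, ny - yy);
          double dz = spacing[2] * std::min(zz + 1, nz - zz);
          double db = std::min(dx, std::min(dy, dz));
          d2 = std::min(d2, db * db);
        }
        out[i] = std::sqrt(d2);
      }
  return out;
}

// Nearest-seed (feature transform) labelling: every voxel gets the label of
// the Euclidean-nearest seed voxel (by voxel-center physical distance).
// seeds: 0-based linear indices; labels: parallel integer labels.
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(IntegerVector dim, NumericVector spacing,
                               NumericVector seeds, IntegerVector labels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<double> f(n, VT_INF);
  std::vector<long long> site(n, -1);
  for (int s = 0; s < seeds.size(); s++) {
    long long i = (long long)seeds[s];
    f[i] = 0.0;
    site[i] = i;
  }
  vt_sqedt(f, &site, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
  // map site linear index -> label
  std::unordered_map<long long, int> lab;
  lab.reserve(seeds.size() * 2);
  for (int s = 0; s < seeds.size(); s++) lab[(long long)seeds[s]] = labels[s];
  IntegerVector out(n);
  for (long long i = 0; i < n; i++)
    out[i] = (site[i] >= 0) ? lab[site[i]] : NA_INTEGER;
  return out;
}
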