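#include <Rcpp.h>
#include "vt_core.h"
using namespace Rcpp;

// Neighbour offset tables. 6-connectivity for background, 26 for vessel
// (the standard digital-topology pairing).
static void offsets(int conn, std::vector<int>& dx, std::vector<int>& dy,
                    std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && m != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<int> dx, dy, dz;
  offsets(conn, dx, dy, dz);
  IntegerVector lab(n);
  std::vector<long long> stack;
  int next = 0;
  for (long long s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((long long)nx * ny));
      for (size_t k = 0; k < dx.size(); k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (!g.inside(xx, yy, zz)) continue;
        long long i = g.idx(xx, yy, zz);
        if (mask[i] && lab[i] == 0) { lab[i] = next; stack.push_back(i); }
      }
    }
  }
  return lab;
}

// 26-connected intensity-window region growing from seed voxels.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              NumericVector seeds, double low, double high) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<int> dx, dy, dz;
  offsets(26, dx, dy, dz);
  LogicalVector out(n);
  std::vector<long long> stack;
  for (int s = 0; s < seeds.size(); s++) {
    long long i = (long long)seeds[s];
    if (!out[i]) { out[i] = true; stack.push_back(i); }
  }
  while (!stack.empty()) {
    long long cur = stack.back(); stack.pop_back();
    int x = (int)(cur % nx);
    int y = (int)((cur / nx) % ny);
    int z = (int)(cur / ((long long)nx * ny));
    for (size_t k = 0; k < dx.size(); k++) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (!g.inside(xx, yy, zz)) continue;
      long long i = g.idx(xx, yy, zz);
      if (!out[i] && vol[i] >= low && vol[i] <= high) {
        out[i] = true;
        stack.push_back(i);
      }
    }
  }
  return out;
}

// Background voxels 6-connected to the grid border (used to detect
// enclosed cavities: background NOT reached here is a cavity).
// [[Rcpp::export]]
LogicalVector cpp_background_from_border(LogicalVector mask,
                                         IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<int> dx, dy, dz;
  offsets(6, dx, dy, dz);
  LogicalVector out(n);
  std::vector<long long> stack;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 &&
            z != 0 && z != nz - 1) continue;
        long long i = g.idx(x, y, z);
        if (!mask[i] && !out[i]) { out[i] = true; stack.push_back(i); }
      }
  while (!stack.empty()) {
    long long cur = stack.back(); stack.pop_back();
    int x = (int)(cur % nx);
    int y = (int)((cur / nx) % ny);
    int z = (int)(cur / ((long long)nx * ny));
    for (size_t k = 0; k < dx.size(); k++) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (!g.inside(xx, yy, zz)) continue;
      long long i = g.idx(xx, yy, zz);
      if (!mask[i] && !out[i]) { out[i] = true; stack.push_back(i); }
    }
  }
  return out;
}
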