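#include <Rcpp.h>
#include "vt_core.h"
using namespace Rcpp;

// Topology-preserving 3D thinning to a curve skeleton.
// A border voxel is deletable when it is a simple point for the (26,6)
// adjacency pair (Bertrand-Malandain topology numbers T26 = T6 = 1) and is
// not a curve endpoint. Deletion proceeds in 6 directional subiterations
// (U, D, N, S, E, W) with sequential re-checking, which preserves the
// numbers of connected components, cavities and tunnels.

// cell index within the 3x3x3 neighborhood: c = (a+1) + 3*(b+1) + 9*(c+1)
static inline int cellid(int a, int b, int c) {
  return (a + 1) + 3 * (b + 1) + 9 * (c + 1);
}

// T26: number of 26-components of object cells among the 26 neighbors.
static int t26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    comps++;
    int stack[27], top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ca = cur % 3 - 1, cb = (cur / 3) % 3 - 1, cc = cur / 9 - 1;
      for (int a = -1; a <= 1; a++)
        for (int b = -1; b <= 1; b++)
          for (int c = -1; c <= 1; c++) {
            if (a == 0 && b == 0 && c == 0) continue;
            int na = ca + a, nbq = cb + b, nc = cc + c;
            if (na < -1 || na > 1 || nbq < -1 || nbq > 1 || nc < -1 || nc > 1)
              continue;
            int id = cellid(na, nbq, nc);
            if (id == 13 || !nb[id] || seen[id]) continue;
            seen[id] = true;
            stack[top++] = id;
          }
    }
  }
  return comps;
}

// T6: number of 6-components of background cells in the 18-neighborhood
// that contain a 6-neighbor of the center.
static int t6(const bool nb[27]) {
  auto in18 = [](int a, int b, int c) {
    int m = std::abs(a) + std::abs(b) + std::abs(c);
    return m >= 1 && m <= 2;
  };
  bool seen[27] = {false};
  int comps = 0;
  // start BFS only from background 6-neighbors of the center
  const int f6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int s = 0; s < 6; s++) {
    int sa = f6[s][0], sb = f6[s][1], sc = f6[s][2];
    int sid = cellid(sa, sb, sc);
    if (nb[sid] || seen[sid]) continue;
    comps++;
    int stack[27], top = 0;
    stack[top++] = sid;
    seen[sid] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ca = cur % 3 - 1, cb = (cur / 3) % 3 - 1, cc = cur / 9 - 1;
      for (int k = 0; k < 6; k++) {
        int na = ca + f6[k][0], nbq = cb + f6[k][1], nc = cc + f6[k][2];
        if (na < -1 || na > 1 || nbq < -1 || nbq > 1 || nc < -1 || nc > 1)
          continue;
        if (!in18(na, nbq, nc)) continue;
        int id = cellid(na, nbq, nc);
        if (nb[id] || seen[id]) continue;
        seen[id] = true;
        stack[top++] = id;
      }
    }
  }
  return comps;
}

static inline void fill_nb(const std::vector<uint8_t>& obj, const Grid3& g,
                           int x, int y, int z, bool nb[27]) {
  for (int c = -1; c <= 1; c++)
    for (int b = -1; b <= 1; b++)
      for (int a = -1; a <= 1; a++) {
        int xx = x + a, yy = y + b, zz = z + c;
        nb[cellid(a, b, c)] =
            g.inside(xx, yy, zz) && obj[g.idx(xx, yy, zz)];
      }
}

static inline int n26_count(const bool nb[27]) {
  int cnt = 0;
  for (int i = 0; i < 27; i++)
    if (i != 13 && nb[i]) cnt++;
  return cnt;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  long long n = g.size();
  std::vector<uint8_t> obj(n);
  std::vector<long long> vox;
  for (long long i = 0; i < n; i++) {
    obj[i] = mask[i] ? 1 : 0;
    if (obj[i]) vox.push_back(i);
  }
  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool nb[27];
  std::vector<long long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (long long i : vox) {
        if (!obj[i]) continue;
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((long long)nx * ny));
        int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
        bool border = !g.inside(xx, yy, zz) || !obj[g.idx(xx, yy, zz)];
        if (!border) continue;
        fill_nb(obj, g, x, y, z, nb);
        int cnt = n26_count(nb);
        if (cnt <= 1) continue;  // endpoint or isolated: keep
        if (t26(nb) == 1 && t6(nb) == 1) cand.push_back(i);
      }
      // sequential re-check: a deletion may invalidate later candidates
      for (long long i : cand) {
        int x = (int)(i % nx);
        int y = (int)((i / nx) % ny);
        int z = (int)(i / ((long long)nx * ny));
        fill_nb(obj, g, x, y, z, nb);
        int cnt = n26_count(nb);
        if (cnt <= 1) continue;
        if (t26(nb) == 1 && t6(nb) == 1) {
          obj[i] = 0;
          changed = true;
        }
      }
    }
    // compact the voxel list
    if (changed) {
      std::vector<long long> keep;
      keep.reserve(vox.size());
      for (long long i : vox)
        if (obj[i]) keep.push_back(i);
      vox.swap(keep);
    }
    Rcpp::checkUserInterrupt();
  }
  LogicalVector out(n);
  for (long long i : vox) out[i] = true;
  return out;
}
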