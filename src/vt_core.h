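#ifndef VT_CORE_H
#define VT_CORE_H

#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

// Shared helpers for 3D grids stored column-major as [x, y, z]
// (R array layout: linear index = x + nx*(y + ny*z), 0-based here).

struct Grid3 {
  int nx, ny, nz;
  Grid3(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_) {}
  inline long long size() const { return (long long)nx * ny * nz; }
  inline long long idx(int x, int y, int z) const {
    return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// anisotropic spacing, with optional nearest-site (feature) tracking.
// f: input squared distances (0 at sites, +inf elsewhere), overwritten.
// site: if non-null, per-voxel linear index of the nearest site, updated.
void vt_sqedt(std::vector<double>& f, std::vector<long long>* site,
              int nx, int ny, int nz,
              double sx, double sy, double sz);

#endif
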