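#include <Rcpp.h>
#include "vt_core.h"
using namespace Rcpp;

// Rasterize a union of capsules (cylinders with hemispherical caps).
// p0, p1: m x 3 segment endpoints (um, physical); radius: m (um).
// A voxel is vessel iff its center lies within distance r of a segment.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(IntegerVector dim, NumericVector spacing,
                                     NumericVector origin, NumericMatrix p0,
                                     NumericMatrix p1, NumericVector radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  LogicalVector out(g.size());
  for (int s = 0; s < p0.nrow(); s++) {
    double ax = p0(s, 0), ay = p0(s, 1), az = p0(s, 2);
    double bx = p1(s, 0), by = p1(s, 1), bz = p1(s, 2);
    double r = radius[s], r2 = r * r;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    // voxel-index bounding box padded by the radius
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - r - origin[0]) / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + r - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - r - origin[1]) / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + r - origin[1]) / spacing[1]));
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - r - origin[2]) / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + r - origin[2]) / spacing[2]));
    for (int z = z0; z <= z1; z++) {
      double pz = origin[2] + z * spacing[2];
      for (int y = y0; y <= y1; y++) {
        double py = origin[1] + y * spacing[1];
        for (int x = x0; x <= x1; x++) {
          double px = origin[0] + x * spacing[0];
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = (L2 > 0) ? (wx * ux + wy * uy + wz * uz) / L2 : 0.0;
          t = std::max(0.0, std::min(1.0, t));
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[g.idx(x, y, z)] = true;
        }
      }
    }
  }
  return out;
}

// Carve spheres out of a mask (casting-gap artifacts).
// [[Rcpp::export]]
LogicalVector cpp_carve_spheres(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix centers, NumericVector radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  LogicalVector out = clone(mask);
  for (int s = 0; s < centers.nrow(); s++) {
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    double r = radius[s], r2 = r * r;
    int x0 = std::max(0, (int)std::floor((cx - r - origin[0]) / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + r - origin[0]) / spacing[0]));
    int y0 = std::max(0, (int)std::floor((cy - r - origin[1]) / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + r - origin[1]) / spacing[1]));
    int z0 = std::max(0, (int)std::floor((cz - r - origin[2]) / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r - origin[2]) / spacing[2]));
    for (int z = z0; z <= z1; z++)
      for (int y = y0; y <= y1; y++)
        for (int x = x0; x <= x1; x++) {
          double dx = origin[0] + x * spacing[0] - cx;
          double dy = origin[1] + y * spacing[1] - cy;
          double dz = origin[2] + z * spacing[2] - cz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[g.idx(x, y, z)] = false;
        }
  }
  return out;
}

// Voxelize a watertight triangle mesh by parity ray casting along +x.
// verts: n x 3 (um); faces: m x 3 (0-based). A voxel is inside iff the ray
// from its center crosses the surface an odd number of times.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix verts, IntegerMatrix faces,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Grid3 g(nx, ny, nz);
  LogicalVector out(g.size());
  int m = faces.nrow();
  // tiny deterministic ray offset avoids exact vertex/edge hits
  double ey = 0.127913 * spacing[1], ez = 0.081731 * spacing[2];
  std::vector<double> xs;
  for (int z = 0; z < nz; z++) {
    double rz = origin[2] + z * spacing[2] + ez;
    for (int y = 0; y < ny; y++) {
      double ry = origin[1] + y * spacing[1] + ey;
      xs.clear();
      for (int t = 0; t < m; t++) {
        const double* A = &verts(faces(t, 0), 0);
        // gather vertices (column-major access via matrix API)
        double ax = verts(faces(t, 0), 0), ay = verts(faces(t, 0), 1),
               az = verts(faces(t, 0), 2);
        double bx = verts(faces(t, 1), 0), by = verts(faces(t, 1), 1),
               bz = verts(faces(t, 1), 2);
        double cx = verts(faces(t, 2), 0), cy = verts(faces(t, 2), 1),
               cz = verts(faces(t, 2), 2);
        (void)A;
        // quick reject in the (y,z) plane
        if (std::max(ay, std::max(by, cy)) < ry ||
            std::min(ay, std::min(by, cy)) > ry)
          continue;
        if (std::max(az, std::max(bz, cz)) < rz ||
            std::min(az, std::min(bz, cz)) > rz)
          continue;
        // 2D barycentric in (y,z)
        double d = (by - ay) * (cz - az) - (bz - az) * (cy - ay);
        if (d == 0) continue;  // triangle parallel to the ray
        double l1 = ((ry - ay) * (cz - az) - (rz - az) * (cy - ay)) / d;
        double l2 = ((by - ay) * (rz - az) - (bz - az) * (ry - ay)) / d;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        xs.push_back(ax + l1 * (bx - ax) + l2 * (cx - ax));
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // walk voxel centers along x, counting crossings passed
      size_t j = 0;
      for (int x = 0; x < nx; x++) {
        double rx = origin[0] + x * spacing[0];
        while (j < xs.size() && xs[j] < rx) j++;
        if (j % 2 == 1) out[g.idx(x, y, z)] = true;
      }
      // reset j for next row
    }
  }
  return out;
}
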