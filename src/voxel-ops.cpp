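#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are indexed [z, y, x] column-major (R convention):
// linear = z + nz*y + nz*ny*x, all 0-based here.

// Connected-component labeling of a binary 3D grid.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full); a 2D grid
// (nz == 1) under 26-connectivity reduces to the usual 8-connectivity.
// Returns an integer grid with background 0 and components labeled 1..n
// in order of first (linear-scan) occurrence.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dzv, dyv, dxv;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dzv.push_back(dz); dyv.push_back(dy); dxv.push_back(dx);
      }
  const int nb = (int)dzv.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nb; ++k) {
        int zz = z + dzv[k], yy = y + dyv[k], xx = x + dxv[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * yy + (R_xlen_t)nz * ny * xx;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Two-pass anisotropic chamfer distance transform: for every foreground
// voxel, the approximate distance (in physical units) to the nearest
// background voxel, propagated over the 26-neighbourhood with weights
// equal to the physical offset lengths.  Voxels on the grid border are
// treated as adjacent to background (distance capped at half the voxel
// diagonal step outward).
// [[Rcpp::export(name = ".chamfer_dt_cpp")]]
NumericVector chamfer_dt_cpp(LogicalVector mask, IntegerVector dim, NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  const double dz = voxel[0], dy = voxel[1], dx = voxel[2];
  const double big = 1e30;

  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? big : 0.0;

  // forward-half neighbour offsets (those already visited in a raster scan)
  std::vector<int> off_z, off_y, off_x;
  std::vector<double> w;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        // visited-before in scan order x (outer), y, z (inner)?
        // scan order below iterates x, then y, then z (linear order).
        if (ax < 0 || (ax == 0 && ay < 0) || (ax == 0 && ay == 0 && az < 0)) {
          off_z.push_back(az); off_y.push_back(ay); off_x.push_back(ax);
          w.push_back(std::sqrt(az * dz * az * dz + ay * dy * ay * dy + ax * dx * ax * dx));
        }
      }
  const int nb = (int)off_z.size();

  // boundary seed: foreground voxels on the grid border are one step from
  // outside-background, but a singleton axis (e.g. a 2D slice) has no
  // out-of-plane background
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    double b = big;
    if (nz > 1 && (z == 0 || z == nz - 1)) b = std::min(b, dz);
    if (ny > 1 && (y == 0 || y == ny - 1)) b = std::min(b, dy);
    if (nx > 1 && (x == 0 || x == nx - 1)) b = std::min(b, dx);
    if (b < big) d[i] = b;
  }

  // forward pass
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * y + (R_xlen_t)nz * ny * x;
        if (!mask[i]) continue;
        double cur = d[i];
        for (int k = 0; k < nb; ++k) {
          int zz = z + off_z[k], yy = y + off_y[k], xx = x + off_x[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t q = zz + (R_xlen_t)nz * yy + (R_xlen_t)nz * ny * xx;
          double cand = d[q] + w[k];
          if (cand < cur) cur = cand;
        }
        d[i] = cur;
      }

  // backward pass (mirrored offsets)
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        R_xlen_t i = z + (R_xlen_t)nz * y + (R_xlen_t)nz * ny * x;
        if (!mask[i]) continue;
        double cur = d[i];
        for (int k = 0; k < nb; ++k) {
          int zz = z - off_z[k], yy = y - off_y[k], xx = x - off_x[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t q = zz + (R_xlen_t)nz * yy + (R_xlen_t)nz * ny * xx;
          double cand = d[q] + w[k];
          if (cand < cur) cur = cand;
        }
        d[i] = cur;
      }

  d.attr("dim") = dim;
  return d;
}
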