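#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a volume at continuous 0-based voxel coordinates.
// Coordinates outside [0, n-1] contribute 0 (handled by the caller's
// ray clipping; clamped here only against round-off at the hull).
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
  if (gx < 0.0) gx = 0.0; if (gx > nx - 1.0) gx = nx - 1.0;
  if (gy < 0.0) gy = 0.0; if (gy > ny - 1.0) gy = ny - 1.0;
  if (gz < 0.0) gz = 0.0; if (gz > nz - 1.0) gz = nz - 1.0;
  int x0 = (int)gx, y0 = (int)gy, z0 = (int)gz;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  const double *p = v + (size_t)x0 + (size_t)nx * ((size_t)y0 + (size_t)ny * z0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Line integrals of trilinearly interpolated attenuation from a point
// source to every detector pixel (midpoint rule along the clipped ray).
// Volume indexed [ix, iy, iz] column-major; detector image returned as
// an nv x nu matrix (rows = v, cols = u).
// [[Rcpp::export]]
NumericMatrix raycast_cpp(NumericVector vol, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericVector src, NumericVector det_center,
                          NumericVector eu, NumericVector ev,
                          double pitch, int nu, int nv, double step) {
  const double *v = vol.begin();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // hull spanned by voxel centers
  double lo[3] = {ox, oy, oz};
  double hi[3] = {ox + (nx - 1) * sx, oy + (ny - 1) * sy, oz + (nz - 1) * sz};
  NumericMatrix out(nv, nu);
  double cu = (nu + 1) / 2.0, cv = (nv + 1) / 2.0;
  for (int j = 0; j < nu; ++j) {
    double umm = ((j + 1) - cu) * pitch;
    for (int i = 0; i < nv; ++i) {
      double vmm = ((i + 1) - cv) * pitch;
      double px = det_center[0] + umm * eu[0] + vmm * ev[0];
      double py = det_center[1] + umm * eu[1] + vmm * ev[1];
      double pz = det_center[2] + umm * eu[2] + vmm * ev[2];
      double dx = px - src[0], dy = py - src[1], dz = pz - src[2];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= len; dy /= len; dz /= len;
      // slab clipping against the voxel-center hull
      double tmin = 0.0, tmax = len, d[3] = {dx, dy, dz},
             s0[3] = {src[0], src[1], src[2]};
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-12) {
          if (s0[a] < lo[a] || s0[a] > hi[a]) { miss = true; break; }
        } else {
          double t1 = (lo[a] - s0[a]) / d[a], t2 = (hi[a] - s0[a]) / d[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
          if (tmin >= tmax) { miss = true; break; }
        }
      }
      if (miss) { out(i, j) = 0.0; continue; }
      int n = (int)std::ceil((tmax - tmin) / step);
      if (n < 1) n = 1;
      double dt = (tmax - tmin) / n, acc = 0.0;
      for (int k = 0; k < n; ++k) {
        double t = tmin + (k + 0.5) * dt;
        double gx = (s0[0] + t * dx - ox) / sx;
        double gy = (s0[1] + t * dy - oy) / sy;
        double gz = (s0[2] + t * dz - oz) / sz;
        acc += trilinear(v, nx, ny, nz, gx, gy, gz);
      }
      out(i, j) = acc * dt;
    }
  }
  return out;
}
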