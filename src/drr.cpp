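#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Trilinear sample of a column-major 3D grid at continuous index (x, y, z).
// Valid domain is [0, n-1] per axis; the caller clips rays to that box.
static inline double trilinear(const double *d, int nx, int ny, int nz,
                               double x, double y, double z) {
  int i0 = (int)std::floor(x);
  int j0 = (int)std::floor(y);
  int k0 = (int)std::floor(z);
  if (i0 < 0 || j0 < 0 || k0 < 0) return 0.0;
  if (i0 > nx - 1 || j0 > ny - 1 || k0 > nz - 1) return 0.0;
  if (i0 == nx - 1) i0 = nx - 2;
  if (j0 == ny - 1) j0 = ny - 2;
  if (k0 == nz - 1) k0 = nz - 2;
  if (nx == 1 || ny == 1 || nz == 1) return 0.0; // degenerate grid
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double *p = d + (size_t)i0 + (size_t)nx * ((size_t)j0 + (size_t)ny * k0);
  size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Line-integral DRR: for each detector pixel, integrate the trilinearly
// interpolated density along the source->pixel ray with fixed step length
// (midpoint rule), in model coordinates. Rays are clipped to the volume's
// valid interpolation box. Returns an nu x nv matrix (u fastest).
// [[Rcpp::export(name = ".render_drr_cpp")]]
NumericMatrix render_drr_cpp(NumericVector data, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix Rwm, NumericVector tvec,
                             NumericVector source, NumericVector det_origin,
                             NumericVector ex, NumericVector ey,
                             double du, double dv, int nu, int nv,
                             int ds, double step, IntegerVector roi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *d = REAL(data);
  // model coordinates of the source: R^T (s - t)
  double sm[3], sw[3];
  for (int a = 0; a < 3; ++a) sw[a] = source[a] - tvec[a];
  for (int a = 0; a < 3; ++a)
    sm[a] = Rwm(0, a) * sw[0] + Rwm(1, a) * sw[1] + Rwm(2, a) * sw[2];
  // valid interpolation box in model mm
  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = origin[a];
    bhi[a] = origin[a] + (dims[a] - 1) * spacing[a];
  }
  // roi: 0-based inclusive pixel window (i0, i1, j0, j1) in the output grid
  int i0r = std::max(roi[0], 0), i1r = std::min(roi[1], nu - 1);
  int j0r = std::max(roi[2], 0), j1r = std::min(roi[3], nv - 1);
  NumericMatrix out(nu, nv);
  const double inv_sp[3] = {1.0 / spacing[0], 1.0 / spacing[1],
                            1.0 / spacing[2]};
  for (int j = j0r; j <= j1r; ++j) {
    double v = ((double)j * ds + 0.5) * dv;
    for (int i = i0r; i <= i1r; ++i) {
      double u = ((double)i * ds + 0.5) * du;
      // pixel center in world, then in model coordinates
      double pw[3], pm[3];
      for (int a = 0; a < 3; ++a)
        pw[a] = det_origin[a] + u * ex[a] + v * ey[a] - tvec[a];
      for (int a = 0; a < 3; ++a)
        pm[a] = Rwm(0, a) * pw[0] + Rwm(1, a) * pw[1] + Rwm(2, a) * pw[2];
      double dir[3];
      double L = 0.0;
      for (int a = 0; a < 3; ++a) {
        dir[a] = pm[a] - sm[a];
        L += dir[a] * dir[a];
      }
      L = std::sqrt(L);
      if (L <= 0.0) continue;
      for (int a = 0; a < 3; ++a) dir[a] /= L;
      // clip [0, L] to the box (slab method)
      double t0 = 0.0, t1 = L;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (sm[a] < blo[a] || sm[a] > bhi[a]) { miss = true; break; }
        } else {
          double ta = (blo[a] - sm[a]) / dir[a];
          double tb = (bhi[a] - sm[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta);
          t1 = std::min(t1, tb);
          if (t0 >= t1) { miss = true; break; }
        }
      }
      if (miss) continue;
      // march in continuous-index space with precomputed increments
      double tmid = t0 + 0.5 * step;
      double x = (sm[0] + tmid * dir[0] - origin[0]) * inv_sp[0];
      double y = (sm[1] + tmid * dir[1] - origin[1]) * inv_sp[1];
      double z = (sm[2] + tmid * dir[2] - origin[2]) * inv_sp[2];
      double ix = step * dir[0] * inv_sp[0];
      double iy = step * dir[1] * inv_sp[1];
      double iz = step * dir[2] * inv_sp[2];
      double acc = 0.0;
      for (double t = tmid; t < t1; t += step) {
        acc += trilinear(d, nx, ny, nz, x, y, z);
        x += ix; y += iy; z += iz;
      }
      out(i, j) = acc * step;
    }
  }
  return out;
}
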