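#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam line integrals of two scalar volumes (delta and beta grids)
// along rays in x-y planes; the rotation axis is z (third dimension).
// Voxel values live at voxel centres ((i+0.5)p, (j+0.5)p, (k+0.5)p) in world
// micrometres; outside the grid both fields are zero (vacuum).
//
// For projection angle theta the ray through detector coordinate s in slice
// iz is  p(t) = centre + s*(-sin, cos) + t*(cos, sin), and the integral is a
// midpoint Riemann sum of the in-slice bilinear interpolant at 'step' um.
// Returns matrices (ns x nz): one detector column per s, one row per slice.
// [[Rcpp::export]]
List project_rays_cpp(NumericVector a, NumericVector b, IntegerVector dims,
                      double pitch, double angle_rad, NumericVector s_grid,
                      double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = s_grid.size();
  const double cx = 0.5 * nx * pitch, cy = 0.5 * ny * pitch;
  const double ca = std::cos(angle_rad), sa = std::sin(angle_rad);
  const double T = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * pitch;
  const int nsteps = (int)std::ceil(2.0 * T / step);
  NumericMatrix ia(ns, nz), ib(ns, nz);
  const double *pa = REAL(a), *pb = REAL(b);
  const size_t nxy = (size_t)nx * ny;

  for (int iz = 0; iz < nz; ++iz) {
    const double *sliceA = pa + nxy * iz;
    const double *sliceB = pb + nxy * iz;
    for (int is = 0; is < ns; ++is) {
      const double s = s_grid[is];
      const double ox = cx - s * sa, oy = cy + s * ca;
      double suma = 0.0, sumb = 0.0;
      for (int k = 0; k < nsteps; ++k) {
        const double t = -T + (k + 0.5) * step;
        const double gx = (ox + t * ca) / pitch - 0.5;
        const double gy = (oy + t * sa) / pitch - 0.5;
        const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
        if (i0 < -1 || i0 >= nx || j0 < -1 || j0 >= ny) continue;
        const double fx = gx - i0, fy = gy - j0;
        const bool iok0 = i0 >= 0, iok1 = i0 + 1 < nx;
        const bool jok0 = j0 >= 0, jok1 = j0 + 1 < ny;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy, w11 = fx * fy;
        size_t k00 = (size_t)i0 + (size_t)nx * j0;
        if (iok0 && jok0) { suma += w00 * sliceA[k00]; sumb += w00 * sliceB[k00]; }
        if (iok1 && jok0) { suma += w10 * sliceA[k00 + 1]; sumb += w10 * sliceB[k00 + 1]; }
        if (iok0 && jok1) { suma += w01 * sliceA[k00 + nx]; sumb += w01 * sliceB[k00 + nx]; }
        if (iok1 && jok1) { suma += w11 * sliceA[k00 + nx + 1]; sumb += w11 * sliceB[k00 + nx + 1]; }
      }
      ia(is, iz) = suma * step;
      ib(is, iz) = sumb * step;
    }
  }
  return List::create(_["a"] = ia, _["b"] = ib);
}

// Back-projection of filtered parallel-beam projections onto an n x n slice.
// 'filtered' is n_angles x ns; detector coordinate of column u is s0 + u*ds
// (world um, origin on the rotation axis). Linear interpolation between
// detector samples; output scaled by pi / n_angles (angles span [0, pi)).
// The detector coordinate of pixel (ix, iy) matches the forward convention
// s = -(x-cx)*sin + (y-cy)*cos.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix filtered, NumericVector angles_rad,
                              double s0, double ds, int n, double pitch) {
  const int na = filtered.nrow(), ns = filtered.ncol();
  NumericMatrix out(n, n);
  const double c = 0.5 * n * pitch;
  for (int ai = 0; ai < na; ++ai) {
    const double sa = std::sin(angles_rad[ai]), ca = std::cos(angles_rad[ai]);
    for (int iy = 0; iy < n; ++iy) {
      const double y = (iy + 0.5) * pitch - c;
      const double yc = y * ca;
      for (int ix = 0; ix < n; ++ix) {
        const double x = (ix + 0.5) * pitch - c;
        const double u = (-x * sa + yc - s0) / ds;
        const int u0 = (int)std::floor(u);
        if (u0 < 0 || u0 >= ns - 1) continue;
        const double f = u - u0;
        out(ix, iy) += (1.0 - f) * filtered(ai, u0) + f * filtered(ai, u0 + 1);
      }
    }
  }
  const double scale = M_PI / na;
  for (int i = 0; i < n * n; ++i) out[i] *= scale;
  return out;
}
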