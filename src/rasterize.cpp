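#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize the analytic lung-phantom geometry into a material label grid.
// Labels: 0 = air, 1 = soft tissue, 2 = bone.
//
// The volume starts as air; a soft-tissue cylinder (axis || z, full height)
// emulates the body; rib arcs (partial tori in z = const planes) are bone;
// airway branches (capsules) and alveoli (spheres) carve air back out.
// Voxel (i,j,k) is tested at its centre ((i+0.5)p, (j+0.5)p, (k+0.5)p).
//
// cylinder: c(cx, cy, radius); radius < 0 fills the whole volume with tissue,
// radius == 0 leaves the volume as air.
// branches: columns x0 y0 z0 x1 y1 z1 radius (um)
// spheres:  columns cx cy cz radius (um)
// ribs:     columns cx cy cz ring_radius tube_radius a0 a1 (radians,
//           arc spans a0..a1 going counter-clockwise, a1 > a0)
// [[Rcpp::export]]
IntegerVector rasterize_phantom_cpp(IntegerVector dims, double pitch,
                                    NumericVector cylinder,
                                    NumericMatrix branches,
                                    NumericMatrix spheres,
                                    NumericMatrix ribs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  IntegerVector lab(nvox);
  int *L = INTEGER(lab);

  // tissue cylinder
  const double ccx = cylinder[0], ccy = cylinder[1], cr = cylinder[2];
  if (cr < 0) {
    for (size_t v = 0; v < nvox; ++v) L[v] = 1;
  } else if (cr > 0) {
    const double cr2 = cr * cr;
    for (int j = 0; j < ny; ++j) {
      const double dy = (j + 0.5) * pitch - ccy, dy2 = dy * dy;
      for (int i = 0; i < nx; ++i) {
        const double dx = (i + 0.5) * pitch - ccx;
        if (dx * dx + dy2 <= cr2)
          for (int k = 0; k < nz; ++k) L[i + nx * j + nxy * k] = 1;
      }
    }
  }

  // helper: clamp voxel index range of a world bounding box
  auto lo = [&](double w) { return std::max(0, (int)std::floor(w / pitch - 0.5)); };
  auto hiX = [&](double w, int n) { return std::min(n - 1, (int)std::ceil(w / pitch - 0.5)); };

  // bone rib arcs
  for (int r = 0; r < ribs.nrow(); ++r) {
    const double cx = ribs(r, 0), cy = ribs(r, 1), cz = ribs(r, 2);
    const double R = ribs(r, 3), tr = ribs(r, 4), a0 = ribs(r, 5), a1 = ribs(r, 6);
    const int i0 = lo(cx - R - tr), i1 = hiX(cx + R + tr, nx);
    const int j0 = lo(cy - R - tr), j1 = hiX(cy + R + tr, ny);
    const int k0 = lo(cz - tr), k1 = hiX(cz + tr, nz);
    const double tr2 = tr * tr;
    for (int k = k0; k <= k1; ++k) {
      const double dz = (k + 0.5) * pitch - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = (j + 0.5) * pitch - cy;
        for (int i = i0; i <= i1; ++i) {
          const double dx = (i + 0.5) * pitch - cx;
          const double rho = std::sqrt(dx * dx + dy * dy);
          double ang = std::atan2(dy, dx);
          // bring azimuth into [a0, a0 + 2pi)
          while (ang < a0) ang += 2.0 * M_PI;
          double d2;
          if (ang <= a1) {
            const double dr = rho - R;
            d2 = dr * dr + dz2;
          } else {
            // distance to the nearer arc endpoint
            const double ex0 = cx + R * std::cos(a0), ey0 = cy + R * std::sin(a0);
            const double ex1 = cx + R * std::cos(a1), ey1 = cy + R * std::sin(a1);
            const double d0 = (dx + cx - ex0) * (dx + cx - ex0) + (dy + cy - ey0) * (dy + cy - ey0);
            const double d1 = (dx + cx - ex1) * (dx + cx - ex1) + (dy + cy - ey1) * (dy + cy - ey1);
            d2 = std::min(d0, d1) + dz2;
          }
          if (d2 <= tr2) L[i + nx * j + nxy * k] = 2;
        }
      }
    }
  }

  // airway branches: capsules (cylinder with hemispherical caps)
  for (int b = 0; b < branches.nrow(); ++b) {
    const double x0 = branches(b, 0), y0 = branches(b, 1), z0 = branches(b, 2);
    const double x1 = branches(b, 3), y1 = branches(b, 4), z1 = branches(b, 5);
    const double br = branches(b, 6), br2 = br * br;
    const double ux = x1 - x0, uy = y1 - y0, uz = z1 - z0;
    const double len2 = ux * ux + uy * uy + uz * uz;
    const int i0 = lo(std::min(x0, x1) - br), i1 = hiX(std::max(x0, x1) + br, nx);
    const int j0 = lo(std::min(y0, y1) - br), j1 = hiX(std::max(y0, y1) + br, ny);
    const int k0 = lo(std::min(z0, z1) - br), k1 = hiX(std::max(z0, z1) + br, nz);
    for (int k = k0; k <= k1; ++k) {
      const double pz = (k + 0.5) * pitch;
      for (int j = j0; j <= j1; ++j) {
        const double py = (j + 0.5) * pitch;
        for (int i = i0; i <= i1; ++i) {
          const double px = (i + 0.5) * pitch;
          double t = 0.0;
          if (len2 > 0)
            t = ((px - x0) * ux + (py - y0) * uy + (pz - z0) * uz) / len2;
          t = std::max(0.0, std::min(1.0, t));
          const double qx = x0 + t * ux - px, qy = y0 + t * uy - py, qz = z0 + t * uz - pz;
          if (qx * qx + qy * qy + qz * qz <= br2) L[i + nx * j + nxy * k] = 0;
        }
      }
    }
  }

  // alveolar spheres
  for (int s = 0; s < spheres.nrow(); ++s) {
    const double cx = spheres(s, 0), cy = spheres(s, 1), cz = spheres(s, 2);
    const double sr = spheres(s, 3), sr2 = sr * sr;
    const int i0 = lo(cx - sr), i1 = hiX(cx + sr, nx);
    const int j0 = lo(cy - sr), j1 = hiX(cy + sr, ny);
    const int k0 = lo(cz - sr), k1 = hiX(cz + sr, nz);
    for (int k = k0; k <= k1; ++k) {
      const double dz = (k + 0.5) * pitch - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = (j + 0.5) * pitch - cy, dy2 = dy * dy;
        for (int i = i0; i <= i1; ++i) {
          const double dx = (i + 0.5) * pitch - cx;
          if (dx * dx + dy2 + dz2 <= sr2) L[i + nx * j + nxy * k] = 0;
        }
      }
    }
  }

  lab.attr("dim") = dims;
  return lab;
}
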