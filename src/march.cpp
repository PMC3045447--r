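#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra: each grid cell is split
// into 6 tetrahedra sharing the main diagonal, and the level set of the
// trilinear-ish field is triangulated per tetrahedron. This decomposition
// has no ambiguous cases, so closed components yield watertight meshes.
//
// Field value at grid node (i,j,k) sits at world position
// origin + (i,j,k)*pitch (um). "Inside" is value >= level. Vertices on
// crossing edges are deduplicated exactly via the (node a, node b) key, and
// each triangle is oriented with its normal pointing from inside to outside.

namespace {

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_point(MeshAcc &m, uint64_t ga, uint64_t gb,
                      const double *pa, const double *pb,
                      double va, double vb, double level) {
  if (ga > gb) { std::swap(ga, gb); std::swap(pa, pb); std::swap(va, vb); }
  const uint64_t key = ga * 0x100000000ULL ^ gb;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  const double t = (level - va) / (vb - va);
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  const int id = (int)m.vx.size() - 1;
  m.edge_vertex[key] = id;
  return id;
}

static void add_tri(MeshAcc &m, int a, int b, int c,
                    const double *inside_c, const double *outside_c) {
  // orient so the normal points from the inside region to the outside
  const double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  const double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  const double dx = outside_c[0] - inside_c[0], dy = outside_c[1] - inside_c[1],
               dz = outside_c[2] - inside_c[2];
  if (nx * dx + ny * dy + nz * dz < 0) std::swap(b, c);
  m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c);
}

static void do_tet(MeshAcc &m, const uint64_t g[4], const double p[4][3],
                   const double v[4], double level) {
  int in[4], nin = 0, out[4], nout = 0;
  for (int i = 0; i < 4; ++i) {
    if (v[i] >= level) in[nin++] = i; else out[nout++] = i;
  }
  if (nin == 0 || nin == 4) return;
  double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
  for (int i = 0; i < nin; ++i)
    for (int d = 0; d < 3; ++d) ci[d] += p[in[i]][d] / nin;
  for (int i = 0; i < nout; ++i)
    for (int d = 0; d < 3; ++d) co[d] += p[out[i]][d] / nout;
  if (nin == 1) {
    const int a = in[0];
    const int e0 = edge_point(m, g[a], g[out[0]], p[a], p[out[0]], v[a], v[out[0]], level);
    const int e1 = edge_point(m, g[a], g[out[1]], p[a], p[out[1]], v[a], v[out[1]], level);
    const int e2 = edge_point(m, g[a], g[out[2]], p[a], p[out[2]], v[a], v[out[2]], level);
    add_tri(m, e0, e1, e2, ci, co);
  } else if (nin == 3) {
    const int o = out[0];
    const int e0 = edge_point(m, g[o], g[in[0]], p[o], p[in[0]], v[o], v[in[0]], level);
    const int e1 = edge_point(m, g[o], g[in[1]], p[o], p[in[1]], v[o], v[in[1]], level);
    const int e2 = edge_point(m, g[o], g[in[2]], p[o], p[in[2]], v[o], v[in[2]], level);
    add_tri(m, e0, e1, e2, ci, co);
  } else {
    const int a = in[0], b = in[1], c = out[0], d = out[1];
    const int eac = edge_point(m, g[a], g[c], p[a], p[c], v[a], v[c], level);
    const int ead = edge_point(m, g[a], g[d], p[a], p[d], v[a], v[d], level);
    const int ebc = edge_point(m, g[b], g[c], p[b], p[c], v[b], v[c], level);
    const int ebd = edge_point(m, g[b], g[d], p[b], p[d], v[b], v[d], level);
    add_tri(m, eac, ead, ebd, ci, co);
    add_tri(m, eac, ebd, ebc, ci, co);
  }
}

// the 6-tetrahedra decomposition of a cell, all sharing diagonal 0-6
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

} // namespace

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, IntegerVector dims, double level,
                    double pitch, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *F = REAL(field);
  const size_t nxy = (size_t)nx * ny;
  MeshAcc m;
  uint64_t g[4];
  double p[4][3], v[4];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all corners same side
        bool any_in = false, any_out = false;
        double cv[8];
        for (int c = 0; c < 8; ++c) {
          const size_t idx = (size_t)(i + CORNER[c][0]) +
                             (size_t)nx * (j + CORNER[c][1]) +
                             nxy * (k + CORNER[c][2]);
          cv[c] = F[idx];
          if (cv[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          for (int q = 0; q < 4; ++q) {
            const int c = TETS[t][q];
            const int ii = i + CORNER[c][0], jj = j + CORNER[c][1], kk = k + CORNER[c][2];
            g[q] = (uint64_t)ii + (uint64_t)nx * jj + (uint64_t)nxy * kk;
            p[q][0] = origin[0] + ii * pitch;
            p[q][1] = origin[1] + jj * pitch;
            p[q][2] = origin[2] + kk * pitch;
            v[q] = cv[c];
          }
          do_tet(m, g, p, v, level);
        }
      }
  const int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  double area = 0.0;
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = m.vx[i]; verts(i, 1) = m.vy[i]; verts(i, 2) = m.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    const int a = m.f0[i], b = m.f1[i], c = m.f2[i];
    faces(i, 0) = a + 1; faces(i, 1) = b + 1; faces(i, 2) = c + 1;
    const double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
    const double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
    const double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
    area += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces, _["area"] = area);
}
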