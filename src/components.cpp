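#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void neighbour_offsets(int nx, int ny, int nz, int connectivity,
                                     std::vector<int> &dx, std::vector<int> &dy,
                                     std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (connectivity == 6) {
    const int ox[6] = {1, -1, 0, 0, 0, 0};
    const int oy[6] = {0, 0, 1, -1, 0, 0};
    const int oz[6] = {0, 0, 0, 0, 1, -1};
    for (int i = 0; i < 6; ++i) { dx.push_back(ox[i]); dy.push_back(oy[i]); dz.push_back(oz[i]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// Connected-component labelling of a 3D logical mask (6 or 26 connectivity).
// Components are numbered 1..K in order of their minimum linear voxel index
// (deterministic: the scan is in linear order).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  IntegerVector lab(nvox);
  int *L = INTEGER(lab);
  const int *M = LOGICAL(mask);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(nx, ny, nz, connectivity, dx, dy, dz);
  const int nn = dx.size();
  std::vector<size_t> queue;
  int next = 0;
  for (size_t v0 = 0; v0 < nvox; ++v0) {
    if (M[v0] != TRUE || L[v0] != 0) continue;
    ++next;
    queue.clear();
    queue.push_back(v0);
    L[v0] = next;
    size_t head = 0;
    while (head < queue.size()) {
      const size_t v = queue[head++];
      const int k = v / nxy;
      const size_t rem = v - (size_t)k * nxy;
      const int j = rem / nx, i = rem - (size_t)j * nx;
      for (int q = 0; q < nn; ++q) {
        const int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        const size_t w = (size_t)ii + nx * (size_t)jj + nxy * (size_t)kk;
        if (M[w] == TRUE && L[w] == 0) { L[w] = next; queue.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Seeded flood fill over the intensity predicate (value <= threshold when
// 'below', else value >= threshold): the maximal connected voxel set
// containing the seed in which every voxel satisfies the predicate.
// seed is 0-based (i, j, k).
// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dims,
                              IntegerVector seed, double threshold,
                              bool below, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  const double *V = REAL(vol);
  LogicalVector out(nvox);
  int *O = LOGICAL(out);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(nx, ny, nz, connectivity, dx, dy, dz);
  const int nn = dx.size();
  auto ok = [&](size_t v) { return below ? (V[v] <= threshold) : (V[v] >= threshold); };
  const size_t v0 = (size_t)seed[0] + nx * (size_t)seed[1] + nxy * (size_t)seed[2];
  std::vector<size_t> queue;
  queue.push_back(v0);
  O[v0] = TRUE;
  size_t head = 0;
  while (head < queue.size()) {
    const size_t v = queue[head++];
    const int k = v / nxy;
    const size_t rem = v - (size_t)k * nxy;
    const int j = rem / nx, i = rem - (size_t)j * nx;
    for (int q = 0; q < nn; ++q) {
      const int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      const size_t w = (size_t)ii + nx * (size_t)jj + nxy * (size_t)kk;
      if (!O[w] && ok(w)) { O[w] = TRUE; queue.push_back(w); }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Cubic box-mean filter of half-width 'radius' (window (2r+1)^3), separable,
// normalized by the in-volume window size (edge-aware).
// [[Rcpp::export]]
NumericVector box_mean3_cpp(NumericVector vol, IntegerVector dims, int radius) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const size_t nvox = (size_t)n[0] * n[1] * n[2];
  std::vector<double> cur(REAL(vol), REAL(vol) + nvox), nxt(nvox);
  std::vector<double> wcur(nvox, 1.0), wnxt(nvox);
  const size_t stride[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  for (int axis = 0; axis < 3; ++axis) {
    const size_t st = stride[axis];
    const int len = n[axis];
    const size_t nlines = nvox / len;
    for (size_t line = 0; line < nlines; ++line) {
      // base index of this line
      size_t base = 0, rem = line;
      for (int a = 0; a < 3; ++a) {
        if (a == axis) continue;
        base += (rem % n[a]) * stride[a];
        rem /= n[a];
      }
      for (int i = 0; i < len; ++i) {
        double s = 0.0, w = 0.0;
        const int j0 = std::max(0, i - radius), j1 = std::min(len - 1, i + radius);
        for (int j = j0; j <= j1; ++j) {
          s += cur[base + st * j];
          w += wcur[base + st * j];
        }
        nxt[base + st * i] = s;
        wnxt[base + st * i] = w;
      }
    }
    cur.swap(nxt);
    wcur.swap(wnxt);
  }
  NumericVector out(nvox);
  for (size_t v = 0; v < nvox; ++v) out[v] = cur[v] / wcur[v];
  out.attr("dim") = dims;
  return out;
}
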