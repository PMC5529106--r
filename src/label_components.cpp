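#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labeling of a binary volume by breadth-first
// search. `mask` is a logical/integer array ordered (z, y, x) flattened
// column-major (z fastest), `dims` its extents, `connectivity` 6 or 26.
// Returns an integer array of the same shape: 0 background, 1..k labels
// in scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  // neighbor offsets as (dz, dy, dx) triples
  std::vector<int> oz, oy, ox;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  const int nn = (int)oz.size();

  std::vector<R_xlen_t> queue;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int zi = (int)(v % nz);
      int yi = (int)((v / nz) % ny);
      int xi = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z2 = zi + oz[k], y2 = yi + oy[k], x2 = xi + ox[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[w] != 0 && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Minimum squared physical distance from each query voxel to any positive
// voxel of `mask` (both (z,y,x) index triples, 1-based), with anisotropic
// voxel sizes. Used for surface-proximity tests on small crops.
// [[Rcpp::export]]
double cpp_min_dist2(IntegerMatrix query, IntegerMatrix target,
                     double dz, double dy, double dx) {
  double best = R_PosInf;
  for (int i = 0; i < query.nrow(); ++i) {
    for (int j = 0; j < target.nrow(); ++j) {
      double a = (query(i, 0) - target(j, 0)) * dz;
      double b = (query(i, 1) - target(j, 1)) * dy;
      double c = (query(i, 2) - target(j, 2)) * dx;
      double d2 = a * a + b * b + c * c;
      if (d2 < best) best = d2;
    }
  }
  return best;
}
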