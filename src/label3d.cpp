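#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a logical array stored in R's
// column-major order with dim = (nz, ny, nx).  Connectivity is 6 (faces),
// 18 (faces + edges) or 26 (faces + edges + corners).  Labels are assigned
// in raster-scan order of the first foreground voxel of each component.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dzs, dys, dxs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  const int nn = (int)dzs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z2 = z + dzs[k], y2 = y + dys[k], x2 = x + dxs[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
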