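#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3-D logical array.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels are assigned
// in raster-scan order of each component's first voxel, starting at 1.
// [[Rcpp::export(name = ".labelComponents3D")]]
IntegerVector labelComponents3D(const LogicalVector& vol, int connectivity) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("vol must be a 3-D array");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;

  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }

  IntegerVector lab(ntot, 0);
  lab.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t v = 0; v < ntot; ++v) {
    if (!vol[v] || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      const int rem = (int)(cur % ((R_xlen_t)nx * ny));
      const int y = rem / nx, x = rem % nx;
      for (size_t o = 0; o < offs_dx.size(); ++o) {
        const int xx = x + offs_dx[o], yy = y + offs_dy[o], zz = z + offs_dz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
        if (vol[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
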