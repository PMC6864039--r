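#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable 3-D Gaussian convolution with reflective boundaries.
// sigma is in voxels, per axis; kernels truncated at 4 sigma.
// [[Rcpp::export(name = ".gaussianSmooth3D")]]
NumericVector gaussianSmooth3D(const NumericVector& vol, const NumericVector& sigma) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("vol must be a 3-D array");
  if (sigma.size() != 3) stop("sigma must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;

  std::vector<double> a(vol.begin(), vol.end()), b(ntot);
  const int dim[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int half = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * half + 1);
    double ksum = 0.0;
    for (int i = -half; i <= half; ++i) {
      ker[i + half] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += ker[i + half];
    }
    for (double& kv : ker) kv /= ksum;

    const int len = dim[axis];
    const R_xlen_t st = stride[axis];
    // iterate over all lines along `axis`
    const int d1 = dim[(axis + 1) % 3], d2 = dim[(axis + 2) % 3];
    const R_xlen_t s1 = stride[(axis + 1) % 3], s2 = stride[(axis + 2) % 3];
    for (int j2 = 0; j2 < d2; ++j2) {
      for (int j1 = 0; j1 < d1; ++j1) {
        const R_xlen_t base = j1 * s1 + j2 * s2;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int t = -half; t <= half; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;            // reflect
            else if (ii >= len) ii = 2 * len - ii - 1;
            acc += ker[t + half] * a[base + (R_xlen_t)ii * st];
          }
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }

  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
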