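#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Volumetric median filter with a cubic (2r+1)^3 window; edge voxels use the
// median of their in-bounds neighbours only (no padding).
// [[Rcpp::export]]
NumericVector cpp_median_filter_3d(NumericVector vol, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  if (radius <= 0) {
    std::copy(vol.begin(), vol.end(), out.begin());
    return out;
  }
  const int w = 2 * radius + 1;
  std::vector<double> buf;
  buf.reserve((size_t)w * w * w);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -radius; dz <= radius; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int dx = -radius; dx <= radius; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              buf.push_back(vol[xx + base]);
            }
          }
        }
        const size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          med = 0.5 * (med + *std::max_element(buf.begin(), buf.begin() + m / 2));
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = med;
      }
    }
  }
  return out;
}

// Separable Gaussian blur, sigma given in voxels per axis; kernel truncated at
// 3 sigma, renormalised at the borders.
static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  std::vector<double> out(v.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int idx3[3] = {x, y, z};
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double s = 0, wsum = 0;
        for (int d = -r; d <= r; ++d) {
          const int p = idx3[axis] + d;
          if (p < 0 || p >= n[axis]) continue;
          const double wk = k[d + r];
          s += wk * v[idx + (R_xlen_t)d * stride[axis]];
          wsum += wk;
        }
        out[idx] = s / wsum;
      }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur_3d(NumericVector vol, IntegerVector dim,
                                   NumericVector sigma_vox) {
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) blur_axis(v, dim[0], dim[1], dim[2], a, sigma_vox[a]);
  return NumericVector(v.begin(), v.end());
}
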