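#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid, by the
// lower-envelope-of-parabolas algorithm applied per axis to squared
// distances (sample coordinate of index i along an axis with spacing w is
// i*w). Returns, for every voxel, the Euclidean distance in physical units
// to the nearest seed (TRUE) voxel centre; seeds carry 0.

static const double DT_INF = 1e30;

static void dt1d(const double *f, double *d, int *v, double *z, int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * w;
    double s;
    for (;;) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_3d(LogicalVector seeds, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = seeds[i] ? 0.0 : DT_INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x axis
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      const R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y axis
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      const R_xlen_t base = xx + (R_xlen_t)nx * ny * (R_xlen_t)zz;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nx * y];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nx * y] = d[y];
    }
  // z axis
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      const R_xlen_t base = xx + (R_xlen_t)nx * yy;
      for (int zc = 0; zc < nz; ++zc) f[zc] = g[base + plane * zc];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2]);
      for (int zc = 0; zc < nz; ++zc) g[base + plane * zc] = d[zc];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
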