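#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Geometry kernels for the capsule tube model: a vessel segment polyline is a
// chain of capsules (cylinders with hemispherical caps), one per edge; the
// network is the union of all capsules.

namespace {

inline double sq(double x) { return x * x; }

// squared distance from point p to segment a-b
inline double pt_seg_d2(const double *p, const double *a, const double *b) {
  const double abx = b[0] - a[0], aby = b[1] - a[1], abz = b[2] - a[2];
  const double apx = p[0] - a[0], apy = p[1] - a[1], apz = p[2] - a[2];
  const double len2 = abx * abx + aby * aby + abz * abz;
  double t = 0.0;
  if (len2 > 0) {
    t = (apx * abx + apy * aby + apz * abz) / len2;
    if (t < 0) t = 0; else if (t > 1) t = 1;
  }
  return sq(p[0] - (a[0] + t * abx)) + sq(p[1] - (a[1] + t * aby)) +
         sq(p[2] - (a[2] + t * abz));
}

} // namespace

// Rasterize capsules onto a voxel grid: voxel (i,j,k), 0-based, has centre
// origin + (i,j,k)*spacing; it is foreground iff its centre lies within
// distance r of some edge. edges: matrix with columns x1,y1,z1,x2,y2,z2,r.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(NumericMatrix edges, IntegerVector dim,
                                     NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);

  for (int e = 0; e < edges.nrow(); ++e) {
    const double a[3] = {edges(e, 0), edges(e, 1), edges(e, 2)};
    const double b[3] = {edges(e, 3), edges(e, 4), edges(e, 5)};
    const double r = edges(e, 6);
    const double r2 = r * r;
    const int x0 = std::max(0, (int)std::ceil((std::min(a[0], b[0]) - r - ox) / sx));
    const int x1 = std::min(nx - 1, (int)std::floor((std::max(a[0], b[0]) + r - ox) / sx));
    const int y0 = std::max(0, (int)std::ceil((std::min(a[1], b[1]) - r - oy) / sy));
    const int y1 = std::min(ny - 1, (int)std::floor((std::max(a[1], b[1]) + r - oy) / sy));
    const int z0 = std::max(0, (int)std::ceil((std::min(a[2], b[2]) - r - oz) / sz));
    const int z1 = std::min(nz - 1, (int)std::floor((std::max(a[2], b[2]) + r - oz) / sz));
    for (int k = z0; k <= z1; ++k)
      for (int j = y0; j <= y1; ++j) {
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = x0; i <= x1; ++i) {
          const R_xlen_t idx = i + base;
          if (out[idx]) continue;
          const double p[3] = {ox + i * sx, oy + j * sy, oz + k * sz};
          if (pt_seg_d2(p, a, b) <= r2) out[idx] = true;
        }
      }
  }
  return out;
}

// Minimum distance from each query point to the union surface: returns
// min over edges of (distance to centerline - r); negative inside a tube.
// Brute force with bounding-box rejection.
// [[Rcpp::export]]
NumericVector cpp_signed_dist_to_tubes(NumericMatrix points, NumericMatrix edges) {
  const int np = points.nrow(), ne = edges.nrow();
  // precompute edge bboxes inflated by r
  std::vector<double> bx0(ne), bx1(ne), by0(ne), by1(ne), bz0(ne), bz1(ne), rr(ne);
  for (int e = 0; e < ne; ++e) {
    const double r = edges(e, 6);
    rr[e] = r;
    bx0[e] = std::min(edges(e, 0), edges(e, 3)) - r;
    bx1[e] = std::max(edges(e, 0), edges(e, 3)) + r;
    by0[e] = std::min(edges(e, 1), edges(e, 4)) - r;
    by1[e] = std::max(edges(e, 1), edges(e, 4)) + r;
    bz0[e] = std::min(edges(e, 2), edges(e, 5)) - r;
    bz1[e] = std::max(edges(e, 2), edges(e, 5)) + r;
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double pt[3] = {points(p, 0), points(p, 1), points(p, 2)};
    double best = R_PosInf;
    for (int e = 0; e < ne; ++e) {
      // skip edges whose inflated bbox is farther than the current best
      const double mx = std::max(std::max(bx0[e] - pt[0], pt[0] - bx1[e]), 0.0);
      const double my = std::max(std::max(by0[e] - pt[1], pt[1] - by1[e]), 0.0);
      const double mz = std::max(std::max(bz0[e] - pt[2], pt[2] - bz1[e]), 0.0);
      if (std::sqrt(mx * mx + my * my + mz * mz) >= best) continue;
      const double a[3] = {edges(e, 0), edges(e, 1), edges(e, 2)};
      const double b[3] = {edges(e, 3), edges(e, 4), edges(e, 5)};
      const double d = std::sqrt(pt_seg_d2(pt, a, b)) - rr[e];
      if (d < best) best = d;
    }
    out[p] = best;
  }
  return out;
}
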