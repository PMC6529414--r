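#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a tube around a polyline. A voxel is marked iff its center lies
// within diameter/2 (inclusive) of the polyline (point-to-segment distance,
// hemispherical caps included). Tubes thinner than the smallest voxel pitch
// additionally mark the chain of voxels nearest to the polyline so a track
// is never lost to undersampling. Coordinates are physical (µm), axis order
// (z, y, x); the center of voxel (i, j, k) (1-based) is ((i-0.5)*w0, ...).
static void rasterize_tube_worker(std::vector<char>& mask,
                                  const IntegerVector& dim,
                                  const NumericVector& spacing,
                                  const NumericMatrix& pts, double diameter) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  double w0 = spacing[0], w1 = spacing[1], w2 = spacing[2];
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;
  double r = diameter / 2.0;
  double r2 = r * r;
  int K = pts.nrow();

  int nseg = std::max(K - 1, 1);
  for (int seg = 0; seg < nseg; ++seg) {
    double A[3], B[3];
    for (int d = 0; d < 3; ++d) {
      A[d] = pts(seg, d);
      B[d] = pts(std::min(seg + 1, K - 1), d);
    }
    double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double len2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];

    // voxel-index bounding box of segment +/- r (half-pitch slack)
    double w[3] = {w0, w1, w2};
    int n[3] = {n0, n1, n2};
    int lo[3], hi[3];
    bool empty = false;
    for (int d = 0; d < 3; ++d) {
      double cmin = std::min(A[d], B[d]) - r;
      double cmax = std::max(A[d], B[d]) + r;
      lo[d] = std::max(0, (int)std::floor(cmin / w[d] - 0.5));
      hi[d] = std::min(n[d] - 1, (int)std::ceil(cmax / w[d] + 0.5));
      if (lo[d] > hi[d]) empty = true;
    }
    if (!empty) {
      for (int c = lo[2]; c <= hi[2]; ++c)
        for (int b = lo[1]; b <= hi[1]; ++b)
          for (int a = lo[0]; a <= hi[0]; ++a) {
            double p[3] = {(a + 0.5) * w0, (b + 0.5) * w1, (c + 0.5) * w2};
            double ap[3] = {p[0] - A[0], p[1] - A[1], p[2] - A[2]};
            double t = 0.0;
            if (len2 > 0.0) {
              t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / len2;
              t = std::max(0.0, std::min(1.0, t));
            }
            double d2 = 0.0;
            for (int d = 0; d < 3; ++d) {
              double q = ap[d] - t * ab[d];
              d2 += q * q;
            }
            if (d2 <= r2)
              mask[a + (R_xlen_t)b * s1 + (R_xlen_t)c * s2] = 1;
          }
    }
  }

  // minimum one-voxel-wide track for sub-pitch diameters
  double wmin = std::min(w0, std::min(w1, w2));
  if (diameter < wmin) {
    double step = wmin / 4.0;
    for (int seg = 0; seg < nseg; ++seg) {
      double A[3], B[3];
      for (int d = 0; d < 3; ++d) {
        A[d] = pts(seg, d);
        B[d] = pts(std::min(seg + 1, K - 1), d);
      }
      double len = std::sqrt((B[0] - A[0]) * (B[0] - A[0]) +
                             (B[1] - A[1]) * (B[1] - A[1]) +
                             (B[2] - A[2]) * (B[2] - A[2]));
      int ns = std::max(1, (int)std::ceil(len / step));
      for (int s = 0; s <= ns; ++s) {
        double t = (double)s / ns;
        double p0 = A[0] + t * (B[0] - A[0]);
        double p1 = A[1] + t * (B[1] - A[1]);
        double p2 = A[2] + t * (B[2] - A[2]);
        int a = (int)std::lround(p0 / w0 - 0.5);
        int b = (int)std::lround(p1 / w1 - 0.5);
        int c = (int)std::lround(p2 / w2 - 0.5);
        if (a < 0 || a >= n0 || b < 0 || b >= n1 || c < 0 || c >= n2)
          continue;
        mask[a + (R_xlen_t)b * s1 + (R_xlen_t)c * s2] = 1;
      }
    }
  }
}

// [[Rcpp::export]]
LogicalVector cpp_rasterize_tube(IntegerVector dim, NumericVector spacing,
                                 NumericMatrix pts, double diameter) {
  R_xlen_t N = (R_xlen_t)dim[0] * dim[1] * dim[2];
  std::vector<char> m((size_t)N, 0);
  rasterize_tube_worker(m, dim, spacing, pts, diameter);
  LogicalVector mask(N);
  for (R_xlen_t i = 0; i < N; ++i) mask[i] = m[i] != 0;
  return mask;
}

// Same rasterization, returning the 1-based linear indices of marked voxels
// (cheap to paint into an existing label array).
// [[Rcpp::export]]
IntegerVector cpp_tube_indices(IntegerVector dim, NumericVector spacing,
                               NumericMatrix pts, double diameter) {
  R_xlen_t N = (R_xlen_t)dim[0] * dim[1] * dim[2];
  std::vector<char> m((size_t)N, 0);
  rasterize_tube_worker(m, dim, spacing, pts, diameter);
  std::vector<int> idx;
  for (R_xlen_t i = 0; i < N; ++i)
    if (m[i]) idx.push_back((int)(i + 1));
  return IntegerVector(idx.begin(), idx.end());
}
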