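#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared distances are propagated axis by axis (Felzenszwalb & Huttenlocher
// lower-envelope transform), each pass weighted by that axis' physical voxel
// pitch, so anisotropic spacings are exact. A very large finite sentinel is
// used instead of Inf so parabola intersections stay well-defined.
static const double BIG = 1e300;

// 1D squared-distance transform along a line of n samples with pitch w.
// f holds squared distances on input; d receives the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  // Boundary sentinels use DBL_MAX so that intersections on the BIG scale
  // (at most ~1e300 / (2 w)) can never pop the leftmost parabola.
  const double ZMAX = std::numeric_limits<double>::max();
  int k = 0;
  v[0] = 0;
  z[0] = -ZMAX;
  z[1] = ZMAX;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZMAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = (q - v[k]) * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Full 3D squared EDT on a buffer laid out with dims (n0, n1, n2) where the
// first index is fastest (R array order).  Values must be 0 on the zero set
// and BIG elsewhere on entry.
static void edt3d(std::vector<double>& D, int n0, int n1, int n2,
                  double w0, double w1, double w2) {
  int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t s0 = 1, s1 = (R_xlen_t)n0, s2 = (R_xlen_t)n0 * n1;

  // axis 0
  for (int c = 0; c < n2; ++c)
    for (int b = 0; b < n1; ++b) {
      R_xlen_t base = b * s1 + c * s2;
      for (int a = 0; a < n0; ++a) f[a] = D[base + a * s0];
      dt1d(f, d, v, z, n0, w0);
      for (int a = 0; a < n0; ++a) D[base + a * s0] = d[a];
    }
  // axis 1
  for (int c = 0; c < n2; ++c)
    for (int a = 0; a < n0; ++a) {
      R_xlen_t base = a * s0 + c * s2;
      for (int b = 0; b < n1; ++b) f[b] = D[base + b * s1];
      dt1d(f, d, v, z, n1, w1);
      for (int b = 0; b < n1; ++b) D[base + b * s1] = d[b];
    }
  // axis 2
  for (int b = 0; b < n1; ++b)
    for (int a = 0; a < n0; ++a) {
      R_xlen_t base = a * s0 + b * s1;
      for (int c = 0; c < n2; ++c) f[c] = D[base + c * s2];
      dt1d(f, d, v, z, n2, w2);
      for (int c = 0; c < n2; ++c) D[base + c * s2] = d[c];
    }
}

// Shared worker: squared EDT to the zero set, optionally treating everything
// outside the volume as part of the zero set (one padding layer).
std::vector<double> edt_sq_worker(const int* zero, int n0, int n1, int n2,
                                  double w0, double w1, double w2, bool pad) {
  if (pad) {
    int p0 = n0 + 2, p1 = n1 + 2, p2 = n2 + 2;
    std::vector<double> D((size_t)p0 * p1 * p2, 0.0);
    for (int c = 0; c < n2; ++c)
      for (int b = 0; b < n1; ++b)
        for (int a = 0; a < n0; ++a) {
          R_xlen_t src = a + (R_xlen_t)n0 * b + (R_xlen_t)n0 * n1 * c;
          R_xlen_t dst = (a + 1) + (R_xlen_t)p0 * (b + 1) +
                         (R_xlen_t)p0 * p1 * (c + 1);
          D[dst] = zero[src] ? 0.0 : BIG;
        }
    edt3d(D, p0, p1, p2, w0, w1, w2);
    std::vector<double> out((size_t)n0 * n1 * n2);
    for (int c = 0; c < n2; ++c)
      for (int b = 0; b < n1; ++b)
        for (int a = 0; a < n0; ++a) {
          R_xlen_t src = (a + 1) + (R_xlen_t)p0 * (b + 1) +
                         (R_xlen_t)p0 * p1 * (c + 1);
          R_xlen_t dst = a + (R_xlen_t)n0 * b + (R_xlen_t)n0 * n1 * c;
          out[dst] = D[src];
        }
    return out;
  }
  std::vector<double> D((size_t)n0 * n1 * n2);
  for (R_xlen_t i = 0; i < (R_xlen_t)n0 * n1 * n2; ++i)
    D[i] = zero[i] ? 0.0 : BIG;
  edt3d(D, n0, n1, n2, w0, w1, w2);
  return D;
}

//' @useDynLib tomomorph, .registration = TRUE
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector zero_set, IntegerVector dim,
                         NumericVector spacing, bool pad) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  std::vector<double> D = edt_sq_worker(LOGICAL(zero_set), n0, n1, n2,
                                        spacing[0], spacing[1], spacing[2],
                                        pad);
  NumericVector out((R_xlen_t)n0 * n1 * n2);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = (D[i] >= BIG) ? R_PosInf : D[i];
  return out;
}
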