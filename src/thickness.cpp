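#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

std::vector<double> edt_sq_worker(const int* zero, int n0, int n1, int n2,
                                  double w0, double w1, double w2, bool pad);

// Local thickness by maximal inscribed spheres (Hildebrand-Ruegsegger):
// thickness(p) = 2 * max{ EDT(x) : x foreground, ||p - x|| < EDT(x) }.
// Distances are voxel-center to voxel-center; everything outside the volume
// counts as background (padding convention); sphere containment uses the
// open ball (strict <).
//
// The implementation paints each candidate sphere, skipping voxels whose
// sphere is provably contained in a 26-neighbour's sphere (containment
// ||x-y|| + r_x <= r_y, checked with a conservative epsilon so that only
// certainly-redundant spheres are dropped); the result is exactly the
// definition above.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  double w0 = spacing[0], w1 = spacing[1], w2 = spacing[2];
  R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  const int* m = LOGICAL(mask);

  // squared EDT to background (zero set = !mask), padded
  std::vector<int> zero(N);
  for (R_xlen_t i = 0; i < N; ++i) zero[i] = m[i] ? 0 : 1;
  std::vector<double> r2 = edt_sq_worker(zero.data(), n0, n1, n2,
                                         w0, w1, w2, true);

  NumericVector out(N);
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;

  // 26-neighbour offsets and physical lengths, for the redundancy prune
  int noff[26][3];
  double nd[26];
  int nn = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (da == 0 && db == 0 && dc == 0) continue;
        noff[nn][0] = da; noff[nn][1] = db; noff[nn][2] = dc;
        nd[nn] = std::sqrt(da * w0 * da * w0 + db * w1 * db * w1 +
                           dc * w2 * dc * w2);
        ++nn;
      }

  for (int c = 0; c < n2; ++c)
    for (int b = 0; b < n1; ++b)
      for (int a = 0; a < n0; ++a) {
        R_xlen_t i = a + b * s1 + c * s2;
        if (!m[i]) continue;
        double rr2 = r2[i];
        double r = std::sqrt(rr2);

        bool redundant = false;
        for (int k = 0; k < nn; ++k) {
          int aa = a + noff[k][0], bb = b + noff[k][1], cc = c + noff[k][2];
          if (aa < 0 || aa >= n0 || bb < 0 || bb >= n1 || cc < 0 || cc >= n2)
            continue;
          R_xlen_t j = aa + bb * s1 + cc * s2;
          if (!m[j]) continue;
          double ry = std::sqrt(r2[j]);
          if (ry >= r + nd[k] + 1e-12) { redundant = true; break; }
        }
        if (redundant) continue;

        int a0 = (int)std::ceil(r / w0) + 1, a1 = (int)std::ceil(r / w1) + 1,
            a2 = (int)std::ceil(r / w2) + 1;
        double diam = 2.0 * r;
        for (int dc = -a2; dc <= a2; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= n2) continue;
          double d2c = dc * w2 * dc * w2;
          if (d2c >= rr2) continue;
          for (int db = -a1; db <= a1; ++db) {
            int bb = b + db;
            if (bb < 0 || bb >= n1) continue;
            double d2b = d2c + db * w1 * db * w1;
            if (d2b >= rr2) continue;
            for (int da = -a0; da <= a0; ++da) {
              int aa = a + da;
              if (aa < 0 || aa >= n0) continue;
              double d2 = d2b + da * w0 * da * w0;
              if (d2 < rr2) {
                R_xlen_t j = aa + bb * s1 + cc * s2;
                if (out[j] < diam) out[j] = diam;
              }
            }
          }
        }
      }
  return out;
}

// Literal evaluation of the same definition, kept algorithmically
// independent: the EDT is an exhaustive nearest-background search over the
// padded volume and every foreground sphere is painted over the whole
// volume. Intended for small volumes (reference/oracle use).
// [[Rcpp::export]]
NumericVector cpp_local_thickness_bruteforce(LogicalVector mask,
                                             IntegerVector dim,
                                             NumericVector spacing) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  double w0 = spacing[0], w1 = spacing[1], w2 = spacing[2];
  R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  const int* m = LOGICAL(mask);
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;
  NumericVector out(N);

  for (int c = 0; c < n2; ++c)
    for (int b = 0; b < n1; ++b)
      for (int a = 0; a < n0; ++a) {
        R_xlen_t i = a + b * s1 + c * s2;
        if (!m[i]) continue;

        // exhaustive nearest-background (including the padding layer)
        double r2 = R_PosInf;
        for (int cc = -1; cc <= n2; ++cc)
          for (int bb = -1; bb <= n1; ++bb)
            for (int aa = -1; aa <= n0; ++aa) {
              bool inside = aa >= 0 && aa < n0 && bb >= 0 && bb < n1 &&
                            cc >= 0 && cc < n2;
              if (inside && m[aa + bb * s1 + cc * s2]) continue;
              double d2 = (aa - a) * w0 * (aa - a) * w0;
              d2 += (bb - b) * w1 * (bb - b) * w1;
              d2 += (cc - c) * w2 * (cc - c) * w2;
              if (d2 < r2) r2 = d2;
            }

        // paint the open ball at 2*EDT
        double diam = 2.0 * std::sqrt(r2);
        for (int cc = 0; cc < n2; ++cc)
          for (int bb = 0; bb < n1; ++bb)
            for (int aa = 0; aa < n0; ++aa) {
              double d2 = (aa - a) * w0 * (aa - a) * w0;
              d2 += (bb - b) * w1 * (bb - b) * w1;
              d2 += (cc - c) * w2 * (cc - c) * w2;
              if (d2 < r2) {
                R_xlen_t j = aa + bb * s1 + cc * s2;
                if (out[j] < diam) out[j] = diam;
              }
            }
      }
  return out;
}
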