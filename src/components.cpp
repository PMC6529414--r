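#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling by flood fill. Connectivity 6 (faces),
// 18 (faces+edges) or 26 (all neighbours). Labels are 1..k in scan order of
// the first voxel of each component; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  R_xlen_t N = (R_xlen_t)n0 * n1 * n2;
  const int* m = LOGICAL(mask);
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;

  int off[26][3];
  int nn = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (da == 0 && db == 0 && dc == 0) continue;
        int ord = std::abs(da) + std::abs(db) + std::abs(dc);
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        off[nn][0] = da; off[nn][1] = db; off[nn][2] = dc;
        ++nn;
      }

  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!m[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int a = (int)(cur % n0);
      int b = (int)((cur / n0) % n1);
      int c = (int)(cur / s2);
      for (int k = 0; k < nn; ++k) {
        int aa = a + off[k][0], bb = b + off[k][1], cc = c + off[k][2];
        if (aa < 0 || aa >= n0 || bb < 0 || bb >= n1 || cc < 0 || cc >= n2)
          continue;
        R_xlen_t j = aa + bb * s1 + cc * s2;
        if (m[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}
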