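#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Iterative (explicit-stack) flood fill labeling of a binary mask.
// Seeds are taken in column-major scan order, so labeling is deterministic.
// An explicit stack is a contract here: recursion would overflow on large
// contiguous fragments (a whole intact nerve swirl is one component).
// [[Rcpp::export]]
IntegerMatrix cm_flood_fill(const LogicalMatrix& mask, const int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity;
  std::vector<int> stack;
  int next_label = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next_label;
      labels(r, c) = next_label;
      stack.push_back(c * nr + r);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && labels(r2, c2) == 0) {
            labels(r2, c2) = next_label;
            stack.push_back(c2 * nr + r2);
          }
        }
      }
    }
  }
  return labels;
}
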