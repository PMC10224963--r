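#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask under 4- or 8-connectivity.
// Returns an integer matrix of labels (0 = background, components 1..n).
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int k = 0; k < nd; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}
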