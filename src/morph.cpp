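// 4-connected component labelling for binary masks (skull stripping).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          const int qi = pi + di[d], qj = pj + dj[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
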