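#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// 3-D connected-component labelling by iterative flood fill.
// connectivity: 6 (face) or 26 (face + edge + corner). NA treated as false.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || labels[i]) continue;
    ++cur;
    labels[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % d1);
      int y = (int)((v / d1) % d2);
      int z = (int)(v / ((R_xlen_t)d1 * d2));
      for (const auto &o : offs) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3) continue;
        R_xlen_t w = nx + (R_xlen_t)d1 * (ny + (R_xlen_t)d2 * nz);
        if (mask[w] == TRUE && !labels[w]) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
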