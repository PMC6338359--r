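#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a binary 3D array (BFS flood fill).
// Returns an integer array of the same shape: 0 for background, 1..n for
// component labels in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector data, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  int next_label = 0;
  std::vector<R_xlen_t> queue;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!data[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t idx = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (data[idx] && labels[idx] == 0) {
              labels[idx] = next_label;
              queue.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
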