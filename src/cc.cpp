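#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected components of a boolean mask; connectivity 6 or 26.
// Works for 2D inputs by passing nz = 1 (26 then degenerates to 8, 6 to 4).
// Returns integer labels, 0 = background, components numbered from 1 in
// scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cc3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dy, dx, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        dy.push_back(a); dx.push_back(b); dz.push_back(c);
      }
  int nd = (int)dy.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur % ((R_xlen_t)ny * nx));
      int j = rem / ny, i = rem % ny;
      for (int d = 0; d < nd; ++d) {
        int ii = i + dy[d], jj = j + dx[d], kk = k + dz[d];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)ny * (jj + (R_xlen_t)nx * kk);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
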