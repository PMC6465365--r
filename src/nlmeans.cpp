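#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Baseline non-local patch-averaging denoiser. Each voxel is replaced by a
// weighted average of the centres of nearby patches, weighted by patch
// similarity: w = exp(-max(0, d2 - 2*sigma^2) / h^2), with d2 the mean squared
// difference between the two patches. Search/patch radii are per-axis so the
// z direction (coarser sections) can use a smaller reach.
// [[Rcpp::export]]
NumericVector nlmeans_cpp(NumericVector z, IntegerVector dims,
                          IntegerVector search_r, IntegerVector patch_r,
                          double h, double sigma) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int sry = search_r[0], srx = search_r[1], srz = search_r[2];
  int pry = patch_r[0], prx = patch_r[1], prz = patch_r[2];
  double h2 = h * h;
  double s2 = 2.0 * sigma * sigma;
  NumericVector out(z.size());

  auto at = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)ny * (j + (R_xlen_t)nx * k);
  };
  double npatch = (2 * pry + 1) * (2 * prx + 1) * (2 * prz + 1);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        double wsum = 0, vsum = 0;
        for (int ck = std::max(0, k - srz); ck <= std::min(nz - 1, k + srz); ++ck)
          for (int cj = std::max(0, j - srx); cj <= std::min(nx - 1, j + srx); ++cj)
            for (int ci = std::max(0, i - sry); ci <= std::min(ny - 1, i + sry); ++ci) {
              double d2 = 0;
              for (int pk = -prz; pk <= prz; ++pk)
                for (int pj = -prx; pj <= prx; ++pj)
                  for (int pi = -pry; pi <= pry; ++pi) {
                    int a1 = std::min(ny - 1, std::max(0, i + pi));
                    int b1 = std::min(nx - 1, std::max(0, j + pj));
                    int c1 = std::min(nz - 1, std::max(0, k + pk));
                    int a2 = std::min(ny - 1, std::max(0, ci + pi));
                    int b2 = std::min(nx - 1, std::max(0, cj + pj));
                    int c2 = std::min(nz - 1, std::max(0, ck + pk));
                    double df = z[at(a1, b1, c1)] - z[at(a2, b2, c2)];
                    d2 += df * df;
                  }
              d2 /= npatch;
              double w = std::exp(-std::max(0.0, d2 - s2) / h2);
              wsum += w;
              vsum += w * z[at(ci, cj, ck)];
            }
        out[at(i, j, k)] = vsum / wsum;
      }
  out.attr("dim") = dims;
  return out;
}
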