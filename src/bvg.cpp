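#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bounded volume growing from one seed.
//
// Iterative batch growth: at iteration k the candidate set N(S_k) holds every
// unclaimed, non-forbidden voxel adjacent (6 or 26 neighbourhood) to the
// current region S_k. All candidates whose intensity differs from the running
// region mean by at most delta_T are appended in one batch; the mean is then
// recomputed. Growth stops when no candidate qualifies. If the region reaches
// the volume cap theta it is discarded (empty result, attribute
// discarded = TRUE), freeing its voxels.
//
// Candidates rejected at one iteration stay candidates: the mean moves, so
// they may qualify later.
//
// z: intensities; forbidden: edge/previously-claimed voxels; seed 0-based.
// Returns 0-based voxel indices of the region in acceptance order.
// [[Rcpp::export]]
IntegerVector bvg_grow_cpp(NumericVector z, IntegerVector dims, int seed,
                           LogicalVector forbidden, double delta_T,
                           double theta, int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (n > INT_MAX) stop("volume too large for BVG index type");
  if (seed < 0 || seed >= n) stop("seed index out of range");
  if (forbidden[seed]) stop("seed lies in the forbidden set");

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

  // state: 0 unknown, 1 in region, 2 candidate, 3 forbidden
  std::vector<unsigned char> state(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) if (forbidden[i]) state[i] = 3;

  std::vector<int> region;
  std::vector<int> cand;
  double sum = z[seed];
  state[seed] = 1;
  region.push_back(seed);
  bool discarded = false;

  auto push_neighbours = [&](int idx) {
    int k = idx / (ny * nx), rem = idx % (ny * nx);
    int j = rem / ny, i = rem % ny;
    for (int d = 0; d < nd; ++d) {
      int ii = i + dy[d], jj = j + dx[d], kk = k + dz[d];
      if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
        continue;
      int q = ii + ny * (jj + nx * kk);
      if (state[q] == 0) { state[q] = 2; cand.push_back(q); }
    }
  };
  push_neighbours(seed);

  std::vector<int> accepted;
  while (true) {
    double mean = sum / region.size();
    accepted.clear();
    size_t keep = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int q = cand[c];
      if (std::fabs(z[q] - mean) <= delta_T) accepted.push_back(q);
      else cand[keep++] = q; // stays a candidate for later iterations
    }
    cand.resize(keep);
    if (accepted.empty()) break;
    for (size_t a = 0; a < accepted.size(); ++a) {
      int q = accepted[a];
      state[q] = 1;
      region.push_back(q);
      sum += z[q];
    }
    if (R_FINITE(theta) && (double)region.size() >= theta) {
      discarded = true;
      break;
    }
    for (size_t a = 0; a < accepted.size(); ++a) push_neighbours(accepted[a]);
  }

  // discarded regions are returned too (with the flag set) so the caller can
  // both free the voxels and remember where growth failed
  IntegerVector out(region.begin(), region.end());
  out.attr("discarded") = discarded;
  return out;
}
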