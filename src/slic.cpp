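#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// SLIC supervoxels on a 3D volume with anisotropic voxels.
//
// Distance measure D = d_int + (c / rho) * d_sp, with d_int the absolute
// intensity difference on a 0-255 scale (inputs are in [0,1]) and d_sp the
// Euclidean distance between voxel and cluster centre in scaled index
// coordinates (index * weight per axis, weights wy, wx, wz). Cluster centres
// start on a regular grid of physical step rho (in scaled units) and are
// iterated localized-k-means style with a search window of 2*rho per axis.
//
// Returns integer labels 1..Q covering every voxel (connectivity enforced:
// each final supervoxel is 6-connected; stray fragments are merged into an
// adjacent supervoxel).
// [[Rcpp::export]]
IntegerVector slic_cpp(NumericVector z, IntegerVector dims,
                       double compactness, double rho, NumericVector weights,
                       int max_iter, double tol) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  double wy = weights[0], wx = weights[1], wz = weights[2];

  // grid step per axis in index units
  int sy = std::max(1, (int)std::lround(rho / wy));
  int sx = std::max(1, (int)std::lround(rho / wx));
  int sz = std::max(1, (int)std::lround(rho / wz));

  std::vector<double> cy, cx, cz, cint;
  for (int k = sz / 2; k < nz; k += sz)
    for (int j = sx / 2; j < nx; j += sx)
      for (int i = sy / 2; i < ny; i += sy) {
        cy.push_back(i); cx.push_back(j); cz.push_back(k);
        cint.push_back(z[i + (R_xlen_t)ny * (j + (R_xlen_t)nx * k)]);
      }
  int Q = (int)cy.size();
  if (Q == 0) stop("grid step larger than volume");

  std::vector<int> lab(n, -1);
  std::vector<double> best(n);
  const double INF = std::numeric_limits<double>::infinity();
  double spw = compactness / rho;

  int ry = std::max(1, (int)std::ceil(2.0 * rho / wy));
  int rx = std::max(1, (int)std::ceil(2.0 * rho / wx));
  int rz = std::max(1, (int)std::ceil(2.0 * rho / wz));

  for (int it = 0; it < max_iter; ++it) {
    std::fill(best.begin(), best.end(), INF);
    for (int q = 0; q < Q; ++q) {
      int i0 = std::max(0, (int)std::floor(cy[q] - ry));
      int i1 = std::min(ny - 1, (int)std::ceil(cy[q] + ry));
      int j0 = std::max(0, (int)std::floor(cx[q] - rx));
      int j1 = std::min(nx - 1, (int)std::ceil(cx[q] + rx));
      int k0 = std::max(0, (int)std::floor(cz[q] - rz));
      int k1 = std::min(nz - 1, (int)std::ceil(cz[q] + rz));
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j) {
          R_xlen_t base = (R_xlen_t)ny * (j + (R_xlen_t)nx * k);
          double ddx = (j - cx[q]) * wx, ddz = (k - cz[q]) * wz;
          double dxz2 = ddx * ddx + ddz * ddz;
          for (int i = i0; i <= i1; ++i) {
            R_xlen_t p = base + i;
            double ddy = (i - cy[q]) * wy;
            double dsp = std::sqrt(dxz2 + ddy * ddy);
            double dint = 255.0 * std::fabs(z[p] - cint[q]);
            double D = dint + spw * dsp;
            if (D < best[p]) { best[p] = D; lab[p] = q; }
          }
        }
    }
    // update centres
    std::vector<double> sy_(Q, 0), sx_(Q, 0), sz_(Q, 0), si_(Q, 0);
    std::vector<double> cnt(Q, 0);
    for (R_xlen_t p = 0; p < n; ++p) {
      int q = lab[p];
      if (q < 0) continue;
      int k = (int)(p / ((R_xlen_t)ny * nx));
      int rem = (int)(p % ((R_xlen_t)ny * nx));
      int j = rem / ny, i = rem % ny;
      sy_[q] += i; sx_[q] += j; sz_[q] += k; si_[q] += z[p]; cnt[q] += 1;
    }
    double shift = 0;
    for (int q = 0; q < Q; ++q) {
      if (cnt[q] == 0) continue;
      double niy = sy_[q] / cnt[q], nix = sx_[q] / cnt[q], niz = sz_[q] / cnt[q];
      double dy = (niy - cy[q]) * wy, dx = (nix - cx[q]) * wx,
             dz = (niz - cz[q]) * wz;
      shift = std::max(shift, std::sqrt(dy * dy + dx * dx + dz * dz));
      cy[q] = niy; cx[q] = nix; cz[q] = niz; cint[q] = si_[q] / cnt[q];
    }
    if (shift < tol) break;
  }

  // any voxel never inside a search window: nearest centre by scaled distance
  for (R_xlen_t p = 0; p < n; ++p) {
    if (lab[p] >= 0) continue;
    int k = (int)(p / ((R_xlen_t)ny * nx));
    int rem = (int)(p % ((R_xlen_t)ny * nx));
    int j = rem / ny, i = rem % ny;
    double bd = INF; int bq = 0;
    for (int q = 0; q < Q; ++q) {
      double dy = (i - cy[q]) * wy, dx = (j - cx[q]) * wx, dz = (k - cz[q]) * wz;
      double d = dy * dy + dx * dx + dz * dz;
      if (d < bd) { bd = d; bq = q; }
    }
    lab[p] = bq;
  }

  // connectivity enforcement: per label keep the largest 6-connected
  // component, merge fragments into an adjacent different label
  std::vector<int> comp(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  std::vector<R_xlen_t> compSize(1, 0);
  std::vector<int> compLab(1, -1);
  std::vector<R_xlen_t> compSeed(1, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++ncomp;
    compSize.push_back(0); compLab.push_back(lab[s]); compSeed.push_back(s);
    comp[s] = ncomp;
    stack.clear(); stack.push_back(s);
    R_xlen_t sz_c = 0;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++sz_c;
      int k = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur % ((R_xlen_t)ny * nx));
      int j = rem / ny, i = rem % ny;
      const int DY[6] = {1, -1, 0, 0, 0, 0}, DX[6] = {0, 0, 1, -1, 0, 0},
                DZ[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + DY[d], jj = j + DX[d], kk = k + DZ[d];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)ny * (jj + (R_xlen_t)nx * kk);
        if (comp[q] == 0 && lab[q] == lab[cur]) {
          comp[q] = ncomp;
          stack.push_back(q);
        }
      }
    }
    compSize[ncomp] = sz_c;
  }
  // largest component per label keeps it
  std::vector<R_xlen_t> largest(Q, 0);
  std::vector<int> keeper(Q, -1);
  for (int c = 1; c <= ncomp; ++c) {
    int L = compLab[c];
    if (compSize[c] > largest[L]) { largest[L] = compSize[c]; keeper[L] = c; }
  }
  // orphan components: relabel to an adjacent kept label (repeat until stable)
  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t p = 0; p < n; ++p) {
      int c = comp[p];
      if (keeper[lab[p]] == c) continue;
      int k = (int)(p / ((R_xlen_t)ny * nx));
      int rem = (int)(p % ((R_xlen_t)ny * nx));
      int j = rem / ny, i = rem % ny;
      const int DY[6] = {1, -1, 0, 0, 0, 0}, DX[6] = {0, 0, 1, -1, 0, 0},
                DZ[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + DY[d], jj = j + DX[d], kk = k + DZ[d];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)ny * (jj + (R_xlen_t)nx * kk);
        if (keeper[lab[q]] == comp[q]) {
          lab[p] = lab[q];
          comp[p] = comp[q];
          changed = true;
          break;
        }
      }
    }
  }

  // compact label ids to 1..Q'
  std::vector<int> remap(Q, 0);
  int nextId = 0;
  IntegerVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    int L = lab[p];
    if (remap[L] == 0) remap[L] = ++nextId;
    out[p] = remap[L];
  }
  out.attr("dim") = dims;
  out.attr("Q") = nextId;
  return out;
}
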