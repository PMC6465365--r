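#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
// f: input squared distances at grid positions 0..n-1, spacing w (physical
// units per step). Overwrites d with the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zi(n + 1);
  double w2 = w * w;
  int k = -1; // envelope holds finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w * (q - v[k]));
      if (s <= zi[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zi[k] = (k == 0) ? -INF : s;
    zi[k + 1] = INF;
  }
  if (k < 0) { // no finite input
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zi[j + 1] < w * q) ++j;
    double diff = w * (q - v[j]);
    d[q] = diff * diff + f[v[j]];
  }
}

// Anisotropic Euclidean distance transform: distance (in physical units)
// from every voxel to the nearest TRUE voxel of `mask`. dims = (ny, nx, nz),
// spacing = (hy, hx, hz).
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double hy = spacing[0], hx = spacing[1], hz = spacing[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> buf, out;
  // pass along y (fastest-varying)
  buf.resize(ny); out.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j) {
      R_xlen_t base = (R_xlen_t)ny * (j + (R_xlen_t)nx * k);
      bool any = false;
      for (int i = 0; i < ny; ++i) { buf[i] = g[base + i]; if (buf[i] < INF) any = true; }
      if (!any) continue;
      dt1d(buf, out, ny, hy);
      for (int i = 0; i < ny; ++i) g[base + i] = out[i];
    }
  // pass along x
  buf.resize(nx); out.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = i + (R_xlen_t)ny * nx * k;
      bool any = false;
      for (int j = 0; j < nx; ++j) { buf[j] = g[base + (R_xlen_t)ny * j]; if (buf[j] < INF) any = true; }
      if (!any) continue;
      dt1d(buf, out, nx, hx);
      for (int j = 0; j < nx; ++j) g[base + (R_xlen_t)ny * j] = out[j];
    }
  // pass along z
  buf.resize(nz); out.resize(nz);
  R_xlen_t slice = (R_xlen_t)ny * nx;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = i + (R_xlen_t)ny * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) { buf[k] = g[base + slice * k]; if (buf[k] < INF) any = true; }
      if (!any) continue;
      dt1d(buf, out, nz, hz);
      for (int k = 0; k < nz; ++k) g[base + slice * k] = out[k];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  res.attr("dim") = dims;
  return res;
}
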