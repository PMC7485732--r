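#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance transform.
// f holds squared distances sampled along one scan line; d receives the
// lower envelope of the parabolas rooted at the finite samples. Samples at
// +Inf (no feature reachable yet) contribute no parabola.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] == INF) ? NA_REAL : std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
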