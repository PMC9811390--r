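#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-D squared distance transform (lower envelope of parabolas), sample
// spacing w = sqrt(w2). f holds squared distances from previous passes.
static void dt1d(const double *f, double *d, int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; q++) {
    int p = v[k];
    double s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
               (2.0 * w2 * (q - p));
    while (s <= z[k]) {
      k--;
      p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

// Exact anisotropic Euclidean distance (mm) to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e30;
  NumericVector D(nvox);
  for (R_xlen_t i = 0; i < nvox; i++) D[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = D[base + i];
      dt1d(f.data(), d.data(), nx, w2);
      for (int i = 0; i < nx; i++) D[base + i] = d[i];
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = D[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, w2);
      for (int j = 0; j < ny; j++) D[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = D[base + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, w2);
      for (int k = 0; k < nz; k++) D[base + (R_xlen_t)k * nx * ny] = d[k];
    }

  for (R_xlen_t i = 0; i < nvox; i++)
    D[i] = (D[i] >= 1e29) ? R_PosInf : std::sqrt(D[i]);
  return D;
}
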