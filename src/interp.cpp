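#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear sample at voxel coordinates (x,y,z), 0-based.
// pad = 0: zero outside; pad = 1: clamp to edge.
static double tri_sample(const double *v, int nx, int ny, int nz,
                         double x, double y, double z, int pad) {
  if (pad == 0) {
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return 0.0;
  }
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) { x0 = 0; fx = 0; }
  if (ny == 1) { y0 = 0; fy = 0; }
  if (nz == 1) { z0 = 0; fz = 0; }
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double *b = v + (R_xlen_t)z0 * sxy + (R_xlen_t)y0 * nx + x0;
  int dx = (nx > 1), dy = (ny > 1) ? nx : 0;
  R_xlen_t dz = (nz > 1) ? sxy : 0;
  double c00 = b[0] * (1 - fx) + b[dx] * fx;
  double c10 = b[dy] * (1 - fx) + b[dy + dx] * fx;
  double c01 = b[dz] * (1 - fx) + b[dz + dx] * fx;
  double c11 = b[dz + dy] * (1 - fx) + b[dz + dy + dx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Trilinear value + gradient (w.r.t. voxel coordinates).
static double tri_sample_grad(const double *v, int nx, int ny, int nz,
                              double x, double y, double z, double g[3]) {
  g[0] = g[1] = g[2] = 0.0;
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return 0.0;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double *b = v + (R_xlen_t)z0 * sxy + (R_xlen_t)y0 * nx + x0;
  double v000 = b[0], v100 = b[1], v010 = b[nx], v110 = b[nx + 1];
  double v001 = b[sxy], v101 = b[sxy + 1], v011 = b[sxy + nx],
         v111 = b[sxy + nx + 1];
  double c00 = v000 * (1 - fx) + v100 * fx;
  double c10 = v010 * (1 - fx) + v110 * fx;
  double c01 = v001 * (1 - fx) + v101 * fx;
  double c11 = v011 * (1 - fx) + v111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  g[0] = ((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
         ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz;
  g[1] = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
  g[2] = c1 - c0;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample a volume through a displacement field: out(x) = vol(x + u(x)).
// field: nvox*3 doubles (mm), or length 0 for identity. nearest: 1 for
// nearest-neighbour (masks), else trilinear with zero padding.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim,
                       NumericVector spacing, NumericVector field,
                       int nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const bool haveField = field.size() == 3 * nvox;
  NumericVector out(nvox);
  const double *vp = vol.begin();
  const double *fp = haveField ? field.begin() : NULL;
  R_xlen_t s = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, s++) {
        double px = i * spacing[0], py = j * spacing[1], pz = k * spacing[2];
        if (haveField) {
          px += fp[s];
          py += fp[s + nvox];
          pz += fp[s + 2 * nvox];
        }
        double x = px / spacing[0], y = py / spacing[1], z = pz / spacing[2];
        if (nearest) {
          int ii = (int)std::lround(x), jj = (int)std::lround(y),
              kk = (int)std::lround(z);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            out[s] = 0.0;
          else
            out[s] = vp[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii];
        } else {
          out[s] = tri_sample(vp, nx, ny, nz, x, y, z, 0);
        }
      }
  return out;
}

// Fixed-point inversion of a displacement field (both fields in mm on the
// same grid): find v with u(y + v(y)) + v(y) ~ 0.
// [[Rcpp::export]]
List cpp_invert_field(NumericVector field, IntegerVector dim,
                      NumericVector spacing, int maxit, double tol_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector inv(3 * nvox);
  const double *u0 = field.begin();
  const double *u1 = field.begin() + nvox;
  const double *u2 = field.begin() + 2 * nvox;
  double maxchange = 0.0;
  int it;
  for (it = 0; it < maxit; it++) {
    maxchange = 0.0;
    R_xlen_t s = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, s++) {
          double x = (i * spacing[0] + inv[s]) / spacing[0];
          double y = (j * spacing[1] + inv[s + nvox]) / spacing[1];
          double z = (k * spacing[2] + inv[s + 2 * nvox]) / spacing[2];
          double nu0 = -tri_sample(u0, nx, ny, nz, x, y, z, 1);
          double nu1 = -tri_sample(u1, nx, ny, nz, x, y, z, 1);
          double nu2 = -tri_sample(u2, nx, ny, nz, x, y, z, 1);
          double ch = std::fabs(nu0 - inv[s]) + std::fabs(nu1 - inv[s + nvox]) +
                      std::fabs(nu2 - inv[s + 2 * nvox]);
          if (ch > maxchange) maxchange = ch;
          inv[s] = nu0;
          inv[s + nvox] = nu1;
          inv[s + 2 * nvox] = nu2;
        }
    if (maxchange < tol_mm) break;
  }
  // composition residual u(y + v(y)) + v(y)
  double ss = 0.0;
  R_xlen_t s = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, s++) {
        double x = (i * spacing[0] + inv[s]) / spacing[0];
        double y = (j * spacing[1] + inv[s + nvox]) / spacing[1];
        double z = (k * spacing[2] + inv[s + 2 * nvox]) / spacing[2];
        double r0 = tri_sample(u0, nx, ny, nz, x, y, z, 1) + inv[s];
        double r1 = tri_sample(u1, nx, ny, nz, x, y, z, 1) + inv[s + nvox];
        double r2 = tri_sample(u2, nx, ny, nz, x, y, z, 1) + inv[s + 2 * nvox];
        ss += r0 * r0 + r1 * r1 + r2 * r2;
      }
  double rms = std::sqrt(ss / (double)nvox);
  return List::create(_["field"] = inv, _["rms_mm"] = rms,
                      _["iterations"] = it + 1);
}

// Separable Gaussian smoothing; sigma in voxel units per axis.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim,
                          NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(vol);
  for (int ax = 0; ax < 3; ax++) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    int r = (int)std::ceil(3.0 * sg);
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; t++) {
      kern[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      tot += kern[t + r];
    }
    for (size_t t = 0; t < kern.size(); t++) kern[t] /= tot;
    NumericVector nxt(nvox);
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (R_xlen_t)nx * ny;
    int len = n[ax];
    R_xlen_t s = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, s++) {
          int pos = (ax == 0) ? i : (ax == 1) ? j : k;
          double acc = 0, wsum = 0;
          for (int t = -r; t <= r; t++) {
            int q = pos + t;
            if (q < 0 || q >= len) continue;
            double w = kern[t + r];
            acc += w * cur[s + (R_xlen_t)t * stride];
            wsum += w;
          }
          nxt[s] = acc / wsum;
        }
    cur = nxt;
  }
  return cur;
}
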