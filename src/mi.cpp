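#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniform cubic B-spline basis on [0,1): weights for control points
// floor(t)-1 .. floor(t)+2.
static inline void bspl_w(double u, double *w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (4.0 - 6.0 * u2 + 3.0 * u3) / 6.0;
  w[2] = (1.0 + 3.0 * u + 3.0 * u2 - 3.0 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Cubic B-spline Parzen kernel (support |u| < 2) and derivative.
static inline double parzen3(double u) {
  double a = std::fabs(u);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return 2.0 / 3.0 - a * a + 0.5 * a * a * a;
  double b = 2.0 - a;
  return b * b * b / 6.0;
}
static inline double dparzen3(double u) {
  double a = std::fabs(u), s = (u < 0) ? -1.0 : 1.0;
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return s * (-2.0 * a + 1.5 * a * a);
  double b = 2.0 - a;
  return s * (-0.5 * b * b);
}

static double tri_grad_pad0(const double *v, int nx, int ny, int nz,
                            double x, double y, double z, double g[3],
                            int *inside) {
  g[0] = g[1] = g[2] = 0.0;
  *inside = 1;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *inside = 0;
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return 0.0;
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
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

// Negative mutual information (Mattes formulation: linear kernel on the
// fixed intensity, cubic B-spline Parzen on the moving intensity) of a
// fixed image vs a moving image warped by affine + base field + cubic
// B-spline FFD, with optional analytic gradient w.r.t. the FFD
// coefficients. Intensities are histogrammed over `samples` only, so
// excluded (e.g. tumor) voxels never touch the metric.
//
// affine: length 12, row-major 3x3 matrix A then translation t (mm),
//         mapping fixed-space physical points to moving-space points.
// baseField: length 3*nvox (mm) or 0.
// coef: ncx*ncy*ncz*3 control displacements (mm).
// [[Rcpp::export]]
List cpp_mi_ffd(NumericVector fixedImg, NumericVector movingImg,
                IntegerVector dim, NumericVector spacing,
                IntegerVector samples, NumericVector affine,
                NumericVector baseField, NumericVector coef,
                IntegerVector cdim, NumericVector corigin, double cspacing,
                NumericVector fRange, NumericVector mRange, int nbins,
                int wantGrad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ns = samples.size();
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
  const bool haveBase = baseField.size() == 3 * nvox;
  const double *bf = haveBase ? baseField.begin() : NULL;
  const double *mv = movingImg.begin();
  const double *A = affine.begin();

  const double fmin = fRange[0], fmax = fRange[1];
  const double mmin = mRange[0], mmax = mRange[1];
  const double fscale = (nbins - 1 - 1e-7) / std::max(fmax - fmin, 1e-12);
  const double mscale = (nbins - 3 - 1e-7) / std::max(mmax - mmin, 1e-12);

  std::vector<double> H((R_xlen_t)nbins * nbins, 0.0);
  // cached per-sample quantities for the gradient pass
  std::vector<double> smpM(wantGrad ? ns : 0), smpKap(ns), smpBf(ns);
  std::vector<double> smpGx, smpGy, smpGz;
  std::vector<char> smpOk(ns, 0);
  if (wantGrad) {
    smpGx.resize(ns);
    smpGy.resize(ns);
    smpGz.resize(ns);
  }

  double wx[4], wy[4], wz[4], g[3];
  double N = 0.0;

  for (R_xlen_t s = 0; s < ns; s++) {
    R_xlen_t idx = samples[s];
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    double px = i * spacing[0], py = j * spacing[1], pz = k * spacing[2];
    if (haveBase) {
      px += bf[idx];
      py += bf[idx + nvox];
      pz += bf[idx + 2 * nvox];
    }
    // FFD displacement
    double tx = (px - corigin[0]) / cspacing;
    double ty = (py - corigin[1]) / cspacing;
    double tz = (pz - corigin[2]) / cspacing;
    int gx = (int)std::floor(tx) - 1, gy = (int)std::floor(ty) - 1,
        gz = (int)std::floor(tz) - 1;
    if (gx < 0 || gy < 0 || gz < 0 || gx + 3 >= ncx || gy + 3 >= ncy ||
        gz + 3 >= ncz)
      continue; // outside lattice support: skip sample
    bspl_w(tx - std::floor(tx), wx);
    bspl_w(ty - std::floor(ty), wy);
    bspl_w(tz - std::floor(tz), wz);
    double ux = 0, uy = 0, uz = 0;
    for (int c = 0; c < 4; c++)
      for (int b = 0; b < 4; b++) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = (R_xlen_t)(gz + c) * ncx * ncy +
                        (R_xlen_t)(gy + b) * ncx + gx;
        for (int a = 0; a < 4; a++) {
          double w = wx[a] * wyz;
          R_xlen_t ci = base + a;
          ux += w * coef[ci];
          uy += w * coef[ci + ncp];
          uz += w * coef[ci + 2 * ncp];
        }
      }
    px += ux;
    py += uy;
    pz += uz;
    // affine
    double qx = A[0] * px + A[1] * py + A[2] * pz + A[9];
    double qy = A[3] * px + A[4] * py + A[5] * pz + A[10];
    double qz = A[6] * px + A[7] * py + A[8] * pz + A[11];
    int inside;
    double M = tri_grad_pad0(mv, nx, ny, nz, qx / spacing[0], qy / spacing[1],
                             qz / spacing[2], g, &inside);
    double F = fixedImg[idx];
    double bfix = (F - fmin) * fscale;
    if (bfix < 0) bfix = 0;
    if (bfix > nbins - 1 - 1e-7) bfix = nbins - 1 - 1e-7;
    double kap = 1.0 + (M - mmin) * mscale;
    int clamped = 0;
    if (kap < 1.0) { kap = 1.0; clamped = 1; }
    if (kap > nbins - 2 - 1e-7) { kap = nbins - 2 - 1e-7; clamped = 1; }
    int f0 = (int)std::floor(bfix);
    double wf1 = bfix - f0;
    int m0 = (int)std::floor(kap);
    for (int dm = -1; dm <= 2; dm++) {
      int m = m0 + dm;
      if (m < 0 || m >= nbins) continue;
      double wm = parzen3(kap - m);
      H[(R_xlen_t)f0 * nbins + m] += (1.0 - wf1) * wm;
      if (f0 + 1 < nbins) H[(R_xlen_t)(f0 + 1) * nbins + m] += wf1 * wm;
    }
    N += 1.0;
    smpOk[s] = (char)(inside && !clamped);
    smpKap[s] = kap;
    smpBf[s] = bfix;
    if (wantGrad) {
      smpM[s] = M;
      // gradient of M w.r.t. fixed-space mm, through the affine
      double gmx = g[0] / spacing[0], gmy = g[1] / spacing[1],
             gmz = g[2] / spacing[2];
      smpGx[s] = gmx * A[0] + gmy * A[3] + gmz * A[6];
      smpGy[s] = gmx * A[1] + gmy * A[4] + gmz * A[7];
      smpGz[s] = gmx * A[2] + gmy * A[5] + gmz * A[8];
    }
  }

  if (N < 10)
    return List::create(_["value"] = NA_REAL, _["grad"] = R_NilValue,
                        _["n"] = N);

  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int f = 0; f < nbins; f++)
    for (int m = 0; m < nbins; m++) {
      double p = H[(R_xlen_t)f * nbins + m] / N;
      H[(R_xlen_t)f * nbins + m] = p;
      pf[f] += p;
      pm[m] += p;
    }
  double mi = 0.0;
  std::vector<double> L((R_xlen_t)nbins * nbins, 0.0);
  for (int f = 0; f < nbins; f++)
    for (int m = 0; m < nbins; m++) {
      double p = H[(R_xlen_t)f * nbins + m];
      if (p > 0 && pf[f] > 0 && pm[m] > 0) {
        double l = std::log(p / (pf[f] * pm[m]));
        mi += p * l;
        L[(R_xlen_t)f * nbins + m] = l;
      }
    }

  if (!std::isfinite(mi))
    stop("mutual information metric is non-finite");

  if (!wantGrad)
    return List::create(_["value"] = -mi, _["grad"] = R_NilValue, _["n"] = N);

  NumericVector grad(3 * ncp);
  for (R_xlen_t s = 0; s < ns; s++) {
    if (!smpOk[s]) continue;
    R_xlen_t idx = samples[s];
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    double px = i * spacing[0], py = j * spacing[1], pz = k * spacing[2];
    if (haveBase) {
      px += bf[idx];
      py += bf[idx + nvox];
      pz += bf[idx + 2 * nvox];
    }
    double tx = (px - corigin[0]) / cspacing;
    double ty = (py - corigin[1]) / cspacing;
    double tz = (pz - corigin[2]) / cspacing;
    int gx = (int)std::floor(tx) - 1, gy = (int)std::floor(ty) - 1,
        gz = (int)std::floor(tz) - 1;
    if (gx < 0 || gy < 0 || gz < 0 || gx + 3 >= ncx || gy + 3 >= ncy ||
        gz + 3 >= ncz)
      continue;
    double kap = smpKap[s], bfix = smpBf[s];
    int f0 = (int)std::floor(bfix);
    double wf1 = bfix - f0;
    int m0 = (int)std::floor(kap);
    double sx = 0.0;
    for (int dm = -1; dm <= 2; dm++) {
      int m = m0 + dm;
      if (m < 0 || m >= nbins) continue;
      double dw = dparzen3(kap - m);
      double acc = (1.0 - wf1) * L[(R_xlen_t)f0 * nbins + m];
      if (f0 + 1 < nbins) acc += wf1 * L[(R_xlen_t)(f0 + 1) * nbins + m];
      sx += dw * acc;
    }
    if (sx == 0.0) continue;
    // d(-MI)/dcoef = -(1/N) * sx * mscale * (gradM . dT/dcoef)
    double c0 = -(sx * mscale) / N;
    double vx = c0 * smpGx[s], vy = c0 * smpGy[s], vz = c0 * smpGz[s];
    bspl_w(tx - std::floor(tx), wx);
    bspl_w(ty - std::floor(ty), wy);
    bspl_w(tz - std::floor(tz), wz);
    for (int c = 0; c < 4; c++)
      for (int b = 0; b < 4; b++) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = (R_xlen_t)(gz + c) * ncx * ncy +
                        (R_xlen_t)(gy + b) * ncx + gx;
        for (int a = 0; a < 4; a++) {
          double w = wx[a] * wyz;
          R_xlen_t ci = base + a;
          grad[ci] += w * vx;
          grad[ci + ncp] += w * vy;
          grad[ci + 2 * ncp] += w * vz;
        }
      }
  }
  return List::create(_["value"] = -mi, _["grad"] = grad, _["n"] = N);
}

// Dense evaluation of a cubic B-spline FFD on the image grid (mm out).
// [[Rcpp::export]]
NumericVector cpp_ffd_eval(NumericVector coef, IntegerVector cdim,
                           NumericVector corigin, double cspacing,
                           IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(3 * nvox);
  double wx[4], wy[4], wz[4];
  R_xlen_t s = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, s++) {
        double tx = (i * spacing[0] - corigin[0]) / cspacing;
        double ty = (j * spacing[1] - corigin[1]) / cspacing;
        double tz = (k * spacing[2] - corigin[2]) / cspacing;
        int gx = (int)std::floor(tx) - 1, gy = (int)std::floor(ty) - 1,
            gz = (int)std::floor(tz) - 1;
        if (gx < 0 || gy < 0 || gz < 0 || gx + 3 >= ncx || gy + 3 >= ncy ||
            gz + 3 >= ncz)
          continue;
        bspl_w(tx - std::floor(tx), wx);
        bspl_w(ty - std::floor(ty), wy);
        bspl_w(tz - std::floor(tz), wz);
        double ux = 0, uy = 0, uz = 0;
        for (int c = 0; c < 4; c++)
          for (int b = 0; b < 4; b++) {
            double wyz = wy[b] * wz[c];
            R_xlen_t base = (R_xlen_t)(gz + c) * ncx * ncy +
                            (R_xlen_t)(gy + b) * ncx + gx;
            for (int a = 0; a < 4; a++) {
              double w = wx[a] * wyz;
              R_xlen_t ci = base + a;
              ux += w * coef[ci];
              uy += w * coef[ci + ncp];
              uz += w * coef[ci + 2 * ncp];
            }
          }
        out[s] = ux;
        out[s + nvox] = uy;
        out[s + 2 * nvox] = uz;
      }
  return out;
}
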