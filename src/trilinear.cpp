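#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a 3D array at fractional 0-based coordinates.
// Points outside the grid sample as `fill`.
static inline double sample_one(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double* p = v + x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * sxy;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
  double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector vol, NumericMatrix pts,
                                   double fill = 0.0) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  const double* v = REAL(vol);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = sample_one(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// Resample a cubic volume under the affine map x_in = A (x_out - c) + c,
// c = N/2 in 0-based voxels (the FFT-centre convention used package-wide).
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, NumericMatrix A,
                                  double fill = 0.0) {
  IntegerVector dim = vol.attr("dim");
  int n = dim[0];
  if (dim[1] != n || dim[2] != n) stop("volume must be cubic");
  double c = n / 2.0;
  // integer centre for even boxes
  c = (double)(n / 2);
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const double* v = REAL(vol);
  double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  double a31 = A(2, 0), a32 = A(2, 1), a33 = A(2, 2);
  R_xlen_t idx = 0;
  for (int k = 0; k < n; ++k) {
    double dz = k - c;
    for (int j = 0; j < n; ++j) {
      double dy = j - c;
      double bx = a12 * dy + a13 * dz + c;
      double by = a22 * dy + a23 * dz + c;
      double bz = a32 * dy + a33 * dz + c;
      for (int i = 0; i < n; ++i, ++idx) {
        double dx = i - c;
        out[idx] = sample_one(v, n, n, n,
                              a11 * dx + bx, a21 * dx + by, a31 * dx + bz,
                              fill);
      }
    }
  }
  return out;
}

// Spread one CTF-weighted central section into the accumulator grids.
// fre/fim: P x P Fourier transform of the (padded, origin-phased,
// shift-corrected) image; ctf: P x P; R maps reference-frame coordinates to
// the imaging frame, so the section pixel (hx, hy, 0) lands at g = R^T h.
// Data are weighted by ctf, weights by ctf^2; grids are modified in place.
// [[Rcpp::export]]
void cpp_insert_slice(NumericVector sre, NumericVector sim, NumericVector wt,
                      NumericMatrix fre, NumericMatrix fim, NumericMatrix ctf,
                      NumericMatrix R) {
  IntegerVector dim = sre.attr("dim");
  int P = dim[0];
  if (fre.nrow() != P) stop("image FT size must match accumulator size");
  // g = R^T (hx, hy, 0) = hx * row1(R) + hy * row2(R)
  double r11 = R(0, 0), r12 = R(0, 1), r13 = R(0, 2);
  double r21 = R(1, 0), r22 = R(1, 1), r23 = R(1, 2);
  double* pre = REAL(sre);
  double* pim = REAL(sim);
  double* pwt = REAL(wt);
  double rmax2 = (P / 2.0 - 1.0) * (P / 2.0 - 1.0);
  R_xlen_t sxy = (R_xlen_t)P * P;
  for (int j = 0; j < P; ++j) {
    int hy = (j <= P / 2) ? j : j - P;
    for (int i = 0; i < P; ++i) {
      int hx = (i <= P / 2) ? i : i - P;
      double gx = r11 * hx + r21 * hy;
      double gy = r12 * hx + r22 * hy;
      double gz = r13 * hx + r23 * hy;
      if (gx * gx + gy * gy + gz * gz > rmax2) continue;
      double c = ctf(i, j);
      double dre = fre(i, j) * c, dim_ = fim(i, j) * c, w = c * c;
      int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
          z0 = (int)std::floor(gz);
      double fx = gx - x0, fy = gy - y0, fz = gz - z0;
      for (int dz = 0; dz < 2; ++dz) {
        double wz = dz ? fz : 1 - fz;
        int kz = ((z0 + dz) % P + P) % P;
        for (int dy2 = 0; dy2 < 2; ++dy2) {
          double wy = dy2 ? fy : 1 - fy;
          int ky = ((y0 + dy2) % P + P) % P;
          for (int dx2 = 0; dx2 < 2; ++dx2) {
            double wxyz = wz * wy * (dx2 ? fx : 1 - fx);
            if (wxyz == 0) continue;
            int kx = ((x0 + dx2) % P + P) % P;
            R_xlen_t id = kx + (R_xlen_t)ky * P + (R_xlen_t)kz * sxy;
            pre[id] += dre * wxyz;
            pim[id] += dim_ * wxyz;
            pwt[id] += w * wxyz;
          }
        }
      }
    }
  }
}
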