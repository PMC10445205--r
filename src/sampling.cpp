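// Interpolation and resampling kernels.
//
// Volumes are R arrays in column-major order, dim (nx, ny, nz) or
// (nx, ny, nz, C).  Voxel indices are 0-based in C++; world position of
// voxel (i,j,k) is origin + (i,j,k) * spacing.  All samplers clamp to the
// border (replicate padding).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double at3(const double* v, int nx, int ny, int nz,
                         int i, int j, int k) {
  i = i < 0 ? 0 : (i >= nx ? nx - 1 : i);
  j = j < 0 ? 0 : (j >= ny ? ny - 1 : j);
  k = k < 0 ? 0 : (k >= nz ? nz - 1 : k);
  return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

static double sample_linear(const double* v, int nx, int ny, int nz,
                            double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 >= nx - 1) i0 = nx - 2 < 0 ? 0 : nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2 < 0 ? 0 : ny - 2;
  if (k0 >= nz - 1) k0 = nz - 2 < 0 ? 0 : nz - 2;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        if (w != 0.0) acc += w * at3(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
      }
  return acc;
}

static double sample_nearest(const double* v, int nx, int ny, int nz,
                             double x, double y, double z) {
  int i = (int)std::lround(clampd(x, 0.0, nx - 1.0));
  int j = (int)std::lround(clampd(y, 0.0, ny - 1.0));
  int k = (int)std::lround(clampd(z, 0.0, nz - 1.0));
  return at3(v, nx, ny, nz, i, j, k);
}

// uniform cubic B-spline basis weights for fractional offset t in [0,1)
static inline void cubic_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static double sample_cubic(const double* v, int nx, int ny, int nz,
                           double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cubic_w(x - i0, wx); cubic_w(y - j0, wy); cubic_w(z - k0, wz);
  double acc = 0.0;
  for (int dk = 0; dk < 4; ++dk) {
    double azk = wz[dk];
    for (int dj = 0; dj < 4; ++dj) {
      double ajk = azk * wy[dj];
      for (int di = 0; di < 4; ++di)
        acc += ajk * wx[di] *
               at3(v, nx, ny, nz, i0 - 1 + di, j0 - 1 + dj, k0 - 1 + dk);
    }
  }
  return acc;
}

// In-place cubic B-spline prefilter (makes sample_cubic interpolating).
// Causal/anticausal recursive filter with pole sqrt(3) - 2, mirror boundary.
static void prefilter_line(double* c, int n, R_xlen_t stride) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  // initial causal coefficient under mirror boundary conditions: truncated
  // series when the line is long enough, exact mirrored sum otherwise
  const int horizon = 32;  // |z|^32 << machine epsilon
  double sum;
  if (n > horizon) {
    sum = c[0];
    double zn = z;
    for (int i = 1; i < horizon; ++i) {
      sum += zn * c[(R_xlen_t)i * stride];
      zn *= z;
    }
  } else {
    double zn = z, iz = 1.0 / z;
    double z2n = std::pow(z, n - 1);
    sum = c[0] + z2n * c[(R_xlen_t)(n - 1) * stride];
    z2n *= z2n * iz;
    for (int i = 1; i <= n - 2; ++i) {
      sum += (zn + z2n) * c[(R_xlen_t)i * stride];
      zn *= z;
      z2n *= iz;
    }
    sum /= (1.0 - std::pow(z, 2 * n - 2));
  }
  c[0] = lambda * sum;
  for (int i = 1; i < n; ++i)
    c[(R_xlen_t)i * stride] = lambda * c[(R_xlen_t)i * stride] + z * c[(R_xlen_t)(i - 1) * stride];
  // initial anticausal coefficient
  c[(R_xlen_t)(n - 1) * stride] =
      (z / (z * z - 1.0)) * (z * c[(R_xlen_t)(n - 2) * stride] + c[(R_xlen_t)(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[(R_xlen_t)i * stride] = z * (c[(R_xlen_t)(i + 1) * stride] - c[(R_xlen_t)i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(vol);
  double* v = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      prefilter_line(v + (R_xlen_t)nx * (j + (R_xlen_t)ny * k), nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      prefilter_line(v + i + (R_xlen_t)nx * ((R_xlen_t)ny * k), ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      prefilter_line(v + i + (R_xlen_t)nx * j, nz, (R_xlen_t)nx * ny);
  return out;
}

// Resample through an affine index map: source voxel coords of target voxel
// (i,j,k) are M %*% c(i,j,k,1), M a 3x4 matrix.  method: 0 nearest,
// 1 trilinear, 2 cubic B-spline (volume must be prefiltered by caller).
// [[Rcpp::export]]
NumericVector cpp_resample_matrix(NumericVector vol, IntegerVector sdims,
                                  NumericMatrix M, IntegerVector tdims,
                                  int method) {
  int nx = sdims[0], ny = sdims[1], nz = sdims[2];
  int mx = tdims[0], my = tdims[1], mz = tdims[2];
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)mx * my * mz);
  double* o = REAL(out);
  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + M(0,3);
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + M(1,3);
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + M(2,3);
        o[idx] = method == 0 ? sample_nearest(v, nx, ny, nz, x, y, z)
               : method == 1 ? sample_linear(v, nx, ny, nz, x, y, z)
                             : sample_cubic(v, nx, ny, nz, x, y, z);
      }
  out.attr("dim") = tdims;
  return out;
}

// Sample a volume at arbitrary voxel coordinates (N x 3 matrix), trilinear.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = sample_linear(v, nx, ny, nz, pts(r,0), pts(r,1), pts(r,2));
  return out;
}

// ---------------------------------------------------------------------------
// Spatial-transformer warp: out(x) = moving(x + u(x)), u in voxel units on
// the same grid, one array per channel stacked in dim 4.  Border replicate.

// [[Rcpp::export]]
NumericVector cpp_warp_linear(NumericVector vol, IntegerVector dims, int nc,
                              NumericVector u) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* ux = REAL(u);
  const double* uy = ux + nvox;
  const double* uz = uy + nvox;
  NumericVector out(nvox * nc);
  for (int c = 0; c < nc; ++c) {
    const double* v = REAL(vol) + nvox * c;
    double* o = REAL(out) + nvox * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx)
          o[idx] = sample_linear(v, nx, ny, nz,
                                 i + ux[idx], j + uy[idx], k + uz[idx]);
  }
  if (nc > 1) out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  else out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Gradient of sum(gout * warp(vol, u)) with respect to u (voxel units).
// [[Rcpp::export]]
NumericVector cpp_warp_linear_bw(NumericVector vol, IntegerVector dims, int nc,
                                 NumericVector u, NumericVector gout) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* ux = REAL(u);
  const double* uy = ux + nvox;
  const double* uz = uy + nvox;
  NumericVector gu(nvox * 3);
  double* gx = REAL(gu);
  double* gy = gx + nvox;
  double* gz = gy + nvox;
  for (int c = 0; c < nc; ++c) {
    const double* v = REAL(vol) + nvox * c;
    const double* g = REAL(gout) + nvox * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          if (g[idx] == 0.0) continue;
          double x = i + ux[idx], y = j + uy[idx], z = k + uz[idx];
          double xc = clampd(x, 0.0, nx - 1.0);
          double yc = clampd(y, 0.0, ny - 1.0);
          double zc = clampd(z, 0.0, nz - 1.0);
          bool inx = (x > 0.0 && x < nx - 1.0);
          bool iny = (y > 0.0 && y < ny - 1.0);
          bool inz = (z > 0.0 && z < nz - 1.0);
          int i0 = (int)std::floor(xc); if (i0 >= nx - 1) i0 = nx - 2 < 0 ? 0 : nx - 2;
          int j0 = (int)std::floor(yc); if (j0 >= ny - 1) j0 = ny - 2 < 0 ? 0 : ny - 2;
          int k0 = (int)std::floor(zc); if (k0 >= nz - 1) k0 = nz - 2 < 0 ? 0 : nz - 2;
          double fx = xc - i0, fy = yc - j0, fz = zc - k0;
          double dgx = 0, dgy = 0, dgz = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                double val = at3(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
                double wx = di ? fx : 1 - fx, dwx = di ? 1.0 : -1.0;
                double wy = dj ? fy : 1 - fy, dwy = dj ? 1.0 : -1.0;
                double wz = dk ? fz : 1 - fz, dwz = dk ? 1.0 : -1.0;
                dgx += dwx * wy * wz * val;
                dgy += wx * dwy * wz * val;
                dgz += wx * wy * dwz * val;
              }
          double gg = g[idx];
          if (inx) gx[idx] += gg * dgx;
          if (iny) gy[idx] += gg * dgy;
          if (inz) gz[idx] += gg * dgz;
        }
  }
  gu.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return gu;
}
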