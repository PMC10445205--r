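// Cubic B-spline free-form deformation kernels.
//
// The control lattice is an R array (ncx, ncy, ncz, 3) of mm displacements;
// control point (a,b,c) sits at world position cp_origin + (a,b,c) *
// cp_spacing.  The dense displacement at world position x is the cubic
// tensor-product B-spline combination of the 4x4x4 surrounding control
// points.  The lattice must cover every evaluation point with the full
// cubic support (no implicit border extension).
#include <Rcpp.h>
using namespace Rcpp;

static inline void cubic_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_bspline_dense(NumericVector cp, IntegerVector cdims,
                                NumericVector cp_origin, NumericVector cp_spacing,
                                IntegerVector gdims, NumericVector gspacing,
                                NumericVector gorigin) {
  int ncx = cdims[0], ncy = cdims[1], ncz = cdims[2];
  int nx = gdims[0], ny = gdims[1], nz = gdims[2];
  R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* c[3] = { REAL(cp), REAL(cp) + ncp, REAL(cp) + 2 * ncp };
  NumericVector out(nvox * 3);
  double* o[3] = { REAL(out), REAL(out) + nvox, REAL(out) + 2 * nvox };
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double sz = (gorigin[2] + k * gspacing[2] - cp_origin[2]) / cp_spacing[2];
    int lz = (int)std::floor(sz);
    double wz[4]; cubic_w(sz - lz, wz);
    for (int j = 0; j < ny; ++j) {
      double sy = (gorigin[1] + j * gspacing[1] - cp_origin[1]) / cp_spacing[1];
      int ly = (int)std::floor(sy);
      double wy[4]; cubic_w(sy - ly, wy);
      for (int i = 0; i < nx; ++i, ++idx) {
        double sx = (gorigin[0] + i * gspacing[0] - cp_origin[0]) / cp_spacing[0];
        int lx = (int)std::floor(sx);
        double wx[4]; cubic_w(sx - lx, wx);
        if (lx < 1 || lx + 2 >= ncx || ly < 1 || ly + 2 >= ncy ||
            lz < 1 || lz + 2 >= ncz)
          stop("control lattice does not cover the target grid with cubic support");
        double acc[3] = { 0, 0, 0 };
        for (int dz = 0; dz < 4; ++dz)
          for (int dy = 0; dy < 4; ++dy) {
            double wyz = wy[dy] * wz[dz];
            R_xlen_t base = (R_xlen_t)(lx - 1) +
                            (R_xlen_t)ncx * ((ly - 1 + dy) +
                            (R_xlen_t)ncy * (lz - 1 + dz));
            for (int dx = 0; dx < 4; ++dx) {
              double w = wx[dx] * wyz;
              acc[0] += w * c[0][base + dx];
              acc[1] += w * c[1][base + dx];
              acc[2] += w * c[2][base + dx];
            }
          }
        o[0][idx] = acc[0]; o[1][idx] = acc[1]; o[2][idx] = acc[2];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Displacements at arbitrary world positions (N x 3, mm).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_at_points(NumericVector cp, IntegerVector cdims,
                                    NumericVector cp_origin,
                                    NumericVector cp_spacing,
                                    NumericMatrix pts) {
  int ncx = cdims[0], ncy = cdims[1], ncz = cdims[2];
  R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
  const double* c[3] = { REAL(cp), REAL(cp) + ncp, REAL(cp) + 2 * ncp };
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    double s[3]; int l[3]; double w[3][4];
    for (int d = 0; d < 3; ++d) {
      s[d] = (pts(r,d) - cp_origin[d]) / cp_spacing[d];
      l[d] = (int)std::floor(s[d]);
      cubic_w(s[d] - l[d], w[d]);
    }
    if (l[0] < 1 || l[0] + 2 >= ncx || l[1] < 1 || l[1] + 2 >= ncy ||
        l[2] < 1 || l[2] + 2 >= ncz)
      stop("control lattice does not cover a sample point with cubic support");
    double acc[3] = { 0, 0, 0 };
    for (int dz = 0; dz < 4; ++dz)
      for (int dy = 0; dy < 4; ++dy) {
        double wyz = w[1][dy] * w[2][dz];
        R_xlen_t base = (R_xlen_t)(l[0] - 1) +
                        (R_xlen_t)ncx * ((l[1] - 1 + dy) +
                        (R_xlen_t)ncy * (l[2] - 1 + dz));
        for (int dx = 0; dx < 4; ++dx) {
          double ww = w[0][dx] * wyz;
          acc[0] += ww * c[0][base + dx];
          acc[1] += ww * c[1][base + dx];
          acc[2] += ww * c[2][base + dx];
        }
      }
    out(r,0) = acc[0]; out(r,1) = acc[1]; out(r,2) = acc[2];
  }
  return out;
}

// Scatter per-point gradients (N x 3, d objective / d displacement at the
// point) back onto the control lattice with the same cubic weights.
// [[Rcpp::export]]
NumericVector cpp_bspline_grad_accum(IntegerVector cdims,
                                     NumericVector cp_origin,
                                     NumericVector cp_spacing,
                                     NumericMatrix pts, NumericMatrix g) {
  int ncx = cdims[0], ncy = cdims[1], ncz = cdims[2];
  R_xlen_t ncp = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(ncp * 3);
  double* oc[3] = { REAL(out), REAL(out) + ncp, REAL(out) + 2 * ncp };
  int n = pts.nrow();
  for (int r = 0; r < n; ++r) {
    double s[3]; int l[3]; double w[3][4];
    for (int d = 0; d < 3; ++d) {
      s[d] = (pts(r,d) - cp_origin[d]) / cp_spacing[d];
      l[d] = (int)std::floor(s[d]);
      cubic_w(s[d] - l[d], w[d]);
    }
    if (l[0] < 1 || l[0] + 2 >= ncx || l[1] < 1 || l[1] + 2 >= ncy ||
        l[2] < 1 || l[2] + 2 >= ncz)
      continue;  // points outside the covered region do not contribute
    for (int dz = 0; dz < 4; ++dz)
      for (int dy = 0; dy < 4; ++dy) {
        double wyz = w[1][dy] * w[2][dz];
        R_xlen_t base = (R_xlen_t)(l[0] - 1) +
                        (R_xlen_t)ncx * ((l[1] - 1 + dy) +
                        (R_xlen_t)ncy * (l[2] - 1 + dz));
        for (int dx = 0; dx < 4; ++dx) {
          double ww = w[0][dx] * wyz;
          oc[0][base + dx] += ww * g(r,0);
          oc[1][base + dx] += ww * g(r,1);
          oc[2][base + dx] += ww * g(r,2);
        }
      }
  }
  out.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
  return out;
}
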