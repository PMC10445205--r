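// Geometric evaluation kernels: surface extraction, directed surface
// distances, Jacobian determinants, and a Euclidean distance transform.
#include <Rcpp.h>
using namespace Rcpp;

// Border voxels: mask voxels with at least one face-adjacent voxel outside
// the mask; voxels on the array boundary count as border.
// [[Rcpp::export]]
LogicalVector cpp_surface_mask(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!m[idx]) continue;
        bool border = i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                      k == 0 || k == nz - 1;
        if (!border) {
          border = !m[idx - 1] || !m[idx + 1] ||
                   !m[idx - nx] || !m[idx + nx] ||
                   !m[idx - (R_xlen_t)nx * ny] || !m[idx + (R_xlen_t)nx * ny];
        }
        o[idx] = border;
      }
  return out;
}

// Minimum Euclidean distance (mm) from each row of A to the point set B.
// Coordinates are voxel indices; spacing converts to mm.
// [[Rcpp::export]]
NumericVector cpp_directed_dists(IntegerMatrix A, IntegerMatrix B,
                                 NumericVector spacing) {
  int na = A.nrow(), nb = B.nrow();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(na);
  for (int r = 0; r < na; ++r) {
    double best = R_PosInf;
    double ax = A(r,0) * sx, ay = A(r,1) * sy, az = A(r,2) * sz;
    for (int s = 0; s < nb; ++s) {
      double dx = ax - B(s,0) * sx;
      double dy = ay - B(s,1) * sy;
      double dz = az - B(s,2) * sz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[r] = std::sqrt(best);
  }
  return out;
}

// Determinant of the Jacobian of x -> x + u(x), u in mm, central differences
// in mm (one-sided at the boundary).
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector u, IntegerVector dims,
                               NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* uc[3] = { REAL(u), REAL(u) + nvox, REAL(u) + 2 * nvox };
  NumericVector out(nvox);
  double* o = REAL(out);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double J[3][3];
        int c0[3] = { i, j, k };
        int nmax[3] = { nx, ny, nz };
        for (int d = 0; d < 3; ++d) {        // derivative direction
          int lo = c0[d] > 0 ? c0[d] - 1 : c0[d];
          int hi = c0[d] < nmax[d] - 1 ? c0[d] + 1 : c0[d];
          double h = (hi - lo) * spacing[d];
          R_xlen_t ilo, ihi;
          int p[3] = { i, j, k };
          p[d] = lo; ilo = p[0] + (R_xlen_t)nx * (p[1] + (R_xlen_t)ny * p[2]);
          p[d] = hi; ihi = p[0] + (R_xlen_t)nx * (p[1] + (R_xlen_t)ny * p[2]);
          for (int c = 0; c < 3; ++c) {      // displacement component
            J[c][d] = (uc[c][ihi] - uc[c][ilo]) / h + (c == d ? 1.0 : 0.0);
          }
        }
        o[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), squared
// distances propagated along each axis in turn, anisotropic spacing.

static void edt_1d(const double* f, double* d, int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -R_PosInf; z[1] = R_PosInf;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      double xi = i * step, xv = v[q] * step;
      s = ((f[i] + xi * xi) - (f[v[q]] + xv * xv)) / (2 * xi - 2 * xv);
      if (s > z[q]) break;
      --q;
    }
    ++q; v[q] = i; z[q] = s; z[q + 1] = R_PosInf;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * step;
    while (z[q + 1] < xi) ++q;
    double dx = xi - v[q] * step;
    d[i] = dx * dx + f[v[q]];
  }
}

// Distance (mm) from every voxel to the nearest TRUE voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(nvox);
  const int* m = LOGICAL(mask);
  // large finite sentinel keeps the parabola intersections well-defined
  for (R_xlen_t v = 0; v < nvox; ++v) d[v] = m[v] ? 0.0 : 1e20;
  std::vector<double> line(std::max({nx, ny, nz}));
  std::vector<double> out_line(std::max({nx, ny, nz}));
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = d[base + i];
      edt_1d(line.data(), out_line.data(), nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = out_line[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ((R_xlen_t)ny * k);
      for (int j = 0; j < ny; ++j) line[j] = d[base + (R_xlen_t)nx * j];
      edt_1d(line.data(), out_line.data(), ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = out_line[j];
    }
  // z pass
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) line[k] = d[base + plane * k];
      edt_1d(line.data(), out_line.data(), nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[base + plane * k] = out_line[k];
    }
  NumericVector res(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) res[v] = std::sqrt(d[v]);
  res.attr("dim") = dims;
  return res;
}
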