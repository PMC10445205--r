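// 3D convolution and upsampling kernels for the registration network.
//
// Feature maps are R arrays (nx, ny, nz, C), column-major.  Convolutions
// use 3x3x3 kernels with zero padding 1 and stride 1 or 2, implemented as
// im2col + GEMM (Armadillo/BLAS).  Weight matrices are (Cout, 27*Cin) with
// row index r = ((cin*3 + kz)*3 + ky)*3 + kx for tap offsets (kx,ky,kz) in
// {0,1,2} relative to the corner of the receptive field.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int outdim(int n, int stride) { return (n + 2 - 3) / stride + 1; }

static void im2col(const double* x, int nx, int ny, int nz, int cin,
                   int stride, arma::mat& col) {
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  col.zeros(27 * cin, (R_xlen_t)ox * oy * oz);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + nvox * c;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          int r = ((c * 3 + kz) * 3 + ky) * 3 + kx;
          R_xlen_t cidx = 0;
          for (int k = 0; k < oz; ++k) {
            int sz = k * stride + kz - 1;
            for (int j = 0; j < oy; ++j) {
              int sy = j * stride + ky - 1;
              bool okyz = sz >= 0 && sz < nz && sy >= 0 && sy < ny;
              for (int i = 0; i < ox; ++i, ++cidx) {
                int sx = i * stride + kx - 1;
                if (okyz && sx >= 0 && sx < nx)
                  col(r, cidx) = xc[sx + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz)];
              }
            }
          }
        }
  }
}

static void col2im(const arma::mat& col, int nx, int ny, int nz, int cin,
                   int stride, double* gx) {
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + nvox * c;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          int r = ((c * 3 + kz) * 3 + ky) * 3 + kx;
          R_xlen_t cidx = 0;
          for (int k = 0; k < oz; ++k) {
            int sz = k * stride + kz - 1;
            for (int j = 0; j < oy; ++j) {
              int sy = j * stride + ky - 1;
              bool okyz = sz >= 0 && sz < nz && sy >= 0 && sy < ny;
              for (int i = 0; i < ox; ++i, ++cidx) {
                int sx = i * stride + kx - 1;
                if (okyz && sx >= 0 && sx < nx)
                  gc[sx + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz)] += col(r, cidx);
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims, int cin,
                            NumericMatrix W, NumericVector b, int stride) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cout = W.nrow();
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  arma::mat col;
  im2col(REAL(x), nx, ny, nz, cin, stride, col);
  arma::mat Wm(W.begin(), cout, 27 * cin, false);
  arma::mat y = Wm * col;  // cout x Nout
  y.each_col() += arma::vec(b.begin(), cout);
  arma::mat yt = y.t();    // Nout x cout, matches R array layout
  NumericVector out(yt.begin(), yt.end());
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims, int cin,
                   NumericMatrix W, NumericVector gy, int stride,
                   bool need_gx) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cout = W.nrow();
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  arma::mat col;
  im2col(REAL(x), nx, ny, nz, cin, stride, col);
  arma::mat gyt(REAL(gy), nout, cout, false);   // Nout x cout
  arma::mat gym = gyt.t();                      // cout x Nout
  arma::mat gW = gym * col.t();                 // cout x 27cin
  arma::vec gb = arma::sum(gym, 1);
  List res;
  res["gW"] = NumericMatrix(cout, 27 * cin, gW.begin());
  res["gb"] = NumericVector(gb.begin(), gb.end());
  if (need_gx) {
    arma::mat Wm(W.begin(), cout, 27 * cin, false);
    arma::mat gcol = Wm.t() * gym;              // 27cin x Nout
    NumericVector gx((R_xlen_t)nx * ny * nz * cin);
    col2im(gcol, nx, ny, nz, cin, stride, REAL(gx));
    gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
    res["gx"] = gx;
  }
  return res;
}

// Nearest-neighbour 2x upsampling of (nx,ny,nz,C): out[i] = in[i/2].
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, IntegerVector dims, int nc) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nout * nc);
  for (int c = 0; c < nc; ++c) {
    const double* v = REAL(x) + nin * c;
    double* o = REAL(out) + nout * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i, ++idx)
          o[idx] = v[(i / 2) + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2))];
  }
  out.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector g, IntegerVector odims, int nc) {
  int mx = odims[0], my = odims[1], mz = odims[2];
  int nx = mx / 2, ny = my / 2, nz = mz / 2;
  R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nin * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gv = REAL(g) + nout * c;
    double* o = REAL(out) + nin * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i, ++idx)
          o[(i / 2) + (R_xlen_t)nx * ((j / 2) + (R_xlen_t)ny * (k / 2))] += gv[idx];
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}

// Trilinear 2x upsampling used for the flow head: output voxel i samples the
// half-resolution map at coordinate i/2 (clamped).  Backward scatters the
// same weights.
// [[Rcpp::export]]
NumericVector cpp_upsample2_lin_fw(NumericVector x, IntegerVector dims, int nc) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nout * nc);
  for (int c = 0; c < nc; ++c) {
    const double* v = REAL(x) + nin * c;
    double* o = REAL(out) + nout * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < mz; ++k) {
      double z = k / 2.0; int k0 = k / 2; double fz = z - k0;
      int k1 = k0 + 1 < nz ? k0 + 1 : nz - 1;
      for (int j = 0; j < my; ++j) {
        double y = j / 2.0; int j0 = j / 2; double fy = y - j0;
        int j1 = j0 + 1 < ny ? j0 + 1 : ny - 1;
        for (int i = 0; i < mx; ++i, ++idx) {
          double xq = i / 2.0; int i0 = i / 2; double fx = xq - i0;
          int i1 = i0 + 1 < nx ? i0 + 1 : nx - 1;
          double v000 = v[i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0)];
          double v100 = v[i1 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0)];
          double v010 = v[i0 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k0)];
          double v110 = v[i1 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k0)];
          double v001 = v[i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k1)];
          double v101 = v[i1 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k1)];
          double v011 = v[i0 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k1)];
          double v111 = v[i1 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k1)];
          double c00 = v000 * (1 - fx) + v100 * fx;
          double c10 = v010 * (1 - fx) + v110 * fx;
          double c01 = v001 * (1 - fx) + v101 * fx;
          double c11 = v011 * (1 - fx) + v111 * fx;
          o[idx] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                   (c01 * (1 - fy) + c11 * fy) * fz;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_lin_bw(NumericVector g, IntegerVector odims, int nc) {
  int mx = odims[0], my = odims[1], mz = odims[2];
  int nx = mx / 2, ny = my / 2, nz = mz / 2;
  R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nin * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gv = REAL(g) + nout * c;
    double* o = REAL(out) + nin * c;
    R_xlen_t idx = 0;
    for (int k = 0; k < mz; ++k) {
      int k0 = k / 2; double fz = k / 2.0 - k0;
      int k1 = k0 + 1 < nz ? k0 + 1 : nz - 1;
      for (int j = 0; j < my; ++j) {
        int j0 = j / 2; double fy = j / 2.0 - j0;
        int j1 = j0 + 1 < ny ? j0 + 1 : ny - 1;
        for (int i = 0; i < mx; ++i, ++idx) {
          int i0 = i / 2; double fx = i / 2.0 - i0;
          int i1 = i0 + 1 < nx ? i0 + 1 : nx - 1;
          double gg = gv[idx];
          if (gg == 0.0) continue;
          o[i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0)] += gg * (1-fx)*(1-fy)*(1-fz);
          o[i1 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0)] += gg * fx*(1-fy)*(1-fz);
          o[i0 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k0)] += gg * (1-fx)*fy*(1-fz);
          o[i1 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k0)] += gg * fx*fy*(1-fz);
          o[i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k1)] += gg * (1-fx)*(1-fy)*fz;
          o[i1 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k1)] += gg * fx*(1-fy)*fz;
          o[i0 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k1)] += gg * (1-fx)*fy*fz;
          o[i1 + (R_xlen_t)nx * (j1 + (R_xlen_t)ny * k1)] += gg * fx*fy*fz;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}

// Forward pass that also returns the im2col matrix so the backward pass
// can skip rebuilding it (the dominant cost at training time).
// [[Rcpp::export]]
List cpp_conv3d_fwc(NumericVector x, IntegerVector dims, int cin,
                    NumericMatrix W, NumericVector b, int stride) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cout = W.nrow();
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  arma::mat col;
  im2col(REAL(x), nx, ny, nz, cin, stride, col);
  arma::mat Wm(W.begin(), cout, 27 * cin, false);
  arma::mat y = Wm * col;
  y.each_col() += arma::vec(b.begin(), cout);
  arma::mat yt = y.t();
  NumericVector out(yt.begin(), yt.end());
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  XPtr<arma::mat> ptr(new arma::mat(std::move(col)), true);
  return List::create(_["y"] = out, _["col"] = ptr);
}

// Backward pass consuming a cached im2col matrix.
// [[Rcpp::export]]
List cpp_conv3d_bwc(SEXP colPtr, IntegerVector dims, int cin,
                    NumericMatrix W, NumericVector gy, int stride,
                    bool need_gx) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cout = W.nrow();
  int ox = outdim(nx, stride), oy = outdim(ny, stride), oz = outdim(nz, stride);
  R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  XPtr<arma::mat> cp(colPtr);
  const arma::mat& col = *cp;
  arma::mat gyt(REAL(gy), nout, cout, false);
  arma::mat gym = gyt.t();
  arma::mat gW = gym * col.t();
  arma::vec gb = arma::sum(gym, 1);
  List res;
  res["gW"] = NumericMatrix(cout, 27 * cin, gW.begin());
  res["gb"] = NumericVector(gb.begin(), gb.end());
  if (need_gx) {
    arma::mat Wm(W.begin(), cout, 27 * cin, false);
    arma::mat gcol = Wm.t() * gym;
    NumericVector gx((R_xlen_t)nx * ny * nz * cin);
    col2im(gcol, nx, ny, nz, cin, stride, REAL(gx));
    gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
    res["gx"] = gx;
  }
  return res;
}
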