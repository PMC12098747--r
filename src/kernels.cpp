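// Numerical kernels: im2col/GEMM 2-D convolution (forward + backward) used by
// the conditional-GAN layers, and a marching-tetrahedra iso-surface area
// estimator used by the 3-D morphometrics.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Unfold x (H, W, Cin) into K of shape (kh*kw*Cin) x (Ho*Wo).
// Row index r = ki + kh*(kj + kw*c) matches R's column-major flattening of a
// (kh, kw, Cin, Cout) weight array; column index = io + Ho*jo.
static void im2col_fill(const cube &x, int kh, int kw, int stride, int pad,
                        int Ho, int Wo, mat &K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  K.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            if (ii < 0 || ii >= H) continue;
            K(r, io + Ho * jo) = x(ii, jj, c);
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_fill.
static void col2im_add(const mat &K, int kh, int kw, int stride, int pad,
                       int Ho, int Wo, cube &gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            if (ii < 0 || ii >= H) continue;
            gx(ii, jj, c) += K(r, io + Ho * jo);
          }
        }
      }
    }
  }
}

// Forward pass; also returns the unfolded input K so the backward pass can
// reuse it (training is batch-1 sequential, so caching K per layer is cheap).
// [[Rcpp::export]]
Rcpp::List conv2d_fwd_cpp(const arma::cube &x, const arma::vec &w,
                          const arma::ivec &wdim, const arma::vec &b,
                          int stride, int pad) {
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if ((int)x.n_slices != Cin) stop("conv2d: channel mismatch");
  const int Ho = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - kw) / stride + 1;
  mat K(kh * kw * Cin, Ho * Wo);
  im2col_fill(x, kh, kw, stride, pad, Ho, Wo, K);
  mat Wm(const_cast<double *>(w.memptr()), kh * kw * Cin, Cout, false, true);
  mat Y = Wm.t() * K;           // Cout x (Ho*Wo)
  Y.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(Y.row(co).t(), Ho, Wo);
  return List::create(Named("out") = out, Named("K") = K);
}

// Backward pass given the cached unfolded input K.
// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::mat &K, const arma::vec &w,
                          const arma::ivec &wdim, const arma::cube &gy,
                          const arma::ivec &xdim, int stride, int pad) {
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  mat Gy(Cout, Ho * Wo);
  for (int co = 0; co < Cout; ++co)
    Gy.row(co) = vectorise(gy.slice(co)).t();
  mat Wm(const_cast<double *>(w.memptr()), kh * kw * Cin, Cout, false, true);
  mat gW = K * Gy.t();           // (kh*kw*Cin) x Cout
  vec gb = sum(Gy, 1);
  mat Kg = Wm * Gy;              // (kh*kw*Cin) x (Ho*Wo)
  cube gx(xdim[0], xdim[1], Cin, fill::zeros);
  col2im_add(Kg, kh, kw, stride, pad, Ho, Wo, gx);
  return List::create(Named("gx") = gx, Named("gw") = gW, Named("gb") = gb);
}

// ---- marching tetrahedra ---------------------------------------------------

static const int TETS[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
// cube corner offsets (di, dj, dk) along the three array dimensions
static const int CNR[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                              {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

static inline void interp_pt(const double *pa, const double *pb, double fa,
                             double fb, double iso, double *out) {
  double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
  for (int d = 0; d < 3; ++d) out[d] = pa[d] + t * (pb[d] - pa[d]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
  double u[3], v[3], w[3];
  for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Iso-surface area of a scalar volume at level `iso` by marching tetrahedra
// (6-tet cube decomposition). `spacing` holds the physical step along each of
// the three array dimensions, so anisotropic voxels are handled exactly.
// [[Rcpp::export]]
double mt_surface_area_cpp(const arma::cube &v, const arma::vec &spacing,
                           double iso) {
  const int N1 = v.n_rows, N2 = v.n_cols, N3 = v.n_slices;
  double total = 0.0;
  double pts[8][3], f[8];
  for (int k = 0; k + 1 < N3; ++k) {
    for (int j = 0; j + 1 < N2; ++j) {
      for (int i = 0; i + 1 < N1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          f[c] = v(i + CNR[c][0], j + CNR[c][1], k + CNR[c][2]);
          (f[c] >= iso ? any_in : any_out) = true;
          pts[c][0] = (i + CNR[c][0]) * spacing[0];
          pts[c][1] = (j + CNR[c][1]) * spacing[1];
          pts[c][2] = (k + CNR[c][2]) * spacing[2];
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int a = 0; a < 4; ++a) {
            if (f[idx[a]] >= iso) in[nin++] = idx[a];
            else out[nout++] = idx[a];
          }
          if (nin == 0 || nin == 4) continue;
          double q[4][3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int *oth = (nin == 1) ? out : in;
            for (int a = 0; a < 3; ++a)
              interp_pt(pts[apex], pts[oth[a]], f[apex], f[oth[a]], iso, q[a]);
            total += tri_area(q[0], q[1], q[2]);
          } else {  // 2 in, 2 out -> quad
            interp_pt(pts[in[0]], pts[out[0]], f[in[0]], f[out[0]], iso, q[0]);
            interp_pt(pts[in[0]], pts[out[1]], f[in[0]], f[out[1]], iso, q[1]);
            interp_pt(pts[in[1]], pts[out[1]], f[in[1]], f[out[1]], iso, q[2]);
            interp_pt(pts[in[1]], pts[out[0]], f[in[1]], f[out[0]], iso, q[3]);
            total += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
    }
  }
  return total;
}
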