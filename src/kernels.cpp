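// Compiled primitives for the U-Net family: 2D/3D convolution, 2x2 stride-2
// transposed convolution and 2x2 max-pooling, each with an explicit backward
// pass. Array layout follows R column-major order: activations are H x W x C
// (2D) or H x W x T x C (temporal); weights arrive reshaped to K x Cout
// matrices whose row index runs over (ky, kx, cin) (or (ky, kx, kt, cin))
// fastest-first, i.e. the column-major flattening of the R weight array.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// Gather im2col in N x K layout (N = H*W output pixels, K = kh*kw*C taps):
// writes are contiguous down each column, K index runs (ky, kx, cin)
// fastest-first to match the column-major flattening of R weight arrays.
static mat im2col2d_nk(const double* xp, const int H, const int W,
                       const int C, const long chan_stride,
                       const int kh, const int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const long N = (long)H * W;
  mat cols(N, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * chan_stride;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        double* col = cols.colptr(di + kh * (dj + kw * c));
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (long)H * sj;
          double* dst = col + (long)H * j;
          const int i0 = std::max(0, ph - di), i1 = H + std::min(0, ph - di);
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di - ph];
        }
      }
    }
  }
  return cols;
}

static mat im2col2d(const cube& x, const int kh, const int kw) {
  return im2col2d_nk(x.memptr(), x.n_rows, x.n_cols, x.n_slices,
                     (long)x.n_rows * x.n_cols, kh, kw);
}

// Scatter-add transpose of im2col2d (N x K layout).
static void col2im2d_ptr(const mat& cols, double* dxp, const int H,
                         const int W, const int C, const long chan_stride,
                         const int kh, const int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dxp + c * chan_stride;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double* col = cols.colptr(di + kh * (dj + kw * c));
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (long)H * sj;
          const double* src = col + (long)H * j;
          const int i0 = std::max(0, ph - di), i1 = H + std::min(0, ph - di);
          for (int i = i0; i < i1; ++i) dst[i + di - ph] += src[i];
        }
      }
    }
  }
}

static void col2im2d(const mat& cols, cube& dx, const int kh, const int kw) {
  col2im2d_ptr(cols, dx.memptr(), dx.n_rows, dx.n_cols, dx.n_slices,
               (long)dx.n_rows * dx.n_cols, kh, kw);
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat cols = im2col2d(x, kh, kw);    // N x K
  cube out(H, W, cout);
  mat y(out.memptr(), (long)H * W, cout, false, true);
  y = cols * w;                      // N x cout, written in place
  y.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  const mat dy_nk(const_cast<double*>(dy.memptr()), (long)H * W, cout,
                  false, true);
  mat cols = im2col2d(x, kh, kw);
  vec db = arma::sum(dy_nk, 0).t();
  mat dw = cols.t() * dy_nk;         // K x cout
  mat dcols = dy_nk * w.t();         // N x K
  cube dx(H, W, cin, arma::fill::zeros);
  col2im2d(dcols, dx, kh, kw);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Forward that also returns the im2col matrix so training can reuse it in
// the backward pass instead of regathering.
// [[Rcpp::export]]
Rcpp::List conv2d_fwd_train_cpp(const arma::cube& x, const arma::mat& w,
                                const arma::vec& b, const int kh,
                                const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat cols = im2col2d(x, kh, kw);
  cube out(H, W, cout);
  mat y(out.memptr(), (long)H * W, cout, false, true);
  y = cols * w;
  y.each_row() += b.t();
  return List::create(_["y"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cols_cpp(const arma::mat& cols, const arma::mat& w,
                               const arma::cube& dy, const int cin,
                               const int kh, const int kw) {
  const int H = dy.n_rows, W = dy.n_cols, cout = dy.n_slices;
  const mat dy_nk(const_cast<double*>(dy.memptr()), (long)H * W, cout,
                  false, true);
  vec db = arma::sum(dy_nk, 0).t();
  mat dw = cols.t() * dy_nk;
  mat dcols = dy_nk * w.t();
  cube dx(H, W, cin, arma::fill::zeros);
  col2im2d(dcols, dx, kh, kw);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);        // 0..3 = (di, dj) offset di + 2*dj
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; arg = di + 2 * dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dy, const arma::icube& idx,
                            const int H, const int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, c);
        dx(2 * i + a % 2, 2 * j + a / 2, c) += dy(i, j, c);
      }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling).
// w: (2*2*cin) x cout, row index di + 2*(dj + 2*ci).
// [[Rcpp::export]]
arma::cube tconv2_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = w.n_cols;
  mat xm(H * W, cin);
  for (int c = 0; c < cin; ++c) xm.col(c) = arma::vectorise(x.slice(c));
  cube y(2 * H, 2 * W, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b(co));
  for (int dj = 0; dj < 2; ++dj) {
    for (int di = 0; di < 2; ++di) {
      mat wk(cin, cout);             // rows ci for fixed (di, dj)
      for (int ci = 0; ci < cin; ++ci)
        wk.row(ci) = w.row(di + 2 * (dj + 2 * ci));
      mat yb = xm * wk;              // (H*W) x cout
      for (int co = 0; co < cout; ++co) {
        mat blk = arma::reshape(yb.col(co), H, W);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + di, 2 * j + dj, co) += blk(i, j);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List tconv2_bwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  mat xm(H * W, cin);
  for (int c = 0; c < cin; ++c) xm.col(c) = arma::vectorise(x.slice(c));
  mat dw(4 * cin, cout, arma::fill::zeros);
  vec db(cout, arma::fill::zeros);
  cube dx(H, W, cin, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) db(co) = arma::accu(dy.slice(co));
  for (int dj = 0; dj < 2; ++dj) {
    for (int di = 0; di < 2; ++di) {
      mat dyb(H * W, cout);
      for (int co = 0; co < cout; ++co) {
        mat blk(H, W);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            blk(i, j) = dy(2 * i + di, 2 * j + dj, co);
        dyb.col(co) = arma::vectorise(blk);
      }
      mat dwk = xm.t() * dyb;        // cin x cout
      for (int ci = 0; ci < cin; ++ci)
        dw.row(di + 2 * (dj + 2 * ci)) += dwk.row(ci);
      mat wk(cin, cout);
      for (int ci = 0; ci < cin; ++ci)
        wk.row(ci) = w.row(di + 2 * (dj + 2 * ci));
      mat dxb = dyb * wk.t();        // (H*W) x cin
      for (int ci = 0; ci < cin; ++ci)
        dx.slice(ci) += arma::reshape(dxb.col(ci), H, W);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- 3D convolution, kernel 3x3x3, same padding, stride 1 ----------------
// x: H x W x T x C flattened column-major in an Rcpp NumericVector with dim.
// Implemented frame-by-frame: the output at frame t sums 2D correlations of
// frames t-1, t, t+1 (zero-padded in time).
// w: (3*3*3*cin) x cout, row index di + 3*(dj + 3*(dk + 3*ci)).
// [[Rcpp::export]]
Rcpp::NumericVector conv3d_fwd_cpp(const Rcpp::NumericVector& x,
                                   const arma::mat& w, const arma::vec& b,
                                   const int H, const int W, const int T,
                                   const int cin) {
  const int cout = w.n_cols;
  const long HW = (long)H * W;
  const long chan_stride = HW * T;   // stride between channels
  NumericVector out(HW * T * (long)cout);
  out.attr("dim") = IntegerVector::create(H, W, T, cout);
  double* op = REAL(out);
  const double* xp = REAL(x);
  // weight slices per time offset dk: rows (di,dj,ci) -> 9*cin x cout
  std::vector<mat> wk(3, mat(9 * cin, cout));
  for (int dk = 0; dk < 3; ++dk)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          wk[dk].row(di + 3 * (dj + 3 * ci)) =
            w.row(di + 3 * (dj + 3 * (dk + 3 * ci)));
  for (int t = 0; t < T; ++t) {
    mat acc(HW, cout, arma::fill::zeros);
    for (int dk = 0; dk < 3; ++dk) {
      const int st = t + dk - 1;
      if (st < 0 || st >= T) continue;
      // gather frame st across channels: channel stride = chan_stride
      mat cols = im2col2d_nk(xp + (long)st * HW, H, W, cin, chan_stride, 3, 3);
      acc += cols * wk[dk];
    }
    acc.each_row() += b.t();
    for (int co = 0; co < cout; ++co)
      std::memcpy(op + (long)t * HW + (long)co * chan_stride,
                  acc.colptr(co), sizeof(double) * HW);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd_cpp(const Rcpp::NumericVector& x, const arma::mat& w,
                          const Rcpp::NumericVector& dy, const int H,
                          const int W, const int T, const int cin,
                          const int cout) {
  const long HW = (long)H * W;
  const long cs_in = HW * T, cs_out = HW * T;
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  NumericVector dxv(HW * T * (long)cin);
  dxv.attr("dim") = IntegerVector::create(H, W, T, cin);
  double* dxp = REAL(dxv);
  mat dw(27 * cin, cout, arma::fill::zeros);
  vec db(cout, arma::fill::zeros);
  std::vector<mat> wk(3, mat(9 * cin, cout));
  for (int dk = 0; dk < 3; ++dk)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          wk[dk].row(di + 3 * (dj + 3 * ci)) =
            w.row(di + 3 * (dj + 3 * (dk + 3 * ci)));
  std::vector<mat> dwk(3, mat(9 * cin, cout, arma::fill::zeros));
  for (int t = 0; t < T; ++t) {
    mat dy_nk(HW, cout);
    for (int co = 0; co < cout; ++co)
      std::memcpy(dy_nk.colptr(co), dyp + (long)t * HW + (long)co * cs_out,
                  sizeof(double) * HW);
    db += arma::sum(dy_nk, 0).t();
    for (int dk = 0; dk < 3; ++dk) {
      const int st = t + dk - 1;
      if (st < 0 || st >= T) continue;
      mat cols = im2col2d_nk(xp + (long)st * HW, H, W, cin, cs_in, 3, 3);
      dwk[dk] += cols.t() * dy_nk;
      mat dcols = dy_nk * wk[dk].t();   // HW x (9*cin)
      col2im2d_ptr(dcols, dxp + (long)st * HW, H, W, cin, cs_in, 3, 3);
    }
  }
  for (int dk = 0; dk < 3; ++dk)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          dw.row(di + 3 * (dj + 3 * (dk + 3 * ci))) =
            dwk[dk].row(di + 3 * (dj + 3 * ci));
  return List::create(_["dx"] = dxv, _["dw"] = dw, _["db"] = db);
}
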