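// 2-D convolution with "same" padding via im2col + GEMM.
// Layout conventions (match R's column-major arrays):
//   feature map  : cube H x W x C            (rows, cols, slices)
//   kernel       : array (kh, kw, Cin, Cout) flattened column-major into a
//                  (kh*kw*Cin) x Cout matrix, so patch column index is
//                  ki + kh*(kj + kw*c).
// Dilation d spaces kernel taps d pixels apart; padding = ((k-1)*d)/2 per
// axis keeps output spatial dims equal to input dims for odd kernels.
// Work is chunked over output columns so the patch matrix stays small at
// 224x224 with wide channel counts.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void im2col_chunk(const cube& x, mat& P, int c0, int cb,
                         int kh, int kw, int dh, int dw, int ph, int pw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  P.zeros(H * cb, kh * kw * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const int di = ki * dh - ph;        // input row offset
        const int i_lo = std::max(0, -di);
        const int i_hi = std::min(H, H - di);
        for (int j = 0; j < cb; ++j) {
          const int jj = c0 + j + kj * dw - pw;
          if (jj < 0 || jj >= W) continue;
          double* dst = P.colptr(col) + H * j;
          const double* src = x.slice_colptr(c, jj);
          for (int i = i_lo; i < i_hi; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& wmat,
                          const arma::vec& bias, int kh, int kw,
                          int dh, int dw, int chunk = 48) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = wmat.n_cols;
  const int ph = ((kh - 1) * dh) / 2, pw = ((kw - 1) * dw) / 2;
  cube y(H, W, cout);
  mat P;
  for (int c0 = 0; c0 < W; c0 += chunk) {
    const int cb = std::min(chunk, W - c0);
    im2col_chunk(x, P, c0, cb, kh, kw, dh, dw, ph, pw);
    mat Yc = P * wmat;                       // (H*cb) x cout
    Yc.each_row() += bias.t();
    for (int oc = 0; oc < cout; ++oc)
      std::memcpy(y.slice_colptr(oc, c0), Yc.colptr(oc),
                  sizeof(double) * H * cb);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::cube& gy,
                          const arma::mat& wmat, int kh, int kw,
                          int dh, int dw, int chunk = 48) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int cout = wmat.n_cols;
  const int ph = ((kh - 1) * dh) / 2, pw = ((kw - 1) * dw) / 2;
  cube gx(H, W, Cin, fill::zeros);
  mat gW(wmat.n_rows, cout, fill::zeros);
  vec gb(cout, fill::zeros);
  mat P, Gc(H, cout);
  for (int c0 = 0; c0 < W; c0 += chunk) {
    const int cb = std::min(chunk, W - c0);
    im2col_chunk(x, P, c0, cb, kh, kw, dh, dw, ph, pw);
    mat Gy(H * cb, cout);
    for (int oc = 0; oc < cout; ++oc)
      std::memcpy(Gy.colptr(oc), gy.slice_colptr(oc, c0),
                  sizeof(double) * H * cb);
    gW += P.t() * Gy;
    gb += sum(Gy, 0).t();
    mat Gp = Gy * wmat.t();                  // (H*cb) x (kh*kw*Cin)
    // col2im scatter-add
    for (int c = 0; c < Cin; ++c) {
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int col = ki + kh * (kj + kw * c);
          const int di = ki * dh - ph;
          const int i_lo = std::max(0, -di);
          const int i_hi = std::min(H, H - di);
          for (int j = 0; j < cb; ++j) {
            const int jj = c0 + j + kj * dw - pw;
            if (jj < 0 || jj >= W) continue;
            const double* src = Gp.colptr(col) + H * j;
            double* dst = gx.slice_colptr(c, jj);
            for (int i = i_lo; i < i_hi; ++i) dst[i + di] += src[i];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gW,
                            Rcpp::Named("gb") = gb);
}

// Batched wrappers: x is an (H, W, Cin, N) array; samples are processed as
// cube views over the same memory, avoiding per-sample copies in R.

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd_batch_cpp(const Rcpp::NumericVector& x,
                                         const arma::mat& wmat,
                                         const arma::vec& bias,
                                         int kh, int kw, int dh, int dw,
                                         int chunk = 48) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int cout = wmat.n_cols;
  Rcpp::NumericVector out(Rcpp::no_init((R_xlen_t)H * W * cout * N));
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, cout, N);
  for (int n = 0; n < N; ++n) {
    const cube xs(const_cast<double*>(x.begin()) + (R_xlen_t)n * H * W * Cin,
                  H, W, Cin, false, true);
    cube y = conv2d_fwd_cpp(xs, wmat, bias, kh, kw, dh, dw, chunk);
    std::memcpy(out.begin() + (R_xlen_t)n * H * W * cout, y.memptr(),
                sizeof(double) * H * W * cout);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_batch_cpp(const Rcpp::NumericVector& x,
                                const Rcpp::NumericVector& gy,
                                const arma::mat& wmat,
                                int kh, int kw, int dh, int dw,
                                int chunk = 48) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int cout = wmat.n_cols;
  Rcpp::NumericVector gx(Rcpp::no_init((R_xlen_t)H * W * Cin * N));
  gx.attr("dim") = xd;
  mat gW(wmat.n_rows, cout, fill::zeros);
  vec gb(cout, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const cube xs(const_cast<double*>(x.begin()) + (R_xlen_t)n * H * W * Cin,
                  H, W, Cin, false, true);
    const cube gys(const_cast<double*>(gy.begin()) +
                   (R_xlen_t)n * H * W * cout, H, W, cout, false, true);
    Rcpp::List r = conv2d_bwd_cpp(xs, gys, wmat, kh, kw, dh, dw, chunk);
    arma::cube gxs = r["gx"];
    std::memcpy(gx.begin() + (R_xlen_t)n * H * W * Cin, gxs.memptr(),
                sizeof(double) * H * W * Cin);
    gW += Rcpp::as<arma::mat>(r["gw"]);
    gb += Rcpp::as<arma::vec>(r["gb"]);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gW,
                            Rcpp::Named("gb") = gb);
}
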