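// 2-D convolution forward/backward via im2col + GEMM.
//
// Images are column-major H x W x C arrays (R array layout). Filters are
// stored as a (k*k*Cin) x Cout matrix whose rows are ordered
// (ki, kj, c) -> ki + kj*k + c*k*k, matching the im2col column order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Ho * (arma::uword)Wo, (arma::uword)k * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& slice = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jsrc = jo * stride - pad + kj;
          if (jsrc < 0 || jsrc >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int isrc = io * stride - pad + ki;
            if (isrc < 0 || isrc >= H) continue;
            cols(io + (arma::uword)jo * Ho, col) = slice(isrc, jsrc);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List cpp_conv_forward(NumericVector x, NumericMatrix Wmat, NumericVector b,
                      int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::cube xc(x.begin(), H, W, C, false);
  arma::mat Wm(Wmat.begin(), Wmat.nrow(), Wmat.ncol(), false);
  arma::mat cols = im2col(xc, k, stride, pad, Ho, Wo);
  arma::mat out = cols * Wm;
  out.each_row() += arma::rowvec(b.begin(), b.size(), false);
  NumericVector out_r(out.begin(), out.end());
  out_r.attr("dim") = IntegerVector::create(Ho, Wo, (int)Wm.n_cols);
  NumericMatrix cols_r(cols.n_rows, cols.n_cols, cols.begin());
  return List::create(_["out"] = out_r, _["cols"] = cols_r);
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericMatrix cols, NumericMatrix Wmat,
                       NumericVector dout, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int Cout = Wmat.ncol();
  arma::mat colsm(cols.begin(), cols.nrow(), cols.ncol(), false);
  arma::mat Wm(Wmat.begin(), Wmat.nrow(), Wmat.ncol(), false);
  arma::mat Do(dout.begin(), (arma::uword)Ho * Wo, Cout, false);
  arma::mat dW = colsm.t() * Do;
  arma::rowvec db = arma::sum(Do, 0);
  arma::mat dcols = Do * Wm.t();
  // col2im: scatter-add dcols back onto the input grid
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& slice = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jsrc = jo * stride - pad + kj;
          if (jsrc < 0 || jsrc >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int isrc = io * stride - pad + ki;
            if (isrc < 0 || isrc >= H) continue;
            slice(isrc, jsrc) += dcols(io + (arma::uword)jo * Ho, col);
          }
        }
      }
    }
  }
  NumericVector dx_r(dx.begin(), dx.end());
  dx_r.attr("dim") = IntegerVector::create(H, W, C);
  NumericMatrix dW_r(dW.n_rows, dW.n_cols, dW.begin());
  NumericVector db_r(db.begin(), db.end());
  return List::create(_["dx"] = dx_r, _["dW"] = dW_r, _["db"] = db_r);
}
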