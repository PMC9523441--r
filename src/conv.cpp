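// im2col-based 2-D convolution and transposed convolution with analytic
// gradients. Feature maps are H x W x C cubes (column-major, matching R
// arrays); convolution weights are (kh*kw*Cin) x Cout matrices with patch
// index q = c*kh*kw + di*kw + dj; transposed-convolution weights are
// (kh*kw*Cout) x Cin (the adjoint layout). All loops are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// gather patches: rows = Hout*Wout (col-major over output positions),
// cols = kh*kw*C
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int ho, int wo) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  mat col(ho * wo, kh * kw * c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int q = ch * kh * kw + di * kw + dj;
        for (int j = 0; j < wo; ++j) {
          const int jj = j * stride + dj - pad;
          if (jj < 0 || jj >= w) continue;
          for (int i = 0; i < ho; ++i) {
            const int ii = i * stride + di - pad;
            if (ii < 0 || ii >= h) continue;
            col(i + j * ho, q) = x(ii, jj, ch);
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col: scatter-add patch gradients back onto the input lattice
static cube col2im(const mat& col, int h, int w, int c, int kh, int kw,
                   int stride, int pad, int ho, int wo) {
  cube x(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int q = ch * kh * kw + di * kw + dj;
        for (int j = 0; j < wo; ++j) {
          const int jj = j * stride + dj - pad;
          if (jj < 0 || jj >= w) continue;
          for (int i = 0; i < ho; ++i) {
            const int ii = i * stride + di - pad;
            if (ii < 0 || ii >= h) continue;
            x(ii, jj, ch) += col(i + j * ho, q);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int kh, int kw,
                              int stride, int pad) {
  const int ho = out_size(x.n_rows, kh, stride, pad);
  const int wo = out_size(x.n_cols, kw, stride, pad);
  const int cout = w.n_cols;
  mat col = im2col(x, kh, kw, stride, pad, ho, wo);
  mat out = col * w;
  out.each_row() += b.t();
  cube y(ho, wo, cout);
  for (int c = 0; c < cout; ++c) {
    y.slice(c) = reshape(out.col(c), ho, wo);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& gout, int kh, int kw,
                               int stride, int pad) {
  const int ho = gout.n_rows, wo = gout.n_cols, cout = gout.n_slices;
  mat gmat(ho * wo, cout);
  for (int c = 0; c < cout; ++c) gmat.col(c) = vectorise(gout.slice(c));
  mat col = im2col(x, kh, kw, stride, pad, ho, wo);
  mat gw = col.t() * gmat;
  vec gb = sum(gmat, 0).t();
  mat gcol = gmat * w.t();
  cube gx = col2im(gcol, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, pad,
                   ho, wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// transposed convolution: x (H, W, Cin) -> y (Hy, Wy, Cout) with
// Hy = (H - 1) * stride - 2 * pad + kh; the forward pass is the adjoint of a
// stride-s convolution from y back to x
// [[Rcpp::export]]
arma::cube cpp_convt2d_forward(const arma::cube& x, const arma::mat& w,
                               const arma::vec& b, int kh, int kw,
                               int stride, int pad) {
  const int h = x.n_rows, wd = x.n_cols, cin = x.n_slices;
  const int cout = w.n_rows / (kh * kw);
  const int hy = (h - 1) * stride - 2 * pad + kh;
  const int wy = (wd - 1) * stride - 2 * pad + kw;
  mat xmat(h * wd, cin);
  for (int c = 0; c < cin; ++c) xmat.col(c) = vectorise(x.slice(c));
  mat gcol = xmat * w.t();  // (H*W) x (kh*kw*Cout)
  cube y = col2im(gcol, hy, wy, cout, kh, kw, stride, pad, h, wd);
  for (int c = 0; c < cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt2d_backward(const arma::cube& x, const arma::mat& w,
                                const arma::cube& gy, int kh, int kw,
                                int stride, int pad) {
  const int h = x.n_rows, wd = x.n_cols, cin = x.n_slices;
  mat xmat(h * wd, cin);
  for (int c = 0; c < cin; ++c) xmat.col(c) = vectorise(x.slice(c));
  mat col = im2col(gy, kh, kw, stride, pad, h, wd);  // (H*W) x (kh*kw*Cout)
  mat gxmat = col * w;                               // (H*W) x Cin
  cube gx(h, wd, cin);
  for (int c = 0; c < cin; ++c) gx.slice(c) = reshape(gxmat.col(c), h, wd);
  mat gw = col.t() * xmat;  // (kh*kw*Cout) x Cin
  vec gb(gy.n_slices);
  for (unsigned int c = 0; c < gy.n_slices; ++c) gb(c) = accu(gy.slice(c));
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
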