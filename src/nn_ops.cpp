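// Low-level kernels for the fully-convolutional segmentation networks:
// same-padded 2-D convolution (im2col + GEMM), 2x2 max pooling and 2x
// nearest-neighbour upsampling, each with its reverse-mode companion.
// Tensors are arma::cube (rows = image rows, cols = image cols, slices =
// channels), matching R arrays of dim (H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for odd k with zero same-padding: output (k*k*Cin) x (H*W),
// column index = i + H*j for output pixel (i, j).
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int row = c * k * k + (dj + p) * k + (di + p);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            cols(row, i + H * j) = xc(i + di, js);
        }
      }
    }
  }
  return cols;
}

// scatter-add of a (k*k*Cin) x (H*W) matrix back onto an (H, W, Cin) cube
static cube col2im(const mat& cols, const int k, const int H, const int W,
                   const int C) {
  const int p = k / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int row = c * k * k + (dj + p) * k + (di + p);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            xc(i + di, js) += cols(row, i + H * j);
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat cols = im2col(x, k);
  mat y = w.t() * cols;          // (Cout x H*W)
  y.each_col() += b;
  cube out(H, W, cout);
  for (int c = 0; c < cout; ++c)
    out.slice(c) = reshape(y.row(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = gy.n_slices;
  mat gym(cout, H * W);
  for (int c = 0; c < cout; ++c)
    gym.row(c) = reshape(gy.slice(c), 1, H * W);
  mat cols = im2col(x, k);
  mat gw = cols * gym.t();                 // (k*k*Cin x Cout)
  vec gb = sum(gym, 1);
  cube gx = col2im(w * gym, k, H, W, cin); // (k*k*Cin x H*W) scattered
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List nn_pool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx(Ho * Wo * C);   // 0-based linear index into x
  int t = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = xc(bi, bj); int ai = bi, aj = bj;
        if (xc(bi + 1, bj) > best) { best = xc(bi + 1, bj); ai = bi + 1; }
        if (xc(bi, bj + 1) > best) { best = xc(bi, bj + 1); ai = bi; aj = bj + 1; }
        if (xc(bi + 1, bj + 1) > best) { best = xc(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
        y(i, j, c) = best;
        idx[c * Ho * Wo + j * Ho + i] = c * H * W + aj * H + ai;
        ++t;
      }
    }
  }
  (void)t;
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_pool2_bwd(const Rcpp::IntegerVector& idx, const arma::cube& gy,
                        const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int n = idx.size();
  double* gxm = gx.memptr();
  const double* gym = gy.memptr();
  for (int t = 0; t < n; ++t) gxm[idx[t]] += gym[t];
  return gx;
}

// [[Rcpp::export]]
arma::cube nn_up2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_up2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}
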