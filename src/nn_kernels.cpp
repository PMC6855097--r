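// Low-level batched kernels for the network engine.
//
// Feature maps are stored as (B*H*W) x C matrices: row b*H*W + y*W + x holds
// pixel (y, x) of image b (0-based, row-major within an image), one column per
// channel.  3x3 convolutions use zero padding of 1 so spatial size is
// preserved; weights are (9*C_in) x C_out with row index k*C_in + c for
// offset k = (dy+1)*3 + (dx+1), dy,dx in {-1,0,1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col3(const arma::mat& X, arma::mat& cols,
                    const int off, const int H, const int W) {
  const int C = X.n_cols;
  cols.zeros();
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    const int len = W - std::abs(dx);
    const int dst_x0 = std::max(0, -dx), src_x0 = std::max(0, dx);
    for (int c = 0; c < C; ++c) {
      const double* src = X.colptr(c) + off;
      double* dst = cols.colptr(k * C + c);
      for (int y = 0; y < H; ++y) {
        const int sy = y + dy;
        if (sy < 0 || sy >= H) continue;
        std::memcpy(dst + y * W + dst_x0, src + sy * W + src_x0,
                    len * sizeof(double));
      }
    }
  }
}

// accumulate columns back onto the padded image (transpose of im2col3)
static void col2im3(const arma::mat& cols, arma::mat& dX,
                    const int off, const int H, const int W) {
  const int C = dX.n_cols;
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    const int len = W - std::abs(dx);
    const int dst_x0 = std::max(0, -dx), src_x0 = std::max(0, dx);
    for (int c = 0; c < C; ++c) {
      double* acc = dX.colptr(c) + off;
      const double* src = cols.colptr(k * C + c);
      for (int y = 0; y < H; ++y) {
        const int sy = y + dy;
        if (sy < 0 || sy >= H) continue;
        double* a = acc + sy * W + src_x0;
        const double* s = src + y * W + dst_x0;
        for (int i = 0; i < len; ++i) a[i] += s[i];
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::mat conv3_forward(const arma::mat& X, const arma::mat& Wt,
                        const arma::rowvec& bias,
                        const int B, const int H, const int W) {
  const int HW = H * W, C = X.n_cols, K = Wt.n_cols;
  if ((int)Wt.n_rows != 9 * C)
    stop("weight rows (%d) != 9 x input channels (%d)", (int)Wt.n_rows, 9 * C);
  arma::mat Y(B * HW, K);
  arma::mat cols(HW, 9 * C);
  for (int b = 0; b < B; ++b) {
    im2col3(X, cols, b * HW, H, W);
    Y.rows(b * HW, (b + 1) * HW - 1) = cols * Wt;
  }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::mat& X, const arma::mat& Wt,
                    const arma::mat& dY,
                    const int B, const int H, const int W) {
  const int HW = H * W, C = X.n_cols;
  arma::mat dW(arma::size(Wt), arma::fill::zeros);
  arma::mat dX(arma::size(X), arma::fill::zeros);
  arma::mat cols(HW, 9 * C);
  for (int b = 0; b < B; ++b) {
    const arma::mat dYb = dY.rows(b * HW, (b + 1) * HW - 1);
    im2col3(X, cols, b * HW, H, W);
    dW += cols.t() * dYb;
    const arma::mat dcols = dYb * Wt.t();
    col2im3(dcols, dX, b * HW, H, W);
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const arma::mat& X,
                      const int B, const int H, const int W) {
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2, C = X.n_cols;
  arma::mat Y(B * Ho * Wo, C);
  arma::umat idx(B * Ho * Wo, C);  // 1-based row index of the max
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* out = Y.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int ioff = b * H * W, ooff = b * Ho * Wo;
      for (int y = 0; y < Ho; ++y) {
        for (int x = 0; x < Wo; ++x) {
          const int r0 = ioff + (2 * y) * W + 2 * x;
          int best = r0;
          double v = src[r0];
          if (src[r0 + 1] > v) { v = src[r0 + 1]; best = r0 + 1; }
          if (src[r0 + W] > v) { v = src[r0 + W]; best = r0 + W; }
          if (src[r0 + W + 1] > v) { v = src[r0 + W + 1]; best = r0 + W + 1; }
          out[ooff + y * Wo + x] = v;
          ix[ooff + y * Wo + x] = best + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::mat maxpool2_backward(const arma::mat& dY, const arma::umat& idx,
                            const int n_in_rows) {
  const int C = dY.n_cols;
  arma::mat dX(n_in_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* acc = dX.colptr(c);
    const double* g = dY.colptr(c);
    const arma::uword* ix = idx.colptr(c);
    for (arma::uword i = 0; i < dY.n_rows; ++i) acc[ix[i] - 1] += g[i];
  }
  return dX;
}

// [[Rcpp::export(name = ".bn_col_stats")]]
List bn_col_stats(const arma::mat& X) {
  arma::rowvec m = arma::mean(X, 0);
  arma::rowvec v = arma::mean(arma::square(X.each_row() - m), 0);
  return List::create(_["mean"] = m, _["var"] = v);
}

// [[Rcpp::export(name = ".bn_forward")]]
List bn_forward_k(const arma::mat& X, const arma::vec& gamma,
                  const arma::vec& beta, const arma::vec& mean,
                  const arma::vec& var, const double eps) {
  arma::rowvec m = mean.t(), g = gamma.t(), b = beta.t();
  arma::rowvec invstd = 1.0 / arma::sqrt(var.t() + eps);
  arma::mat xhat = X.each_row() - m;
  xhat.each_row() %= invstd;
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_k(const arma::mat& dY, const arma::mat& xhat,
                   const arma::vec& gamma, const arma::rowvec& invstd,
                   const bool train_mode) {
  const double n = dY.n_rows;
  arma::rowvec dgamma = arma::sum(dY % xhat, 0);
  arma::rowvec dbeta = arma::sum(dY, 0);
  arma::mat dxhat = dY.each_row() % gamma.t();
  arma::mat dX;
  if (train_mode) {
    arma::rowvec s1 = arma::sum(dxhat, 0);
    arma::rowvec s2 = arma::sum(dxhat % xhat, 0);
    dX = n * dxhat;
    dX.each_row() -= s1;
    dX -= xhat.each_row() % s2;
    dX.each_row() %= invstd / n;
  } else {
    dX = dxhat.each_row() % invstd;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
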