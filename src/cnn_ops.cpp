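// Hot loops for the small convolutional classifier: 3x3 same-padding
// convolution (forward/backward, including the gradient with respect to the
// input, needed for saliency) and 2x2 max pooling. Activations are stored as
// (H*W*C) x B matrices with feature index h + H*w + H*W*c (column-major
// spatial layout, channels outermost).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3(const double* x, int H, int W, int C, arma::mat& col) {
  // col is (C*9) x (H*W); patch row index = c*9 + (dw+1)*3 + (dh+1)
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int r = c * 9 + (dw + 1) * 3 + (dh + 1);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) {
            col(r, h + (size_t)H * w) = xc[(h + dh) + (size_t)H * ws];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat nn_conv_fwd(const arma::mat& X, const arma::mat& Wt,
                      const arma::vec& bias, int H, int W) {
  int B = X.n_cols;
  int C = X.n_rows / (H * W);
  int Cout = Wt.n_rows;
  arma::mat Y(H * W * Cout, B);
  arma::mat col(C * 9, H * W);
  for (int b = 0; b < B; ++b) {
    im2col3(X.colptr(b), H, W, C, col);
    arma::mat yb = Wt * col;              // Cout x (H*W)
    yb.each_col() += bias;
    Y.col(b) = arma::vectorise(yb.t());   // h + H*w + H*W*cout
  }
  return Y;
}

// [[Rcpp::export]]
List nn_conv_bwd(const arma::mat& X, const arma::mat& Wt, const arma::mat& dY,
                 int H, int W, bool need_dx) {
  int B = X.n_cols;
  int C = X.n_rows / (H * W);
  int Cout = Wt.n_rows;
  arma::mat dW(Cout, C * 9, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dX;
  if (need_dx) dX.zeros(X.n_rows, B);
  arma::mat col(C * 9, H * W);
  for (int b = 0; b < B; ++b) {
    im2col3(X.colptr(b), H, W, C, col);
    // dY column -> (H*W) x Cout, transpose to Cout x (H*W)
    arma::mat g = arma::reshape(dY.col(b), H * W, Cout).t();
    dW += g * col.t();
    db += arma::sum(g, 1);
    if (need_dx) {
      arma::mat dcol = Wt.t() * g;        // (C*9) x (H*W)
      double* dx = dX.colptr(b);
      for (int c = 0; c < C; ++c) {
        double* dxc = dx + (size_t)c * H * W;
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            int r = c * 9 + (dw + 1) * 3 + (dh + 1);
            for (int w = 0; w < W; ++w) {
              int ws = w + dw;
              if (ws < 0 || ws >= W) continue;
              int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
              for (int h = h0; h < h1; ++h) {
                dxc[(h + dh) + (size_t)H * ws] += dcol(r, h + (size_t)H * w);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export]]
List nn_pool_fwd(const arma::mat& X, int H, int W) {
  int B = X.n_cols;
  int C = X.n_rows / (H * W);
  int Ho = H / 2, Wo = W / 2;
  arma::mat Y(Ho * Wo * C, B);
  arma::umat amax(Ho * Wo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* x = X.colptr(b);
    double* y = Y.colptr(b);
    arma::uword* am = amax.colptr(b);
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)c * H * W;
      size_t offo = (size_t)c * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = off + 2 * h + (size_t)H * (2 * w);
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          for (int k = 1; k < 4; ++k) if (x[cand[k]] > x[best]) best = cand[k];
          y[offo + h + (size_t)Ho * w] = x[best];
          am[offo + h + (size_t)Ho * w] = best;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat nn_pool_bwd(const arma::mat& dY, const arma::umat& amax, int in_len) {
  int B = dY.n_cols;
  arma::mat dX(in_len, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* dy = dY.colptr(b);
    const arma::uword* am = amax.colptr(b);
    double* dx = dX.colptr(b);
    for (size_t i = 0; i < dY.n_rows; ++i) dx[am[i]] += dy[i];
  }
  return dX;
}
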