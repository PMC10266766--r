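// 3D convolution ("same" padding, stride 1) and 2x max-pooling for the
// residue-environment representation network. Convolution is im2col + GEMM
// (Armadillo), sample by sample to keep memory flat.
//
// Array layout (R column-major): x has dim (C, D, H, W, N) with the channel
// index fastest. im2col rows are ordered channel-fastest, then kernel
// offsets (kd, kh, kw); conv weights are an (F x C*K^3) matrix using the
// same row order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col3d(const double* x, int C, int D, int H, int W,
                            int K, arma::mat& cols) {
  const int pad = (K - 1) / 2;
  // cols: (C*K^3) x (D*H*W)
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const int q = d + D * (h + H * w);
        double* colq = cols.colptr(q);
        int r = 0;
        for (int kw = 0; kw < K; ++kw) {
          const int sw = w + kw - pad;
          for (int kh = 0; kh < K; ++kh) {
            const int sh = h + kh - pad;
            for (int kd = 0; kd < K; ++kd) {
              const int sd = d + kd - pad;
              if (sd >= 0 && sd < D && sh >= 0 && sh < H &&
                  sw >= 0 && sw < W) {
                const double* src = x + C * (sd + D * (sh + H * (size_t)sw));
                for (int c = 0; c < C; ++c) colq[r + c] = src[c];
              } else {
                for (int c = 0; c < C; ++c) colq[r + c] = 0.0;
              }
              r += C;
            }
          }
        }
      }
    }
  }
}

static inline void col2im3d(const arma::mat& cols, int C, int D, int H,
                            int W, int K, double* x) {
  const int pad = (K - 1) / 2;
  std::fill(x, x + (size_t)C * D * H * W, 0.0);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const int q = d + D * (h + H * w);
        const double* colq = cols.colptr(q);
        int r = 0;
        for (int kw = 0; kw < K; ++kw) {
          const int sw = w + kw - pad;
          for (int kh = 0; kh < K; ++kh) {
            const int sh = h + kh - pad;
            for (int kd = 0; kd < K; ++kd) {
              const int sd = d + kd - pad;
              if (sd >= 0 && sd < D && sh >= 0 && sh < H &&
                  sw >= 0 && sw < W) {
                double* dst = x + C * (sd + D * (sh + H * (size_t)sw));
                for (int c = 0; c < C; ++c) dst[c] += colq[r + c];
              }
              r += C;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward(NumericVector x, IntegerVector dims,
                             NumericMatrix weight, NumericVector bias,
                             int K) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int F = weight.nrow();
  const size_t vox = (size_t)D * H * W;
  if ((size_t)weight.ncol() != (size_t)C * K * K * K)
    stop("conv weight shape mismatch");
  NumericVector out((size_t)F * vox * N);
  out.attr("dim") = IntegerVector::create(F, D, H, W, N);
  arma::mat Wm(weight.begin(), F, weight.ncol(), false);
  arma::vec b(bias.begin(), F, false);
  arma::mat cols(C * K * K * K, vox);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (size_t)C * vox * n, C, D, H, W, K, cols);
    arma::mat o(out.begin() + (size_t)F * vox * n, F, vox, false, true);
    o = Wm * cols;
    o.each_col() += b;
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_backward(NumericVector x, IntegerVector dims,
                     NumericMatrix weight, NumericVector dout, int K) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int F = weight.nrow();
  const size_t vox = (size_t)D * H * W;
  arma::mat Wm(weight.begin(), F, weight.ncol(), false);
  NumericVector dx((size_t)C * vox * N);
  dx.attr("dim") = dims;
  arma::mat dW(F, C * K * K * K, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat cols(C * K * K * K, vox);
  arma::mat dcols(C * K * K * K, vox);
  for (int n = 0; n < N; ++n) {
    arma::mat dOut(const_cast<double*>(dout.begin()) + (size_t)F * vox * n,
                   F, vox, false);
    im2col3d(x.begin() + (size_t)C * vox * n, C, D, H, W, K, cols);
    dW += dOut * cols.t();
    db += arma::sum(dOut, 1);
    dcols = Wm.t() * dOut;
    col2im3d(dcols, C, D, H, W, K, dx.begin() + (size_t)C * vox * n);
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export]]
List maxpool3d_forward(NumericVector x, IntegerVector dims, int k) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int Do = D / k, Ho = H / k, Wo = W / k;
  const size_t ovox = (size_t)C * Do * Ho * Wo;
  NumericVector out(ovox * N);
  out.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  IntegerVector argmax(ovox * N);  // 1-based linear index into x
  const size_t stride_n = (size_t)C * D * H * W;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + stride_n * n;
    size_t oi = ovox * n;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dd = 0; dd < Do; ++dd)
          for (int c = 0; c < C; ++c) {
            double best = -std::numeric_limits<double>::infinity();
            size_t besti = 0;
            for (int kw = 0; kw < k; ++kw)
              for (int kh = 0; kh < k; ++kh)
                for (int kd = 0; kd < k; ++kd) {
                  const size_t ix = c + (size_t)C *
                    ((dd * k + kd) + (size_t)D *
                     ((ho * k + kh) + (size_t)H * (wo * k + kw)));
                  if (xs[ix] > best) { best = xs[ix]; besti = ix; }
                }
            const size_t o = oi + c + (size_t)C *
              (dd + (size_t)Do * (ho + (size_t)Ho * wo));
            out[o] = best;
            argmax[o] = (int)(besti + stride_n * n) + 1;
          }
  }
  return List::create(_["out"] = out, _["argmax"] = argmax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward(NumericVector dout, IntegerVector argmax,
                                 double xlen, IntegerVector xdims) {
  NumericVector dx((size_t)xlen);
  dx.attr("dim") = xdims;
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  return dx;
}
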