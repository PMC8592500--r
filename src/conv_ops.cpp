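// Minimal conv-net primitives: im2col + GEMM convolutions in single
// precision. Tensor layout follows R's column-major arrays:
//   activations  (H, W, C, N)
//   conv weights (k, k, Cin, Cout)
// A transposed convolution is expressed in R as the data-gradient of a
// forward convolution, so only three conv kernels are needed here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fvec as_float(const NumericVector& x) {
  arma::fvec out(x.size());
  const double* p = x.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out[i] = (float)p[i];
  return out;
}

static NumericVector as_double(const arma::fvec& x, IntegerVector dim) {
  NumericVector out(x.n_elem);
  double* p = out.begin();
  for (arma::uword i = 0; i < x.n_elem; ++i) p[i] = (double)x[i];
  out.attr("dim") = dim;
  return out;
}

// Gather one image's patches into cols (k*k*C x Ho*Wo); out-of-range
// (padding) positions stay zero. Column index = ho + Ho*wo, row index
// = ki + k*kj + k*k*c, matching the flattened weight layout.
static void im2col(const float* x, int H, int W, int C, int k, int s,
                   int pb, int Ho, int Wo, arma::fmat& cols) {
  cols.zeros();
  float* cp = cols.memptr();
  const int nr = k * k * C;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - pb + kj;
          if (wi < 0 || wi >= W) continue;
          const float* src = xc + (size_t)H * wi;
          float* dst = cp + row + (size_t)nr * Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - pb + ki;
            if (hi >= 0 && hi < H) dst[(size_t)nr * ho] = src[hi];
          }
        }
      }
    }
  }
}

// Scatter-add of cols back into one image (adjoint of im2col).
static void col2im(const arma::fmat& cols, int H, int W, int C, int k,
                   int s, int pb, int Ho, int Wo, float* x) {
  const float* cp = cols.memptr();
  const int nr = k * k * C;
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - pb + kj;
          if (wi < 0 || wi >= W) continue;
          float* dst = xc + (size_t)H * wi;
          const float* src = cp + row + (size_t)nr * Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - pb + ki;
            if (hi >= 0 && hi < H) dst[hi] += src[(size_t)nr * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int pad, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv: weight Cin (%d) != input C (%d)", (int)wd[2], C);
  arma::fvec xf = as_float(x), wf = as_float(w);
  arma::fmat Wm(wf.memptr(), k * k * C, Cout, false, true);
  arma::fvec yf((size_t)Ho * Wo * Cout * N, arma::fill::zeros);
  arma::fmat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(xf.memptr() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Ho, Wo, cols);
    arma::fmat Y(yf.memptr() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    Y = cols.t() * Wm;
  }
  return as_double(yf, IntegerVector::create(Ho, Wo, Cout, N));
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericVector w,
                                int H, int W, int stride, int pad) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int k = wd[0], C = wd[2];
  if (wd[3] != Cout) stop("conv: weight Cout (%d) != dy C (%d)", (int)wd[3], Cout);
  arma::fvec yf = as_float(dy), wf = as_float(w);
  arma::fmat Wm(wf.memptr(), k * k * C, Cout, false, true);
  arma::fvec xf((size_t)H * W * C * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::fmat dY(yf.memptr() + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    arma::fmat cols = Wm * dY.t();
    col2im(cols, H, W, C, k, stride, pad, Ho, Wo,
           xf.memptr() + (size_t)H * W * C * n);
  }
  return as_double(xf, IntegerVector::create(H, W, C, N));
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_filter(NumericVector dy, NumericVector x,
                                  int k, int stride, int pad) {
  IntegerVector yd = dy.attr("dim"), xd = x.attr("dim");
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int H = xd[0], W = xd[1], C = xd[2];
  arma::fvec yf = as_float(dy), xf = as_float(x);
  arma::fmat dW(k * k * C, Cout, arma::fill::zeros);
  arma::fmat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(xf.memptr() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           Ho, Wo, cols);
    arma::fmat dY(yf.memptr() + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    dW += cols * dY;
  }
  arma::fvec dwv(dW.memptr(), dW.n_elem);
  return as_double(dwv, IntegerVector::create(k, k, C, Cout));
}

// 2x2 max pooling, stride 2. Returns pooled values and the flat (1-based)
// argmax index into the input array, used for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  NumericVector idx((size_t)Ho * Wo * C * N);  // double: may exceed 2^31
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * ((size_t)C * n + c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (size_t)(2 * ho) + (size_t)H * (2 * wo);
          double bv = xp[best];
          const int dh[3] = {1, 0, 1}, dw[3] = {0, 1, 1};
          for (int j = 0; j < 3; ++j) {
            size_t cand = base + (size_t)(2 * ho + dh[j]) +
                          (size_t)H * (2 * wo + dw[j]);
            if (xp[cand] > bv) { bv = xp[cand]; best = cand; }
          }
          yp[o] = bv;
          ip[o] = (double)(best + 1);
          ++o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, NumericVector idx,
                              int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  const double* dp = dy.begin();
  const double* ip = idx.begin();
  double* xp = dx.begin();
  const size_t M = dy.size();
  for (size_t i = 0; i < M; ++i) xp[(size_t)ip[i] - 1] += dp[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
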