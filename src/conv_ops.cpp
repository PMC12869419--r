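// Convolution primitives for the generator / discriminator stacks.
//
// Tensor layout everywhere: R arrays dim = c(H, W, C, N), column-major,
// so H varies fastest. Convolution weights: dim = c(k, k, Cin, Cout);
// transposed-convolution weights: dim = c(k, k, Cout, Cin).
// Forward/backward are implemented as im2col/col2im plus GEMM; col2im is
// the exact adjoint of im2col, so transposed convolution is the adjoint of
// the matching convolution and gradients are exact (finite-difference
// checked in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cols: (k*k*Cin) x (Ho*Wo), column index = ho + Ho*wo
static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, arma::mat& cols) {
  cols.zeros(k * k * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) { dst += k; continue; }
          const double* xcol = xc + (size_t)wi * H;
          const int hi0 = ho * stride - pad;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = hi0 + kh;
            if (hi >= 0 && hi < H) *dst = xcol[hi];
            ++dst;
          }
        }
      }
    }
  }
}

// adjoint of im2col_one: accumulate cols back into an H x W x C block
static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, double* x) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) { src += k; continue; }
          double* xcol = xc + (size_t)wi * H;
          const int hi0 = ho * stride - pad;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = hi0 + kh;
            if (hi >= 0 && hi < H) xcol[hi] += *src;
            ++src;
          }
        }
      }
    }
  }
}

static IntegerVector tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export(name = ".conv_out_size")]]
int conv_out_size(int H, int k, int stride, int pad) {
  int o = (H + 2 * pad - k) / stride + 1;
  if (o < 1) stop("convolution output size < 1");
  return o;
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  IntegerVector xd = tensor_dims(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k || Cin != C) stop("weight/input channel mismatch");
  const int Ho = conv_out_size(H, k, stride, pad);
  const int Wo = conv_out_size(W, k, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C,
               k, stride, pad, Ho, Wo, cols);
    arma::mat Yn = cols.t() * Wm;          // (Ho*Wo) x Cout
    Yn.each_row() += bv;
    std::copy(Yn.begin(), Yn.end(), y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
              int stride, int pad) {
  IntegerVector xd = tensor_dims(x), yd = tensor_dims(dy);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dW((size_t)k * k * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col_one(xn, H, W, C, k, stride, pad, Ho, Wo, cols);
    dW += cols * dYn;
    db += arma::sum(dYn, 0);
    arma::mat dcols = Wm * dYn.t();        // (k*k*Cin) x (Ho*Wo)
    col2im_one(dcols, H, W, C, k, stride, pad, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// transposed convolution: output spatial size (H-1)*stride - 2*pad + k
// [[Rcpp::export(name = ".tconv_fwd")]]
NumericVector tconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = tensor_dims(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  if (wd[3] != Cin) stop("weight/input channel mismatch");
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("transposed convolution output size < 1");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cout, Cin,
               false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 (size_t)H * W, Cin, false, true);
    arma::mat K = Wm * Xn.t();             // (k*k*Cout) x (H*W)
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    col2im_one(K, Ho, Wo, Cout, k, stride, pad, H, W, yn);
    for (int c = 0; c < Cout; ++c) {
      double* yc = yn + (size_t)c * Ho * Wo;
      const double bc = b[c];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv_bwd")]]
List tconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad) {
  IntegerVector xd = tensor_dims(x), yd = tensor_dims(dy);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = yd[0], Wo = yd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cout, Cin,
               false, true);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  arma::mat dW((size_t)k * k * Cout, Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    im2col_one(dyn, Ho, Wo, Cout, k, stride, pad, H, W, cols);
    arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 (size_t)H * W, Cin, false, true);
    arma::mat dXn = cols.t() * Wm;         // (H*W) x Cin
    std::copy(dXn.begin(), dXn.end(), dx.begin() + (size_t)n * H * W * Cin);
    dW += cols * Xn;
    for (int c = 0; c < Cout; ++c) {
      const double* dyc = dyn + (size_t)c * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) db[c] += dyc[i];
    }
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
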