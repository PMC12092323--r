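// Low-level convolution kernels for the segmentation network engine.
// Tensor layout throughout: numeric array with dim = c(C, H, W, N)
// (channels fastest, column-major), weights for dense convolutions as
// (Cout, Cin, Kh, Kw). All arithmetic in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col: returns (Cin*K*K) x (Ho*Wo*N) matrix, row index r = c + Cin*(kh + K*kw),
// column index = ho + Ho*(wo + Wo*n) so the GEMM output matches the (C,H,W,N) layout.
static arma::mat im2col(const double* x, int C, int H, int W, int N,
                        int K, int stride, int pad, int Ho, int Wo) {
  arma::mat cols(C * K * K, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* dst = cols.colptr(col);
        for (int kw = 0; kw < K; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            const double* src = xn + (size_t)C * (hi + (size_t)H * wi);
            double* d = dst + (size_t)C * (kh + (size_t)K * kw);
            for (int c = 0; c < C; ++c) d[c] = src[c];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const arma::mat& cols, double* dx, int C, int H, int W, int N,
                   int K, int stride, int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* xn = dx + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double* src = cols.colptr(col);
        for (int kw = 0; kw < K; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double* dst = xn + (size_t)C * (hi + (size_t)H * wi);
            const double* s = src + (size_t)C * (kh + (size_t)K * kw);
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0], Cin = wd[1], K = wd[2];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  arma::mat cols = im2col(x.begin(), C, H, W, N, K, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), Cout, (size_t)Cin * K * K, false, true);
  arma::mat Y = Wm * cols;
  Y.each_col() += arma::vec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0], Cin = wd[1], K = wd[2];
  int Ho = yd[1], Wo = yd[2];
  arma::mat cols = im2col(x.begin(), C, H, W, N, K, stride, pad, Ho, Wo);
  arma::mat dY(const_cast<double*>(dy.begin()), Cout, (size_t)Ho * Wo * N, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), Cout, (size_t)Cin * K * K, false, true);
  arma::mat dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcols = Wm.t() * dY;
  NumericVector dx(x.size());
  col2im(dcols, dx.begin(), C, H, W, N, K, stride, pad, Ho, Wo);
  dx.attr("dim") = xd;
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Depthwise KxK convolution, same padding (K odd), weights (C, K, K).
// Uses a zero-padded copy of each sample plus weight vectors replicated
// along the channel-interleaved axis so the inner loops are contiguous
// fused multiply-adds without bounds checks.
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3], K = wd[1];
  int pad = K / 2;
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  NumericVector out(x.size());
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* bp = b.begin();
  double* op = out.begin();
  std::vector<double> padbuf((size_t)C * Hp * Wp, 0.0);
  std::vector<double> wrep((size_t)C * H);   // weight replicated along a column
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    double* on = op + (size_t)C * H * W * n;
    // padded copy
    for (int wi = 0; wi < W; ++wi) {
      std::copy(xn + (size_t)C * H * wi, xn + (size_t)C * H * (wi + 1),
                padbuf.data() + (size_t)C * (pad + (size_t)Hp * (wi + pad)));
    }
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* wk = wp + (size_t)C * (kh + (size_t)K * kw);
        for (int h = 0; h < H; ++h)
          for (int c = 0; c < C; ++c) wrep[(size_t)C * h + c] = wk[c];
        for (int wo = 0; wo < W; ++wo) {
          double* dst = on + (size_t)C * H * wo;
          const double* src = padbuf.data() +
            (size_t)C * (kh + (size_t)Hp * (wo + kw));
          const size_t len = (size_t)C * H;
          for (size_t i = 0; i < len; ++i) dst[i] += wrep[i] * src[i];
        }
      }
    }
    for (size_t i = 0; i < (size_t)H * W; ++i) {
      double* dst = on + C * i;
      for (int c = 0; c < C; ++c) dst[c] += bp[c];
    }
  }
  out.attr("dim") = xd;
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3], K = wd[1];
  int pad = K / 2;
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  NumericVector dx(x.size()), dw(w.size()), db(C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  std::vector<double> padbuf((size_t)C * Hp * Wp);
  std::vector<double> dpad((size_t)C * Hp * Wp);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    const double* gn = dyp + (size_t)C * H * W * n;
    double* dxn = dx.begin() + (size_t)C * H * W * n;
    std::fill(padbuf.begin(), padbuf.end(), 0.0);
    std::fill(dpad.begin(), dpad.end(), 0.0);
    for (int wi = 0; wi < W; ++wi) {
      std::copy(xn + (size_t)C * H * wi, xn + (size_t)C * H * (wi + 1),
                padbuf.data() + (size_t)C * (pad + (size_t)Hp * (wi + pad)));
    }
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* wk = wp + (size_t)C * (kh + (size_t)K * kw);
        double* dwk = dw.begin() + (size_t)C * (kh + (size_t)K * kw);
        for (int wo = 0; wo < W; ++wo) {
          const double* g = gn + (size_t)C * H * wo;
          size_t off = (size_t)C * (kh + (size_t)Hp * (wo + kw));
          const double* src = padbuf.data() + off;
          double* dsrc = dpad.data() + off;
          for (int h = 0; h < H; ++h) {
            const size_t base = (size_t)C * h;
            for (int c = 0; c < C; ++c) {
              dsrc[base + c] += wk[c] * g[base + c];
              dwk[c] += src[base + c] * g[base + c];
            }
          }
        }
      }
    }
    for (int wi = 0; wi < W; ++wi) {
      const double* s = dpad.data() + (size_t)C * (pad + (size_t)Hp * (wi + pad));
      double* d = dxn + (size_t)C * H * wi;
      for (size_t i = 0; i < (size_t)C * H; ++i) d[i] += s[i];
    }
    for (size_t i = 0; i < (size_t)H * W; ++i) {
      const double* g = gn + C * i;
      for (int c = 0; c < C; ++c) db[c] += g[c];
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Pointwise (1x1) convolution as a direct GEMM over the channel axis,
// avoiding R-side reshapes. x (C,H,W,N), W (Cout,Cin), b length Cout.
// [[Rcpp::export]]
NumericVector cpp_pwconv(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0];
  size_t M = (size_t)xd[1] * xd[2] * xd[3];
  int Cout = wd[0];
  arma::mat X(const_cast<double*>(x.begin()), C, M, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
  NumericVector out((size_t)Cout * M);
  arma::mat Y(out.begin(), Cout, M, false, true);
  Y = Wm * X;
  Y.each_col() += arma::vec(const_cast<double*>(b.begin()), Cout, false, true);
  out.attr("dim") = IntegerVector::create(Cout, xd[1], xd[2], xd[3]);
  return out;
}

// [[Rcpp::export]]
List cpp_pwconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0];
  size_t M = (size_t)xd[1] * xd[2] * xd[3];
  int Cout = wd[0];
  arma::mat X(const_cast<double*>(x.begin()), C, M, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
  arma::mat dY(const_cast<double*>(dy.begin()), Cout, M, false, true);
  NumericVector dx(x.size());
  arma::mat dX(dx.begin(), C, M, false, true);
  dX = Wm.t() * dY;
  arma::mat dW = dY * X.t();
  arma::vec db = arma::sum(dY, 1);
  dx.attr("dim") = xd;
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Layer normalization across the channel axis (per column), with affine
// parameters. Returns y and caches (xhat, ivar) for the backward pass.
// [[Rcpp::export]]
List cpp_layernorm(NumericVector x, NumericVector gamma, NumericVector beta,
                   double eps) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0];
  size_t M = x.size() / C;
  NumericVector y(x.size()), xhat(x.size()), ivar(M);
  const double* xp = x.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  double* vp = ivar.begin();
  for (size_t m = 0; m < M; ++m) {
    const double* col = xp + (size_t)C * m;
    double mu = 0;
    for (int c = 0; c < C; ++c) mu += col[c];
    mu /= C;
    double v = 0;
    for (int c = 0; c < C; ++c) { double d = col[c] - mu; v += d * d; }
    v /= C;
    double iv = 1.0 / std::sqrt(v + eps);
    vp[m] = iv;
    double* hc = hp + (size_t)C * m;
    double* yc = yp + (size_t)C * m;
    for (int c = 0; c < C; ++c) {
      hc[c] = (col[c] - mu) * iv;
      yc[c] = gp[c] * hc[c] + bp[c];
    }
  }
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar);
}

// [[Rcpp::export]]
List cpp_layernorm_bwd(NumericVector xhat, NumericVector ivar,
                       NumericVector gamma, NumericVector dy) {
  IntegerVector xd = xhat.attr("dim");
  int C = xd[0];
  size_t M = xhat.size() / C;
  NumericVector dx(xhat.size()), dgamma(C), dbeta(C);
  const double* hp = xhat.begin();
  const double* vp = ivar.begin();
  const double* gp = gamma.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  for (size_t m = 0; m < M; ++m) {
    const double* hc = hp + (size_t)C * m;
    const double* dc = dp + (size_t)C * m;
    double* oc = op + (size_t)C * m;
    double m1 = 0, m2 = 0;
    for (int c = 0; c < C; ++c) {
      double dxh = dc[c] * gp[c];
      m1 += dxh;
      m2 += dxh * hc[c];
      dgp[c] += dc[c] * hc[c];
      dbp[c] += dc[c];
    }
    m1 /= C;
    m2 /= C;
    for (int c = 0; c < C; ++c) {
      oc[c] = (dc[c] * gp[c] - m1 - hc[c] * m2) * vp[m];
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Exact GELU x * Phi(x) with Phi from erf. The forward pass returns the
// activation and caches Phi(x) so the backward pass only needs the
// Gaussian density.
// [[Rcpp::export]]
List cpp_gelu(NumericVector x) {
  NumericVector out(x.size()), phi(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  double* pp = phi.begin();
  const double inv_sqrt2 = 0.7071067811865475244;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    pp[i] = 0.5 * (1.0 + std::erf(xp[i] * inv_sqrt2));
    op[i] = xp[i] * pp[i];
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["y"] = out, _["phi"] = phi);
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector x, NumericVector phi,
                           NumericVector dy) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  const double* pp = phi.begin();
  const double* dp = dy.begin();
  double* op = out.begin();
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double dens = inv_sqrt2pi * std::exp(-0.5 * xp[i] * xp[i]);
    op[i] = dp[i] * (pp[i] + xp[i] * dens);
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Transpose convolution 2x2, stride 2: out (Cout, 2H, 2W, N), weights (Cout, Cin, 2, 2).
// [[Rcpp::export]]
NumericVector cpp_tconv2(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0], Cin = wd[1];
  if (Cin != C) stop("tconv2: channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Cout * Ho * Wo * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    double* on = out.begin() + (size_t)Cout * Ho * Wo * n;
    for (int wi = 0; wi < W; ++wi) {
      for (int hi = 0; hi < H; ++hi) {
        const double* src = xn + (size_t)C * (hi + (size_t)H * wi);
        for (int dw_ = 0; dw_ < 2; ++dw_) {
          for (int dh = 0; dh < 2; ++dh) {
            double* dst = on + (size_t)Cout * ((2 * hi + dh) + (size_t)Ho * (2 * wi + dw_));
            const double* wk = wp + (size_t)Cout * Cin * (dh + 2 * dw_);
            for (int ci = 0; ci < C; ++ci) {
              double v = src[ci];
              const double* wc = wk + (size_t)Cout * ci;
              for (int co = 0; co < Cout; ++co) dst[co] += wc[co] * v;
            }
          }
        }
      }
    }
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
      double* dst = on + Cout * i;
      for (int co = 0; co < Cout; ++co) dst[co] += bp[co];
    }
  }
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    const double* gn = dyp + (size_t)Cout * Ho * Wo * n;
    double* dxn = dx.begin() + (size_t)C * H * W * n;
    for (int wi = 0; wi < W; ++wi) {
      for (int hi = 0; hi < H; ++hi) {
        const double* src = xn + (size_t)C * (hi + (size_t)H * wi);
        double* dsrc = dxn + (size_t)C * (hi + (size_t)H * wi);
        for (int dw_ = 0; dw_ < 2; ++dw_) {
          for (int dh = 0; dh < 2; ++dh) {
            const double* g = gn + (size_t)Cout * ((2 * hi + dh) + (size_t)Ho * (2 * wi + dw_));
            const double* wk = wp + (size_t)Cout * C * (dh + 2 * dw_);
            double* dwk = dw.begin() + (size_t)Cout * C * (dh + 2 * dw_);
            for (int ci = 0; ci < C; ++ci) {
              const double* wc = wk + (size_t)Cout * ci;
              double* dwc = dwk + (size_t)Cout * ci;
              double acc = 0.0, v = src[ci];
              for (int co = 0; co < Cout; ++co) {
                acc += wc[co] * g[co];
                dwc[co] += v * g[co];
              }
              dsrc[ci] += acc;
            }
          }
        }
      }
    }
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
      const double* g = gn + Cout * i;
      for (int co = 0; co < Cout; ++co) db[co] += g[co];
    }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
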