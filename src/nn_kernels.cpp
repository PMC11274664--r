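// Compute kernels for the convolutional engine. Feature maps use the
// package's channel-first layout (C, H, W, N), column-major as stored by R.
// Convolutions are im2col + GEMM; the im2col panel is rebuilt in the
// backward pass instead of cached, trading a cheap loop for memory.
// Weight matrices have one row per output channel and one column per
// kernel offset (input channel fastest, then ki, then kj).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column r of the weight matrix corresponds to kernel offset
// (c fastest, then ki, then kj), so both the gather below and the
// scatter in the backward pass copy contiguous runs of C doubles.
static inline void build_col(const double* x, arma::mat& col,
                             int C, int H, int W, int N,
                             int k, int s, int p, int Ho, int Wo) {
  long m = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (long) n * C * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi, ++m) {
        double* cm = col.colptr(m);
        for (int kj = 0; kj < k; ++kj) {
          int j = oj * s + kj - p;
          for (int ki = 0; ki < k; ++ki, cm += C) {
            int i = oi * s + ki - p;
            if (j < 0 || j >= W || i < 0 || i >= H) {
              std::memset(cm, 0, C * sizeof(double));
            } else {
              std::memcpy(cm, xn + ((long) j * H + i) * C,
                          C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_conv_fwd(NumericVector x, IntegerVector xdim,
                          NumericMatrix Wm, NumericVector b,
                          int k, int s, int p) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const int cout = Wm.nrow();
  const long M = (long) Ho * Wo * N;
  arma::mat col((long) k * k * C, M);
  build_col(x.begin(), col, C, H, W, N, k, s, p, Ho, Wo);
  arma::mat Wa(Wm.begin(), cout, Wm.ncol(), false);
  arma::mat Y = Wa * col;
  if (b.size() > 0) {
    arma::vec bv(b.begin(), b.size(), false);
    Y.each_col() += bv;
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(cout, Ho, Wo, N);
  return out;
}

// [[Rcpp::export(rng = false)]]
List nn_conv_bwd(NumericVector x, IntegerVector xdim, NumericMatrix Wm,
                 NumericVector dy, int k, int s, int p, bool bias) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const int cout = Wm.nrow();
  const long M = (long) Ho * Wo * N;
  arma::mat col((long) k * k * C, M);
  build_col(x.begin(), col, C, H, W, N, k, s, p, Ho, Wo);
  arma::mat dYm(dy.begin(), cout, M, false);
  arma::mat dW = dYm * col.t();
  arma::mat Wa(Wm.begin(), cout, Wm.ncol(), false);
  arma::mat dcol = Wa.t() * dYm;            // (k*k*C) x M
  NumericVector dx(x.size());
  double* dxp = dx.begin();
  long m = 0;
  for (int n = 0; n < N; ++n) {
    double* dxn = dxp + (long) n * C * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi, ++m) {
        const double* cm = dcol.colptr(m);
        for (int kj = 0; kj < k; ++kj) {
          int j = oj * s + kj - p;
          for (int ki = 0; ki < k; ++ki, cm += C) {
            int i = oi * s + ki - p;
            if (j < 0 || j >= W || i < 0 || i >= H) continue;
            double* dst = dxn + ((long) j * H + i) * C;
            for (int c = 0; c < C; ++c) dst[c] += cm[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  List out = List::create(_["dW"] = wrap(dW), _["dx"] = dx);
  if (bias) out["db"] = wrap(arma::vec(arma::sum(dYm, 1)));
  return out;
}

// [[Rcpp::export(rng = false)]]
List nn_maxpool_fwd(NumericVector x, IntegerVector xdim,
                    int k, int s, int p) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const long M = (long) C * Ho * Wo * N;
  NumericVector y(M);
  IntegerVector arg(M);                     // 1-based linear index into x
  const double* xp = x.begin();
  long m = 0;
  for (int n = 0; n < N; ++n) {
    const long off = (long) n * C * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        for (int c = 0; c < C; ++c, ++m) {
          double best = R_NegInf;
          long besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            int j = oj * s + kj - p;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int i = oi * s + ki - p;
              if (i < 0 || i >= H) continue;
              long idx = off + c + (long) C * (i + (long) j * H);
              double v = xp[idx];
              if (v > best) { best = v; besti = idx; }
            }
          }
          y[m] = best;
          arg[m] = (int) (besti + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_scatter1(NumericVector dy, IntegerVector arg, int xlen) {
  NumericVector dx(xlen);
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[arg[i] - 1] += dy[i];
  return dx;
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_avgpool_fwd(NumericVector x, IntegerVector xdim,
                             int k, int s) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = (H - k) / s + 1;
  const int Wo = (W - k) / s + 1;
  NumericVector y((long) C * Ho * Wo * N);
  const double inv = 1.0 / (k * k);
  const double* xp = x.begin();
  long m = 0;
  for (int n = 0; n < N; ++n) {
    const long off = (long) n * C * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        for (int c = 0; c < C; ++c, ++m) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            long jcol = off + c + (long) C * (long) H * (oj * s + kj);
            for (int ki = 0; ki < k; ++ki) {
              acc += xp[jcol + (long) C * (oi * s + ki)];
            }
          }
          y[m] = acc * inv;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_avgpool_bwd(NumericVector dy, IntegerVector xdim,
                             int k, int s) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = (H - k) / s + 1;
  const int Wo = (W - k) / s + 1;
  NumericVector dx((long) C * H * W * N);
  const double inv = 1.0 / (k * k);
  double* dxp = dx.begin();
  long m = 0;
  for (int n = 0; n < N; ++n) {
    const long off = (long) n * C * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        for (int c = 0; c < C; ++c, ++m) {
          const double v = dy[m] * inv;
          for (int kj = 0; kj < k; ++kj) {
            long jcol = off + c + (long) C * (long) H * (oj * s + kj);
            for (int ki = 0; ki < k; ++ki) {
              dxp[jcol + (long) C * (oi * s + ki)] += v;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Batch norm over channels (x viewed as C x M, channels fastest).
// [[Rcpp::export(rng = false)]]
List nn_bn_fwd(NumericVector x, int C, NumericVector gamma,
               NumericVector beta, NumericVector mu, NumericVector var,
               double eps, bool train) {
  const long M = x.size() / C;
  NumericVector y(x.size()), xhat(x.size());
  std::vector<double> mu_(C), invstd(C);
  if (train) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    const double* xp = x.begin();
    for (long m = 0; m < M; ++m) {
      const double* xm = xp + m * C;
      for (int c = 0; c < C; ++c) { s1[c] += xm[c]; s2[c] += xm[c] * xm[c]; }
    }
    NumericVector muo(C), varo(C);
    for (int c = 0; c < C; ++c) {
      mu_[c] = s1[c] / M;
      double v = s2[c] / M - mu_[c] * mu_[c];
      if (v < 0) v = 0;
      muo[c] = mu_[c]; varo[c] = v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
    const double* g = gamma.begin(); const double* b = beta.begin();
    double* yp = y.begin(); double* hp = xhat.begin();
    for (long m = 0; m < M; ++m) {
      const double* xm = xp + m * C;
      double* ym = yp + m * C; double* hm = hp + m * C;
      for (int c = 0; c < C; ++c) {
        double h = (xm[c] - mu_[c]) * invstd[c];
        hm[c] = h;
        ym[c] = h * g[c] + b[c];
      }
    }
    return List::create(_["y"] = y, _["xhat"] = xhat,
                        _["mu"] = muo, _["var"] = varo);
  }
  for (int c = 0; c < C; ++c) {
    mu_[c] = mu[c];
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  const double* xp = x.begin();
  const double* g = gamma.begin(); const double* b = beta.begin();
  double* yp = y.begin();
  for (long m = 0; m < M; ++m) {
    const double* xm = xp + m * C;
    double* ym = yp + m * C;
    for (int c = 0; c < C; ++c) {
      ym[c] = (xm[c] - mu_[c]) * invstd[c] * g[c] + b[c];
    }
  }
  return List::create(_["y"] = y);
}

// [[Rcpp::export(rng = false)]]
List nn_bn_bwd(NumericVector dy, NumericVector xhat, int C,
               NumericVector gamma, NumericVector invstd) {
  const long M = dy.size() / C;
  NumericVector dgamma(C), dbeta(C), dx(dy.size());
  std::vector<double> sdh(C, 0.0), sdhh(C, 0.0);
  const double* dyp = dy.begin(); const double* hp = xhat.begin();
  const double* g = gamma.begin();
  for (long m = 0; m < M; ++m) {
    const double* dm = dyp + m * C; const double* hm = hp + m * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += dm[c] * hm[c];
      dbeta[c] += dm[c];
      sdh[c] += dm[c] * g[c];
      sdhh[c] += dm[c] * g[c] * hm[c];
    }
  }
  double* dxp = dx.begin();
  for (long m = 0; m < M; ++m) {
    const double* dm = dyp + m * C; const double* hm = hp + m * C;
    double* xm = dxp + m * C;
    for (int c = 0; c < C; ++c) {
      double dxhat = dm[c] * g[c];
      xm[c] = (invstd[c] / M) * (M * dxhat - sdh[c] - hm[c] * sdhh[c]);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["dx"] = dx);
}

// Fused batch-norm + ReLU. Backward recomputes xhat from the saved input
// instead of storing it, and reads the ReLU gate off the saved output --
// no intermediate arrays, two passes total.
// [[Rcpp::export(rng = false)]]
List nn_bnrelu_fwd(NumericVector x, int C, NumericVector gamma,
                   NumericVector beta, NumericVector mu, NumericVector var,
                   double eps, bool train) {
  const long M = x.size() / C;
  NumericVector y(x.size());
  std::vector<double> mu_(C), invstd(C);
  NumericVector muo(C), varo(C);
  const double* xp = x.begin();
  if (train) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (long m = 0; m < M; ++m) {
      const double* xm = xp + m * C;
      for (int c = 0; c < C; ++c) { s1[c] += xm[c]; s2[c] += xm[c] * xm[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu_[c] = s1[c] / M;
      double v = s2[c] / M - mu_[c] * mu_[c];
      if (v < 0) v = 0;
      muo[c] = mu_[c]; varo[c] = v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu_[c] = mu[c];
      invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    }
  }
  const double* g = gamma.begin(); const double* b = beta.begin();
  double* yp = y.begin();
  for (long m = 0; m < M; ++m) {
    const double* xm = xp + m * C;
    double* ym = yp + m * C;
    for (int c = 0; c < C; ++c) {
      double v = (xm[c] - mu_[c]) * invstd[c] * g[c] + b[c];
      ym[c] = v > 0 ? v : 0.0;
    }
  }
  if (train) return List::create(_["y"] = y, _["mu"] = muo, _["var"] = varo);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(rng = false)]]
List nn_bnrelu_bwd(NumericVector dy, NumericVector y, NumericVector x,
                   int C, NumericVector gamma, NumericVector mu,
                   NumericVector invstd) {
  const long M = dy.size() / C;
  NumericVector dgamma(C), dbeta(C), dx(dy.size());
  std::vector<double> sdh(C, 0.0), sdhh(C, 0.0);
  const double* dyp = dy.begin(); const double* yp = y.begin();
  const double* xp = x.begin();
  const double* g = gamma.begin();
  for (long m = 0; m < M; ++m) {
    const double* dm = dyp + m * C; const double* ym = yp + m * C;
    const double* xm = xp + m * C;
    for (int c = 0; c < C; ++c) {
      if (ym[c] <= 0) continue;
      double h = (xm[c] - mu[c]) * invstd[c];
      double d = dm[c];
      dgamma[c] += d * h;
      dbeta[c] += d;
      sdh[c] += d * g[c];
      sdhh[c] += d * g[c] * h;
    }
  }
  double* dxp = dx.begin();
  for (long m = 0; m < M; ++m) {
    const double* dm = dyp + m * C; const double* ym = yp + m * C;
    const double* xm = xp + m * C;
    double* om = dxp + m * C;
    for (int c = 0; c < C; ++c) {
      double h = (xm[c] - mu[c]) * invstd[c];
      double dxhat = (ym[c] > 0) ? dm[c] * g[c] : 0.0;
      om[c] = (invstd[c] / M) * (M * dxhat - sdh[c] - h * sdhh[c]);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["dx"] = dx);
}

// Fused residual join: y = relu(a + b).
// [[Rcpp::export(rng = false)]]
NumericVector nn_addrelu_fwd(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  const double* ap = a.begin(); const double* bp = b.begin();
  double* yp = y.begin();
  const long n = a.size();
  for (long i = 0; i < n; ++i) {
    double v = ap[i] + bp[i];
    yp[i] = v > 0 ? v : 0.0;
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_addrelu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dp = dy.begin(); const double* yp = y.begin();
  double* xp = dx.begin();
  const long n = dy.size();
  for (long i = 0; i < n; ++i) xp[i] = yp[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
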