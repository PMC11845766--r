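// Dense numerical kernels for the convolutional feature heads: 3x3 "same"
// convolution via im2col + BLAS gemm, 2x2 max pooling, and per-channel
// batch normalization, all on [H, W, C, B] column-major arrays (the native
// R array layout). Gradients are exact; everything is single-threaded and
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W,
                             int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d [H, W, C, B] array");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

// im2col for one sample: K[9*c + 3*kw + kh, h + H*w] = X[h+kh-1, w+kw-1, c]
// (zero padding outside). Row order matches an R [3,3,Cin,Cout] weight
// array flattened to [9*Cin, Cout].
static void im2col3x3(const double* X, int H, int W, int C, arma::mat& K) {
  K.zeros(9 * C, (size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + (size_t)c * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int r = 9 * c + 3 * kw + kh;
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* src = Xc + (size_t)sw * H + (h0 + dh);
          for (int h = h0; h < h1; ++h) {
            K.at(r, (size_t)w * H + h) = src[h - h0];
          }
        }
      }
    }
  }
}

static void col2im3x3(const arma::mat& K, int H, int W, int C, double* X) {
  for (int c = 0; c < C; ++c) {
    double* Xc = X + (size_t)c * H * W;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        int r = 9 * c + 3 * kw + kh;
        int dh = kh - 1, dw = kw - 1;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          double* dst = Xc + (size_t)sw * H + (h0 + dh);
          for (int h = h0; h < h1; ++h) {
            dst[h - h0] += K.at(r, (size_t)w * H + h);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
NumericVector conv3x3_forward(NumericVector x, NumericVector w) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("weight must be [3, 3, Cin, Cout] with Cin matching input");
  int Cout = wd[3];
  arma::mat Wmat(w.begin(), 9 * C, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat K;
  for (int b = 0; b < B; ++b) {
    im2col3x3(x.begin() + (size_t)b * H * W * C, H, W, C, K);
    arma::mat Yb(y.begin() + (size_t)b * H * W * Cout,
                 (size_t)H * W, Cout, false, true);
    Yb = K.t() * Wmat;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  arma::mat Wmat(w.begin(), 9 * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw((size_t)9 * C * Cout);
  dw.attr("dim") = wd;
  arma::mat dWmat(dw.begin(), 9 * C, Cout, false, true);
  arma::mat K, dK;
  for (int b = 0; b < B; ++b) {
    im2col3x3(x.begin() + (size_t)b * H * W * C, H, W, C, K);
    arma::mat dYb(dy.begin() + (size_t)b * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    dWmat += K * dYb;
    dK = Wmat * dYb.t();
    col2im3x3(dK, H, W, C, dx.begin() + (size_t)b * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling, stride 2, trailing row/column dropped when odd.
// Returns the pooled array and the 1-based linear argmax index into the
// input array (for the backward scatter).
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  NumericVector idx((size_t)Ho * Wo * C * B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = x.begin() + ((size_t)b * C + c) * H * W;
      size_t base = ((size_t)b * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          double bv = Xc[cand[0]];
          for (int t = 1; t < 4; ++t) {
            if (Xc[cand[t]] > bv) { bv = Xc[cand[t]]; best = cand[t]; }
          }
          y[o] = bv;
          idx[o] = (double)(base + best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector idx, NumericVector dy,
                                IntegerVector in_dim) {
  size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    dx[(size_t)idx[i] - 1] += dy[i];
  }
  return dx;
}

// Per-channel batch statistics over batch and spatial axes.
// [[Rcpp::export(name = ".bn2d_stats")]]
List bn2d_stats(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  std::vector<double> sum(C, 0.0), sq(C, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = x.begin() + ((size_t)b * C + c) * H * W;
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        s += Xc[i];
        s2 += Xc[i] * Xc[i];
      }
      sum[c] += s;
      sq[c] += s2;
    }
  }
  double n = (double)H * W * B;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    mean[c] = sum[c] / n;
    var[c] = sq[c] / n - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var, _["n"] = n);
}

// xhat = (x - mean) * inv_std ; y = gamma * xhat + beta
// [[Rcpp::export(name = ".bn2d_apply")]]
List bn2d_apply(NumericVector x, NumericVector mean, NumericVector inv_std,
                NumericVector gamma, NumericVector beta,
                bool keep_xhat) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector xhat;
  if (keep_xhat) {
    xhat = NumericVector(x.size());
    xhat.attr("dim") = x.attr("dim");
  }
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)b * C + c) * H * W;
      double mu = mean[c], is = inv_std[c], g = gamma[c], bt = beta[c];
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        double xh = (x[off + i] - mu) * is;
        if (keep_xhat) xhat[off + i] = xh;
        y[off + i] = g * xh + bt;
      }
    }
  }
  if (keep_xhat) return List::create(_["y"] = y, _["xhat"] = xhat);
  return List::create(_["y"] = y);
}

// Batch-norm backward (training mode, batch statistics):
// dx = gamma * inv_std * (dy - mean(dy) - xhat * mean(dy * xhat))
// [[Rcpp::export(name = ".bn2d_backward")]]
List bn2d_backward(NumericVector dy, NumericVector xhat,
                   NumericVector gamma, NumericVector inv_std) {
  int H, W, C, B;
  get_dims4(dy, H, W, C, B);
  double n = (double)H * W * B;
  std::vector<double> sdy(C, 0.0), sdyx(C, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)b * C + c) * H * W;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        sdy[c] += dy[off + i];
        sdyx[c] += dy[off + i] * xhat[off + i];
      }
    }
  }
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sdyx[c];
    dbeta[c] = sdy[c];
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)b * C + c) * H * W;
      double g = gamma[c] * inv_std[c];
      double mdy = sdy[c] / n, mdyx = sdyx[c] / n;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        dx[off + i] = g * (dy[off + i] - mdy - xhat[off + i] * mdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
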