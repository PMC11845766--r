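// Fused single-precision forward/backward of one convolutional feature
// head: three 3x3 conv blocks (batch norm + ReLU, 2x2 max pool after
// blocks 1-2) and global average pooling. Activations are kept in float
// workspaces owned by an external-pointer cache that is reused across
// batches; matrix products go through BLAS sgemm (Armadillo fmat). The
// double-precision reference kernels in conv_ops.cpp implement the same
// operations layer by layer and serve as the correctness oracle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct BlockDims {
  int H, W, Cin, Cout;   // conv geometry ("same" padding)
  int Hp, Wp;            // after pooling (== H, W when no pool)
  bool pool;
};

struct HeadCache {
  int B = -1, H0 = -1, W0 = -1;
  BlockDims d1, d2, d3;
  std::vector<float> x0, c1, c2, c3;   // block inputs / conv outputs
  std::vector<float> p1, p2, y3;       // post bn+relu(+pool) activations
  std::vector<int> i1, i2;             // pool argmax (within-sample index)
  std::vector<float> mean1, istd1, mean2, istd2, mean3, istd3;
  arma::fmat K;                        // im2col workspace
};

static void to_float(const NumericVector& src, std::vector<float>& dst) {
  dst.resize(src.size());
  for (R_xlen_t i = 0; i < src.size(); ++i) dst[i] = (float)src[i];
}

static arma::fmat weights_to_fmat(const NumericVector& w, int rows,
                                  int cols) {
  arma::fmat W(rows, cols);
  for (int j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      W.at(i, j) = (float)w[(size_t)j * rows + i];
  return W;
}

// cache-friendly im2col: columns of K (one output pixel each) are filled
// contiguously; K[9*c + 3*kw + kh, h + H*w] = X[h+kh-1, w+kw-1, c]
static void im2col3x3f(const float* X, int H, int W, int C, arma::fmat& K) {
  K.set_size(9 * C, (size_t)H * W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      float* col = K.colptr((size_t)w * H + h);
      for (int c = 0; c < C; ++c) {
        const float* Xc = X + (size_t)c * H * W;
        for (int kw = 0; kw < 3; ++kw) {
          int sw = w + kw - 1;
          bool wok = sw >= 0 && sw < W;
          const float* Xcw = Xc + (size_t)sw * H;
          for (int kh = 0; kh < 3; ++kh) {
            int sh = h + kh - 1;
            col[9 * c + 3 * kw + kh] =
              (wok && sh >= 0 && sh < H) ? Xcw[sh] : 0.0f;
          }
        }
      }
    }
  }
}

static void col2im3x3f(const arma::fmat& K, int H, int W, int C,
                       float* X) {
  std::fill(X, X + (size_t)H * W * C, 0.0f);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const float* col = K.colptr((size_t)w * H + h);
      for (int c = 0; c < C; ++c) {
        float* Xc = X + (size_t)c * H * W;
        for (int kw = 0; kw < 3; ++kw) {
          int sw = w + kw - 1;
          if (sw < 0 || sw >= W) continue;
          float* Xcw = Xc + (size_t)sw * H;
          for (int kh = 0; kh < 3; ++kh) {
            int sh = h + kh - 1;
            if (sh >= 0 && sh < H) Xcw[sh] += col[9 * c + 3 * kw + kh];
          }
        }
      }
    }
  }
}

// conv for a whole batch: out[., ., co, b] = sum_{ci,k} in * w
static void conv_batch(const std::vector<float>& in, const arma::fmat& Wm,
                       const BlockDims& d, int B, std::vector<float>& out,
                       arma::fmat& K) {
  out.resize((size_t)d.H * d.W * d.Cout * B);
  for (int b = 0; b < B; ++b) {
    im2col3x3f(in.data() + (size_t)b * d.H * d.W * d.Cin, d.H, d.W,
               d.Cin, K);
    arma::fmat Y(out.data() + (size_t)b * d.H * d.W * d.Cout,
                 (size_t)d.H * d.W, d.Cout, false, true);
    Y = K.t() * Wm;
  }
}

static void batch_stats(const std::vector<float>& c, const BlockDims& d,
                        int B, std::vector<float>& mean,
                        std::vector<float>& var) {
  mean.assign(d.Cout, 0.0f);
  var.assign(d.Cout, 0.0f);
  size_t hw = (size_t)d.H * d.W;
  std::vector<double> s(d.Cout, 0.0), s2(d.Cout, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < d.Cout; ++ch) {
      const float* p = c.data() + ((size_t)b * d.Cout + ch) * hw;
      double a = 0.0, a2 = 0.0;
      for (size_t i = 0; i < hw; ++i) {
        a += p[i];
        a2 += (double)p[i] * p[i];
      }
      s[ch] += a;
      s2[ch] += a2;
    }
  }
  double n = (double)hw * B;
  for (int ch = 0; ch < d.Cout; ++ch) {
    double m = s[ch] / n;
    double v = s2[ch] / n - m * m;
    mean[ch] = (float)m;
    var[ch] = (float)(v > 0 ? v : 0);
  }
}

// fused bn + relu + optional 2x2 pool; y is written pooled (or full size)
static void bn_relu_pool(const std::vector<float>& c, const BlockDims& d,
                         int B, const std::vector<float>& mean,
                         const std::vector<float>& istd,
                         const NumericVector& gamma,
                         const NumericVector& beta,
                         std::vector<float>& y, std::vector<int>& idx) {
  size_t hw = (size_t)d.H * d.W;
  if (d.pool) {
    size_t hwp = (size_t)d.Hp * d.Wp;
    y.resize(hwp * d.Cout * B);
    idx.resize(hwp * d.Cout * B);
    for (int b = 0; b < B; ++b) {
      for (int ch = 0; ch < d.Cout; ++ch) {
        const float* p = c.data() + ((size_t)b * d.Cout + ch) * hw;
        float* yo = y.data() + ((size_t)b * d.Cout + ch) * hwp;
        int* io = idx.data() + ((size_t)b * d.Cout + ch) * hwp;
        float m = mean[ch], is = istd[ch];
        float g = (float)gamma[ch], bt = (float)beta[ch];
        for (int w = 0; w < d.Wp; ++w) {
          for (int h = 0; h < d.Hp; ++h) {
            size_t i00 = (size_t)(2 * w) * d.H + 2 * h;
            size_t cand[4] = {i00, i00 + 1, i00 + (size_t)d.H,
                              i00 + (size_t)d.H + 1};
            float best = -1e30f;
            size_t bi = cand[0];
            for (int t = 0; t < 4; ++t) {
              float v = g * (p[cand[t]] - m) * is + bt;
              if (v > best) { best = v; bi = cand[t]; }
            }
            yo[(size_t)w * d.Hp + h] = best > 0.0f ? best : 0.0f;
            io[(size_t)w * d.Hp + h] = (int)bi;
          }
        }
      }
    }
  } else {
    y.resize(hw * d.Cout * B);
    for (int b = 0; b < B; ++b) {
      for (int ch = 0; ch < d.Cout; ++ch) {
        const float* p = c.data() + ((size_t)b * d.Cout + ch) * hw;
        float* yo = y.data() + ((size_t)b * d.Cout + ch) * hw;
        float m = mean[ch], is = istd[ch];
        float g = (float)gamma[ch], bt = (float)beta[ch];
        for (size_t i = 0; i < hw; ++i) {
          float v = g * (p[i] - m) * is + bt;
          yo[i] = v > 0.0f ? v : 0.0f;
        }
      }
    }
  }
}

// backward through bn (training statistics) given the upstream gradient on
// the bn output (already relu-masked): dx = g*is*(dy - mdy - xhat*mdyx)
static void bn_backward_f(const std::vector<float>& dy,
                          const std::vector<float>& c, const BlockDims& d,
                          int B, const std::vector<float>& mean,
                          const std::vector<float>& istd,
                          const NumericVector& gamma,
                          std::vector<float>& dx, NumericVector& dgamma,
                          NumericVector& dbeta) {
  size_t hw = (size_t)d.H * d.W;
  double n = (double)hw * B;
  std::vector<double> sdy(d.Cout, 0.0), sdyx(d.Cout, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < d.Cout; ++ch) {
      size_t off = ((size_t)b * d.Cout + ch) * hw;
      float m = mean[ch], is = istd[ch];
      double a = 0.0, ax = 0.0;
      for (size_t i = 0; i < hw; ++i) {
        a += dy[off + i];
        ax += (double)dy[off + i] * (c[off + i] - m) * is;
      }
      sdy[ch] += a;
      sdyx[ch] += ax;
    }
  }
  dx.resize(dy.size());
  for (int ch = 0; ch < d.Cout; ++ch) {
    dgamma[ch] = sdyx[ch];
    dbeta[ch] = sdy[ch];
  }
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < d.Cout; ++ch) {
      size_t off = ((size_t)b * d.Cout + ch) * hw;
      float m = mean[ch], is = istd[ch];
      float g = (float)gamma[ch] * is;
      float mdy = (float)(sdy[ch] / n), mdyx = (float)(sdyx[ch] / n);
      for (size_t i = 0; i < hw; ++i) {
        float xh = (c[off + i] - m) * is;
        dx[off + i] = g * (dy[off + i] - mdy - xh * mdyx);
      }
    }
  }
}

// conv backward for a batch: accumulates dW, writes d(input) unless the
// caller passes dx = nullptr (input layer)
static void conv_backward_batch(const std::vector<float>& in,
                                const arma::fmat& Wm, const BlockDims& d,
                                int B, const std::vector<float>& dy,
                                arma::fmat& dWm, std::vector<float>* dx,
                                arma::fmat& K) {
  dWm.zeros(Wm.n_rows, Wm.n_cols);
  if (dx) dx->resize((size_t)d.H * d.W * d.Cin * B);
  arma::fmat dK;
  for (int b = 0; b < B; ++b) {
    im2col3x3f(in.data() + (size_t)b * d.H * d.W * d.Cin, d.H, d.W,
               d.Cin, K);
    arma::fmat dY(const_cast<float*>(dy.data()) +
                    (size_t)b * d.H * d.W * d.Cout,
                  (size_t)d.H * d.W, d.Cout, false, true);
    dWm += K * dY;
    if (dx) {
      dK = Wm * dY.t();
      col2im3x3f(dK, d.H, d.W, d.Cin,
                 dx->data() + (size_t)b * d.H * d.W * d.Cin);
    }
  }
}

// scatter pooled gradients back to the conv grid, applying the relu mask
// (pooled value > 0) at the argmax position
static void pool_relu_backward(const std::vector<float>& dpool,
                               const std::vector<float>& ypool,
                               const std::vector<int>& idx,
                               const BlockDims& d, int B,
                               std::vector<float>& dgrid) {
  size_t hw = (size_t)d.H * d.W;
  size_t hwp = (size_t)d.Hp * d.Wp;
  dgrid.assign(hw * d.Cout * B, 0.0f);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < d.Cout; ++ch) {
      size_t po = ((size_t)b * d.Cout + ch) * hwp;
      size_t go = ((size_t)b * d.Cout + ch) * hw;
      for (size_t i = 0; i < hwp; ++i) {
        if (ypool[po + i] > 0.0f) dgrid[go + idx[po + i]] += dpool[po + i];
      }
    }
  }
}

static BlockDims block_dims(int H, int W, int Cin, int Cout, bool pool) {
  BlockDims d;
  d.H = H; d.W = W; d.Cin = Cin; d.Cout = Cout; d.pool = pool;
  d.Hp = pool ? H / 2 : H;
  d.Wp = pool ? W / 2 : W;
  return d;
}

// [[Rcpp::export(name = ".head_forward")]]
List head_forward(NumericVector x, List p, bool training, SEXP cache_in) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4 || dim[2] != 1) stop("expected [H, W, 1, B] input");
  int H = dim[0], W = dim[1], B = dim[3];
  int f1 = 32, f2 = 64, f3 = 256;

  Rcpp::XPtr<HeadCache> cache =
    (cache_in != R_NilValue) ? Rcpp::XPtr<HeadCache>(cache_in)
                             : Rcpp::XPtr<HeadCache>(new HeadCache(), true);
  HeadCache& cc = *cache;
  cc.B = B; cc.H0 = H; cc.W0 = W;
  cc.d1 = block_dims(H, W, 1, f1, true);
  cc.d2 = block_dims(cc.d1.Hp, cc.d1.Wp, f1, f2, true);
  cc.d3 = block_dims(cc.d2.Hp, cc.d2.Wp, f2, f3, false);

  arma::fmat W1 = weights_to_fmat(p["w1"], 9, f1);
  arma::fmat W2 = weights_to_fmat(p["w2"], 9 * f1, f2);
  arma::fmat W3 = weights_to_fmat(p["w3"], 9 * f2, f3);
  double eps = as<double>(p["eps"]);

  to_float(x, cc.x0);
  conv_batch(cc.x0, W1, cc.d1, B, cc.c1, cc.K);

  std::vector<float> var1, var2, var3;
  auto stats_for = [&](const std::vector<float>& c, const BlockDims& d,
                       const char* rm, const char* rv,
                       std::vector<float>& mean, std::vector<float>& var,
                       std::vector<float>& istd) {
    if (training) {
      batch_stats(c, d, B, mean, var);
    } else {
      NumericVector m = p[rm], v = p[rv];
      mean.assign(m.begin(), m.end());
      var.assign(v.begin(), v.end());
    }
    istd.resize(d.Cout);
    for (int ch = 0; ch < d.Cout; ++ch) {
      istd[ch] = (float)(1.0 / std::sqrt((double)var[ch] + eps));
    }
  };

  stats_for(cc.c1, cc.d1, "rm1", "rv1", cc.mean1, var1, cc.istd1);
  bn_relu_pool(cc.c1, cc.d1, B, cc.mean1, cc.istd1, p["g1"], p["b1"],
               cc.p1, cc.i1);
  conv_batch(cc.p1, W2, cc.d2, B, cc.c2, cc.K);
  stats_for(cc.c2, cc.d2, "rm2", "rv2", cc.mean2, var2, cc.istd2);
  bn_relu_pool(cc.c2, cc.d2, B, cc.mean2, cc.istd2, p["g2"], p["b2"],
               cc.p2, cc.i2);
  conv_batch(cc.p2, W3, cc.d3, B, cc.c3, cc.K);
  stats_for(cc.c3, cc.d3, "rm3", "rv3", cc.mean3, var3, cc.istd3);
  std::vector<int> no_idx;
  bn_relu_pool(cc.c3, cc.d3, B, cc.mean3, cc.istd3, p["g3"], p["b3"],
               cc.y3, no_idx);

  // global average pooling -> [B, f3]
  NumericMatrix emb(B, f3);
  size_t hw3 = (size_t)cc.d3.H * cc.d3.W;
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < f3; ++ch) {
      const float* yp = cc.y3.data() + ((size_t)b * f3 + ch) * hw3;
      double s = 0.0;
      for (size_t i = 0; i < hw3; ++i) s += yp[i];
      emb(b, ch) = s / hw3;
    }
  }

  List out = List::create(_["emb"] = emb, _["cache"] = cache);
  if (training) {
    out["batch_stats"] = List::create(
      _["m1"] = NumericVector(cc.mean1.begin(), cc.mean1.end()),
      _["v1"] = NumericVector(var1.begin(), var1.end()),
      _["m2"] = NumericVector(cc.mean2.begin(), cc.mean2.end()),
      _["v2"] = NumericVector(var2.begin(), var2.end()),
      _["m3"] = NumericVector(cc.mean3.begin(), cc.mean3.end()),
      _["v3"] = NumericVector(var3.begin(), var3.end()));
  }
  return out;
}

// [[Rcpp::export(name = ".head_backward")]]
List head_backward(SEXP cache_in, NumericMatrix demb, List p) {
  Rcpp::XPtr<HeadCache> cache(cache_in);
  HeadCache& cc = *cache;
  int B = cc.B;
  int f1 = 32, f2 = 64, f3 = 256;
  arma::fmat W1 = weights_to_fmat(p["w1"], 9, f1);
  arma::fmat W2 = weights_to_fmat(p["w2"], 9 * f1, f2);
  arma::fmat W3 = weights_to_fmat(p["w3"], 9 * f2, f3);

  // GAP backward + relu mask of block 3
  size_t hw3 = (size_t)cc.d3.H * cc.d3.W;
  std::vector<float> dy3(hw3 * f3 * B);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < f3; ++ch) {
      float g = (float)(demb(b, ch) / hw3);
      size_t off = ((size_t)b * f3 + ch) * hw3;
      for (size_t i = 0; i < hw3; ++i) {
        dy3[off + i] = cc.y3[off + i] > 0.0f ? g : 0.0f;
      }
    }
  }

  NumericVector dg3(f3), db3(f3), dg2(f2), db2(f2), dg1(f1), db1(f1);
  std::vector<float> dc3, dp2, dgrid2, dc2, dp1, dgrid1, dc1;
  bn_backward_f(dy3, cc.c3, cc.d3, B, cc.mean3, cc.istd3, p["g3"], dc3,
                dg3, db3);
  arma::fmat dW3m, dW2m, dW1m;
  conv_backward_batch(cc.p2, W3, cc.d3, B, dc3, dW3m, &dp2, cc.K);

  pool_relu_backward(dp2, cc.p2, cc.i2, cc.d2, B, dgrid2);
  bn_backward_f(dgrid2, cc.c2, cc.d2, B, cc.mean2, cc.istd2, p["g2"],
                dc2, dg2, db2);
  conv_backward_batch(cc.p1, W2, cc.d2, B, dc2, dW2m, &dp1, cc.K);

  pool_relu_backward(dp1, cc.p1, cc.i1, cc.d1, B, dgrid1);
  bn_backward_f(dgrid1, cc.c1, cc.d1, B, cc.mean1, cc.istd1, p["g1"],
                dc1, dg1, db1);
  conv_backward_batch(cc.x0, W1, cc.d1, B, dc1, dW1m, nullptr, cc.K);

  NumericVector dw1(9 * f1), dw2(9 * f1 * f2), dw3(9 * f2 * f3);
  std::copy(dW1m.begin(), dW1m.end(), dw1.begin());
  std::copy(dW2m.begin(), dW2m.end(), dw2.begin());
  std::copy(dW3m.begin(), dW3m.end(), dw3.begin());
  dw1.attr("dim") = IntegerVector::create(3, 3, 1, f1);
  dw2.attr("dim") = IntegerVector::create(3, 3, f1, f2);
  dw3.attr("dim") = IntegerVector::create(3, 3, f2, f3);
  return List::create(_["dw1"] = dw1, _["dg1"] = dg1, _["db1"] = db1,
                      _["dw2"] = dw2, _["dg2"] = dg2, _["db2"] = db2,
                      _["dw3"] = dw3, _["dg3"] = dg3, _["db3"] = db3);
}
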