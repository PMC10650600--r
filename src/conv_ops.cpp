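// Low-level kernels for the conv-net engine.
//
// Tensor layout everywhere: column-major R array [H, W, C, B]
// (spatial fastest, batch slowest).  Conv weights are packed as a
// matrix [kh*kw*Cin, Cout] with row index r = ki + kh*(kj + kw*c).
//
// im2col uses a [N, kh*kw*C] matrix (N = OH*OW*B rows indexed oh-fastest)
// so that the hot inner loops read and write contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// cols(i, r): i = oh + OH*(ow + OW*b), r = ki + kh*(kj + kw*c)
template <typename MatT>
static void im2col(const double* x, int H, int W, int C, int B,
                   int kh, int kw, int s, int p,
                   MatT& cols, int OH, int OW) {
  const size_t N = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        auto* col = cols.colptr(ki + kh * (kj + kw * c));
        for (int b = 0; b < B; ++b) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * b);
          for (int ow = 0; ow < OW; ++ow) {
            auto* dst = col + (size_t)OH * (ow + (size_t)OW * b);
            const int wi = ow * s - p + kj;
            if (wi < 0 || wi >= W) {
              std::fill(dst, dst + OH, typename MatT::elem_type(0));
              continue;
            }
            const double* xcw = xc + (size_t)H * wi;
            if (s == 1) {
              // hi = oh - p + ki ranges over [ -p+ki, OH-1-p+ki ]
              int oh0 = std::max(0, p - ki);
              int oh1 = std::min(OH, H + p - ki);
              if (oh0 > 0) std::fill(dst, dst + oh0, typename MatT::elem_type(0));
              if (oh1 < OH) std::fill(dst + std::max(oh0, oh1), dst + OH, typename MatT::elem_type(0));
              for (int oh = oh0; oh < oh1; ++oh)
                dst[oh] = xcw[oh - p + ki];
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int hi = oh * s - p + ki;
                dst[oh] = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  (void)N;
}

template <typename MatT>
static void col2im(const MatT& cols, int H, int W, int C, int B,
                   int kh, int kw, int s, int p,
                   double* dx, int OH, int OW) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const auto* col = cols.colptr(ki + kh * (kj + kw * c));
        for (int b = 0; b < B; ++b) {
          double* xc = dx + (size_t)H * W * (c + (size_t)C * b);
          for (int ow = 0; ow < OW; ++ow) {
            const auto* src = col + (size_t)OH * (ow + (size_t)OW * b);
            const int wi = ow * s - p + kj;
            if (wi < 0 || wi >= W) continue;
            double* xcw = xc + (size_t)H * wi;
            for (int oh = 0; oh < OH; ++oh) {
              const int hi = oh * s - p + ki;
              if (hi >= 0 && hi < H) xcw[hi] += src[oh];
            }
          }
        }
      }
    }
  }
}

// y[OH,OW,Cout,B] = conv(x, W) + b
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector bias,
                             int H, int W, int C, int B,
                             int kh, int kw, int stride, int pad, bool has_bias) {
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);
  const int Cout = Wm.ncol();
  const size_t N = (size_t)OH * OW * B;
  // single-precision GEMM: conv arithmetic runs in float32 (the usual deep
  // learning precision); inputs/outputs stay double at the R level
  arma::fmat cols(N, (size_t)kh * kw * C);
  im2col(REAL(x), H, W, C, B, kh, kw, stride, pad, cols, OH, OW);
  arma::fmat Wa(Wm.nrow(), Wm.ncol());
  std::copy(Wm.begin(), Wm.end(), Wa.begin());
  arma::fmat y = cols * Wa;   // [N, Cout]
  NumericVector out(N * Cout);
  double* po = REAL(out);
  const double* pb = REAL(bias);
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      const double add = has_bias ? pb[co] : 0.0;
      const float* src = y.colptr(co) + (size_t)OH * OW * b;
      double* dst = po + (size_t)OH * OW * (co + (size_t)Cout * b);
      for (size_t i = 0; i < (size_t)OH * OW; ++i) dst[i] = src[i] + add;
    }
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, B);
  return out;
}

// Backward: returns list(dx, dW, db).  dy is [OH,OW,Cout,B].
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector dy,
                    int H, int W, int C, int B,
                    int kh, int kw, int stride, int pad) {
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);
  const int Cout = Wm.ncol();
  const size_t N = (size_t)OH * OW * B;

  arma::fmat dyM(N, Cout);
  const double* pdy = REAL(dy);
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      const double* src = pdy + (size_t)OH * OW * (co + (size_t)Cout * b);
      float* dst = dyM.colptr(co) + (size_t)OH * OW * b;
      std::copy(src, src + (size_t)OH * OW, dst);
    }

  arma::fmat cols(N, (size_t)kh * kw * C);
  im2col(REAL(x), H, W, C, B, kh, kw, stride, pad, cols, OH, OW);

  arma::fmat dW = cols.t() * dyM;                // [khkwC, Cout]
  arma::fmat Wa(Wm.nrow(), Wm.ncol());
  std::copy(Wm.begin(), Wm.end(), Wa.begin());
  arma::fmat dcols = dyM * Wa.t();               // [N, khkwC]

  NumericVector dx((size_t)H * W * C * B);       // zero-initialised
  col2im(dcols, H, W, C, B, kh, kw, stride, pad, REAL(dx), OH, OW);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);

  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co)
    db[co] = arma::accu(dyM.col(co));

  NumericMatrix dWr(Wm.nrow(), Wm.ncol());
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(Named("dx") = dx, Named("dW") = dWr, Named("db") = db);
}

// Bilinear resize (align_corners = FALSE, edge-clamped), [H,W,C,B] -> [OH,OW,C,B].
static inline void lin_coef(int i, double scale, int n, int& i0, int& i1, double& w1) {
  double src = (i + 0.5) * scale - 0.5;
  if (src < 0) src = 0;
  if (src > n - 1) src = n - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, n - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fwd_cpp(NumericVector x, int H, int W, int C, int B,
                                      int OH, int OW) {
  const double sh = (double)H / OH, sw = (double)W / OW;
  NumericVector out((size_t)OH * OW * C * B);
  double* po = REAL(out);
  const double* px = REAL(x);
  std::vector<int> h0(OH), h1(OH), w0(OW), w1(OW);
  std::vector<double> ah(OH), aw(OW);
  for (int i = 0; i < OH; ++i) lin_coef(i, sh, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < OW; ++j) lin_coef(j, sw, W, w0[j], w1[j], aw[j]);
  const size_t ncb = (size_t)C * B;
  for (size_t cb = 0; cb < ncb; ++cb) {
    const double* xc = px + (size_t)H * W * cb;
    double* oc = po + (size_t)OH * OW * cb;
    for (int j = 0; j < OW; ++j) {
      const double* c0 = xc + (size_t)H * w0[j];
      const double* c1 = xc + (size_t)H * w1[j];
      const double wj = aw[j];
      double* od = oc + (size_t)OH * j;
      for (int i = 0; i < OH; ++i) {
        const double top = c0[h0[i]] * (1 - ah[i]) + c0[h1[i]] * ah[i];
        const double bot = c1[h0[i]] * (1 - ah[i]) + c1[h1[i]] * ah[i];
        od[i] = top * (1 - wj) + bot * wj;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, C, B);
  return out;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dy, int H, int W, int C, int B,
                                      int OH, int OW) {
  const double sh = (double)H / OH, sw = (double)W / OW;
  NumericVector dx((size_t)H * W * C * B);
  double* pdx = REAL(dx);
  const double* pdy = REAL(dy);
  std::vector<int> h0(OH), h1(OH), w0(OW), w1(OW);
  std::vector<double> ah(OH), aw(OW);
  for (int i = 0; i < OH; ++i) lin_coef(i, sh, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < OW; ++j) lin_coef(j, sw, W, w0[j], w1[j], aw[j]);
  const size_t ncb = (size_t)C * B;
  for (size_t cb = 0; cb < ncb; ++cb) {
    double* xc = pdx + (size_t)H * W * cb;
    const double* oc = pdy + (size_t)OH * OW * cb;
    for (int j = 0; j < OW; ++j) {
      double* d0 = xc + (size_t)H * w0[j];
      double* d1 = xc + (size_t)H * w1[j];
      const double wj = aw[j];
      const double* od = oc + (size_t)OH * j;
      for (int i = 0; i < OH; ++i) {
        const double g = od[i];
        d0[h0[i]] += g * (1 - ah[i]) * (1 - wj);
        d0[h1[i]] += g * ah[i] * (1 - wj);
        d1[h0[i]] += g * (1 - ah[i]) * wj;
        d1[h1[i]] += g * ah[i] * wj;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}

// ---- fast paths -------------------------------------------------------------

// 1x1 stride-1 convolution: per-batch GEMM on the contiguous [H*W, C] slab.
// [[Rcpp::export]]
NumericVector conv1x1_fwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector bias,
                              int H, int W, int C, int B, bool has_bias) {
  const int Cout = Wm.ncol();
  const size_t hw = (size_t)H * W;
  const arma::mat Wa(const_cast<double*>(Wm.begin()), C, Cout, false, true);
  NumericVector out(hw * Cout * B);
  const double* pb = REAL(bias);
  for (int b = 0; b < B; ++b) {
    const arma::mat Xb(const_cast<double*>(REAL(x)) + hw * C * b, hw, C, false, true);
    arma::mat Yb(REAL(out) + hw * Cout * b, hw, Cout, false, true);
    Yb = Xb * Wa;
    if (has_bias)
      for (int co = 0; co < Cout; ++co)
        Yb.col(co) += pb[co];
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return out;
}

// [[Rcpp::export]]
List conv1x1_bwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector dy,
                     int H, int W, int C, int B) {
  const int Cout = Wm.ncol();
  const size_t hw = (size_t)H * W;
  const arma::mat Wa(const_cast<double*>(Wm.begin()), C, Cout, false, true);
  NumericVector dx(hw * C * B);
  arma::mat dW(C, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  arma::rowvec dbv(Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat Xb(const_cast<double*>(REAL(x)) + hw * C * b, hw, C, false, true);
    const arma::mat dYb(const_cast<double*>(REAL(dy)) + hw * Cout * b, hw, Cout, false, true);
    arma::mat dXb(REAL(dx) + hw * C * b, hw, C, false, true);
    dXb = dYb * Wa.t();
    dW += Xb.t() * dYb;
    dbv += arma::sum(dYb, 0);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericMatrix dWr(C, Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  std::copy(dbv.begin(), dbv.end(), REAL(db));
  return List::create(Named("dx") = dx, Named("dW") = dWr, Named("db") = db);
}

// Batch-norm element work, fused: y = (x - mu[c]) * istd[c] * gamma[c] + beta[c]
// [[Rcpp::export]]
NumericVector bn_apply_cpp(NumericVector x, NumericVector mu, NumericVector istd,
                           NumericVector gamma, NumericVector beta,
                           int hw, int C, int B) {
  NumericVector out((size_t)hw * C * B);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double a = istd[c] * gamma[c];
      const double d = beta[c] - mu[c] * a;
      const double* sx = px + (size_t)hw * (c + (size_t)C * b);
      double* so = po + (size_t)hw * (c + (size_t)C * b);
      for (int i = 0; i < hw; ++i) so[i] = sx[i] * a + d;
    }
  out.attr("dim") = x.attr("dim");
  return out;
}

// per-channel sum and sum of squares
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int hw, int C, int B) {
  NumericVector s1(C), s2(C);
  const double* px = REAL(x);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* sx = px + (size_t)hw * (c + (size_t)C * b);
      double a = 0, q = 0;
      for (int i = 0; i < hw; ++i) { a += sx[i]; q += sx[i] * sx[i]; }
      s1[c] += a; s2[c] += q;
    }
  return List::create(Named("sum") = s1, Named("sumsq") = s2);
}

// fused BN backward; train = true uses the batch-statistics correction terms
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector mu,
                NumericVector istd, NumericVector gamma,
                int hw, int C, int B, bool train) {
  NumericVector dgamma(C), dbeta(C);
  const double* px = REAL(x);
  const double* pdy = REAL(dy);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)hw * (c + (size_t)C * b);
      const double* sx = px + off;
      const double* sd = pdy + off;
      double dg = 0, dbv = 0;
      for (int i = 0; i < hw; ++i) {
        dg += sd[i] * (sx[i] - mu[c]) * istd[c];
        dbv += sd[i];
      }
      dgamma[c] += dg; dbeta[c] += dbv;
    }
  NumericVector dx((size_t)hw * C * B);
  double* pdx = REAL(dx);
  const double m = (double)hw * B;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)hw * (c + (size_t)C * b);
      const double* sx = px + off;
      const double* sd = pdy + off;
      double* sdx = pdx + off;
      const double gi = gamma[c] * istd[c];
      if (train) {
        const double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
        for (int i = 0; i < hw; ++i)
          sdx[i] = gi * (sd[i] - t1 - (sx[i] - mu[c]) * istd[c] * t2);
      } else {
        for (int i = 0; i < hw; ++i) sdx[i] = gi * sd[i];
      }
    }
  dx.attr("dim") = x.attr("dim");
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* px = REAL(x); double* py = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  const double* py = REAL(y); const double* pd = REAL(dy); double* px = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) px[i] = py[i] > 0 ? pd[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Fused batch-norm + ReLU: y = max(0, (x - mu)*istd*gamma + beta)
// [[Rcpp::export]]
NumericVector bnrelu_fwd_cpp(NumericVector x, NumericVector mu, NumericVector istd,
                             NumericVector gamma, NumericVector beta,
                             int hw, int C, int B) {
  NumericVector out((size_t)hw * C * B);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double a = istd[c] * gamma[c];
      const double d = beta[c] - mu[c] * a;
      const double* sx = px + (size_t)hw * (c + (size_t)C * b);
      double* so = po + (size_t)hw * (c + (size_t)C * b);
      for (int i = 0; i < hw; ++i) {
        const double v = sx[i] * a + d;
        so[i] = v > 0 ? v : 0.0;
      }
    }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Fused backward of BN + ReLU.  y is the forward output (for the ReLU mask),
// x the BN input.
// [[Rcpp::export]]
List bnrelu_bwd_cpp(NumericVector x, NumericVector y, NumericVector dy,
                    NumericVector mu, NumericVector istd, NumericVector gamma,
                    int hw, int C, int B, bool train) {
  NumericVector dgamma(C), dbeta(C);
  const double* px = REAL(x);
  const double* py = REAL(y);
  const double* pdy = REAL(dy);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)hw * (c + (size_t)C * b);
      const double* sx = px + off;
      const double* sy = py + off;
      const double* sd = pdy + off;
      double dg = 0, dbv = 0;
      for (int i = 0; i < hw; ++i) {
        const double g = sy[i] > 0 ? sd[i] : 0.0;
        dg += g * (sx[i] - mu[c]) * istd[c];
        dbv += g;
      }
      dgamma[c] += dg; dbeta[c] += dbv;
    }
  NumericVector dx((size_t)hw * C * B);
  double* pdx = REAL(dx);
  const double m = (double)hw * B;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)hw * (c + (size_t)C * b);
      const double* sx = px + off;
      const double* sy = py + off;
      const double* sd = pdy + off;
      double* sdx = pdx + off;
      const double gi = gamma[c] * istd[c];
      if (train) {
        const double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
        for (int i = 0; i < hw; ++i) {
          const double g = sy[i] > 0 ? sd[i] : 0.0;
          sdx[i] = gi * (g - t1 - (sx[i] - mu[c]) * istd[c] * t2);
        }
      } else {
        for (int i = 0; i < hw; ++i)
          sdx[i] = sy[i] > 0 ? gi * sd[i] : 0.0;
      }
    }
  dx.attr("dim") = x.attr("dim");
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// ---- axis attention core ----------------------------------------------------
// axis_w: attention over image columns (n = W, feature length C*H with
// column index j = h + H*c); otherwise over rows (n = H, j = w + W*c).

static void att_pack(const double* x, int H, int W, int C, size_t off,
                     bool axis_w, arma::mat& M) {
  if (axis_w) {            // M(w, h + H*c)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const double* src = x + off + H * ((size_t)w + (size_t)W * c);
        for (int h = 0; h < H; ++h) M(w, h + (size_t)H * c) = src[h];
      }
  } else {                 // M(h, w + W*c)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const double* src = x + off + H * ((size_t)w + (size_t)W * c);
        for (int h = 0; h < H; ++h) M(h, w + (size_t)W * c) = src[h];
      }
  }
}

static void att_unpack_add(double* x, int H, int W, int C, size_t off,
                           bool axis_w, const arma::mat& M) {
  if (axis_w) {
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        double* dst = x + off + H * ((size_t)w + (size_t)W * c);
        for (int h = 0; h < H; ++h) dst[h] += M(w, h + (size_t)H * c);
      }
  } else {
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        double* dst = x + off + H * ((size_t)w + (size_t)W * c);
        for (int h = 0; h < H; ++h) dst[h] += M(h, w + (size_t)W * c);
      }
  }
}

static void att_softmax(arma::mat& S, bool as_printed) {
  if (as_printed) {        // normalise over the first index: columns sum to 1
    for (arma::uword j = 0; j < S.n_cols; ++j) {
      arma::vec col = S.col(j);
      col -= col.max();
      col = arma::exp(col);
      S.col(j) = col / arma::accu(col);
    }
  } else {
    for (arma::uword i = 0; i < S.n_rows; ++i) {
      arma::rowvec row = S.row(i);
      row -= row.max();
      row = arma::exp(row);
      S.row(i) = row / arma::accu(row);
    }
  }
}

// [[Rcpp::export]]
List axis_att_fwd_cpp(NumericVector q, NumericVector k, NumericVector v,
                      int H, int W, int C, int B, bool axis_w, bool as_printed) {
  const int n = axis_w ? W : H;
  const int f = axis_w ? C * H : C * W;
  NumericVector z((size_t)H * W * C * B);
  NumericVector Aout((size_t)n * n * B);
  arma::mat Qm(n, f), Km(n, f), Vm(n, f);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)H * W * C * b;
    att_pack(REAL(q), H, W, C, off, axis_w, Qm);
    att_pack(REAL(k), H, W, C, off, axis_w, Km);
    att_pack(REAL(v), H, W, C, off, axis_w, Vm);
    arma::mat A = Qm * Km.t();
    att_softmax(A, as_printed);
    // Z (f x n) = Vm^T (f x n) * A^T; stored back through the packed view:
    // Zpacked(n x f) = A * Vm
    arma::mat Zp = A * Vm;
    att_unpack_add(REAL(z), H, W, C, off, axis_w, Zp);
    std::copy(A.begin(), A.end(), REAL(Aout) + (size_t)n * n * b);
  }
  z.attr("dim") = IntegerVector::create(H, W, C, B);
  Aout.attr("dim") = IntegerVector::create(n, n, B);
  return List::create(Named("z") = z, Named("A") = Aout);
}

// [[Rcpp::export]]
List axis_att_bwd_cpp(NumericVector q, NumericVector k, NumericVector v,
                      NumericVector Aall, NumericVector dz,
                      int H, int W, int C, int B, bool axis_w, bool as_printed) {
  const int n = axis_w ? W : H;
  const int f = axis_w ? C * H : C * W;
  NumericVector dq((size_t)H * W * C * B), dk(dq.size()), dv(dq.size());
  arma::mat Qm(n, f), Km(n, f), Vm(n, f), dZp(n, f);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)H * W * C * b;
    att_pack(REAL(q), H, W, C, off, axis_w, Qm);
    att_pack(REAL(k), H, W, C, off, axis_w, Km);
    att_pack(REAL(v), H, W, C, off, axis_w, Vm);
    att_pack(REAL(dz), H, W, C, off, axis_w, dZp);
    const arma::mat A(const_cast<double*>(REAL(Aall)) + (size_t)n * n * b,
                      n, n, false, true);
    // Zp = A * Vm  =>  dVm = A^T * dZp ; dA = dZp * Vm^T
    arma::mat dVm = A.t() * dZp;
    arma::mat dA = dZp * Vm.t();
    arma::mat dS(n, n);
    if (as_printed) {
      for (int j = 0; j < n; ++j) {
        const double s = arma::dot(dA.col(j), A.col(j));
        dS.col(j) = (dA.col(j) - s) % A.col(j);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double s = arma::dot(dA.row(i), A.row(i));
        dS.row(i) = (dA.row(i) - s) % A.row(i);
      }
    }
    arma::mat dQm = dS * Km;
    arma::mat dKm = dS.t() * Qm;
    att_unpack_add(REAL(dq), H, W, C, off, axis_w, dQm);
    att_unpack_add(REAL(dk), H, W, C, off, axis_w, dKm);
    att_unpack_add(REAL(dv), H, W, C, off, axis_w, dVm);
  }
  dq.attr("dim") = IntegerVector::create(H, W, C, B);
  dk.attr("dim") = dq.attr("dim");
  dv.attr("dim") = dq.attr("dim");
  return List::create(Named("dq") = dq, Named("dk") = dk, Named("dv") = dv);
}
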