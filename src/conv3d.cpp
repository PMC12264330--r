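// 3D convolution primitives used by the U-Net backbone.
//
// Array layout follows R column-major order throughout: a volume is an
// R array with dim (D, H, W, C), so index = d + D*(h + H*(w + W*c)) and each
// channel occupies a contiguous block of D*H*W values.  Convolutions are
// lowered to dense matrix products (im2col + dgemm), which is where almost
// all training time is spent.
//
// Weight layout: conv kernels are R arrays with dim (k, k, k, Cin, Cout);
// flattened, this is exactly the (k^3*Cin) x Cout matrix the gemm needs.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Valid output range [lo, hi) for one kernel tap along one axis:
// input index i = o * stride + koff - pad must lie in [0, n).
static inline void tap_range(int n_out, int n_in, int koff, int stride,
                             int pad, int& lo, int& hi) {
  lo = 0;
  while (lo < n_out && lo * stride + koff - pad < 0) ++lo;
  hi = n_out;
  while (hi > lo && (hi - 1) * stride + koff - pad >= n_in) --hi;
}

// Fill the im2col matrix: rows = output voxels (d fastest, then h, then w),
// cols = kernel taps in (kd, kh, kw, cin) order. Out-of-bounds taps are zero.
// The innermost (slice) axis is copied as a contiguous run when stride == 1.
static void im2col(const double* x, int D, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& col) {
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const long DHW = (long)D * H * W;
  col.zeros();
  long cidx = 0;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + ci * DHW;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          double* colp = col.colptr(cidx++);
          int d0, d1, h0, h1, w0, w1;
          tap_range(Do, D, kd, stride, pad, d0, d1);
          tap_range(Ho, H, kh, stride, pad, h0, h1);
          tap_range(Wo, W, kw, stride, pad, w0, w1);
          for (int wo = w0; wo < w1; ++wo) {
            const int wi = wo * stride + kw - pad;
            for (int ho = h0; ho < h1; ++ho) {
              const int hi = ho * stride + kh - pad;
              const double* src = xc + ((long)wi * H + hi) * D + (kd - pad);
              double* dst = colp + ((long)wo * Ho + ho) * Do;
              if (stride == 1) {
                std::memcpy(dst + d0, src + d0, (d1 - d0) * sizeof(double));
              } else {
                for (int dout = d0; dout < d1; ++dout)
                  dst[dout] = src[dout * stride];
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col (used for the data gradient).
static void col2im(const arma::mat& col, int D, int H, int W, int C,
                   int k, int stride, int pad, double* dx) {
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const long DHW = (long)D * H * W;
  std::fill(dx, dx + DHW * C, 0.0);
  long cidx = 0;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + ci * DHW;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const double* colp = col.colptr(cidx++);
          int d0, d1, h0, h1, w0, w1;
          tap_range(Do, D, kd, stride, pad, d0, d1);
          tap_range(Ho, H, kh, stride, pad, h0, h1);
          tap_range(Wo, W, kw, stride, pad, w0, w1);
          for (int wo = w0; wo < w1; ++wo) {
            const int wi = wo * stride + kw - pad;
            for (int ho = h0; ho < h1; ++ho) {
              const int hi = ho * stride + kh - pad;
              double* dst = xc + ((long)wi * H + hi) * D + (kd - pad);
              const double* src = colp + ((long)wo * Ho + ho) * Do;
              if (stride == 1) {
                for (int dout = d0; dout < d1; ++dout) dst[dout] += src[dout];
              } else {
                for (int dout = d0; dout < d1; ++dout)
                  dst[dout * stride] += src[dout];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, int k, int cin, int cout,
                         NumericVector b, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const long nvox = (long)Do * Ho * Wo;
  arma::mat col(nvox, (long)k * k * k * cin);
  im2col(x.begin(), D, H, W, cin, k, stride, pad, col);
  const arma::mat wm(const_cast<double*>(w.begin()), (long)k * k * k * cin,
                     cout, false, true);
  arma::mat y = col * wm;
  y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), cout, false, true);
  NumericVector out(y.memptr(), y.memptr() + nvox * cout);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, int k, int cin, int cout,
                NumericVector dy, int stride, int pad,
                bool need_dx, bool need_dw) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = out_dim(D, k, stride, pad);
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const long nvox = (long)Do * Ho * Wo;
  const long kc = (long)k * k * k * cin;
  const arma::mat dym(const_cast<double*>(dy.begin()), nvox, cout, false, true);
  const arma::mat wm(const_cast<double*>(w.begin()), kc, cout, false, true);

  List out;
  out["db"] = NumericVector(wrap(arma::conv_to<std::vector<double>>::from(
      arma::sum(dym, 0).t())));

  if (need_dw) {
    arma::mat col(nvox, kc);
    im2col(x.begin(), D, H, W, cin, k, stride, pad, col);
    arma::mat dwm = col.t() * dym;
    NumericVector dw(dwm.memptr(), dwm.memptr() + kc * cout);
    dw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
    out["dw"] = dw;
  }
  if (need_dx) {
    arma::mat dcol = dym * wm.t();
    NumericVector dx(x.size());
    col2im(dcol, D, H, W, cin, k, stride, pad, dx.begin());
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  return out;
}

// Transposed convolution with kernel 2, stride 2 (exact 2x upsampling).
// Output blocks are non-overlapping, so the op is a per-voxel gemm followed
// by a gather/scatter.  Weight layout: (2, 2, 2, Cin, Cout).

// [[Rcpp::export(name = ".tconv3d_fwd")]]
NumericVector tconv3d_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, int cin, int cout,
                          NumericVector b) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const long nvox = (long)D * H * W;
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  const arma::mat xm(const_cast<double*>(x.begin()), nvox, cin, false, true);
  // Rearrange w[kd,kh,kw,ci,co] into (cin) x (8*cout) with tap fastest.
  arma::mat wr(cin, 8 * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int o = 0; o < 8; ++o)
        wr(ci, o + 8 * co) = wp[o + 8 * (ci + (long)cin * co)];
  arma::mat yb = xm * wr;  // nvox x (8*cout)
  NumericVector y((long)Do * Ho * Wo * cout);
  double* yp = y.begin();
  const long DHWo = (long)Do * Ho * Wo;
  for (int co = 0; co < cout; ++co) {
    double* yc = yp + co * DHWo;
    for (long wi = 0; wi < W; ++wi)
      for (long hi = 0; hi < H; ++hi)
        for (long di = 0; di < D; ++di) {
          const long v = di + D * (hi + H * wi);
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                const int o = kd + 2 * kh + 4 * kw;
                yc[(2 * di + kd) + (long)Do * ((2 * hi + kh) + (long)Ho * (2 * wi + kw))] =
                    yb(v, o + 8 * co) + b[co];
              }
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, cout);
  return y;
}

// [[Rcpp::export(name = ".tconv3d_bwd")]]
List tconv3d_bwd(NumericVector x, IntegerVector xdim,
                 NumericVector w, int cin, int cout,
                 NumericVector dy, bool need_dx, bool need_dw) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const long nvox = (long)D * H * W;
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  const long DHWo = (long)Do * Ho * Wo;
  const double* dyp = dy.begin();

  arma::mat dyb(nvox, 8 * cout);
  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) {
    const double* dyc = dyp + co * DHWo;
    double s = 0.0;
    for (long wi = 0; wi < W; ++wi)
      for (long hi = 0; hi < H; ++hi)
        for (long di = 0; di < D; ++di) {
          const long v = di + D * (hi + H * wi);
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                const int o = kd + 2 * kh + 4 * kw;
                const double g = dyc[(2 * di + kd) +
                    (long)Do * ((2 * hi + kh) + (long)Ho * (2 * wi + kw))];
                dyb(v, o + 8 * co) = g;
                s += g;
              }
        }
    db[co] = s;
  }

  arma::mat wr(cin, 8 * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int o = 0; o < 8; ++o)
        wr(ci, o + 8 * co) = wp[o + 8 * (ci + (long)cin * co)];

  List out;
  out["db"] = db;
  if (need_dw) {
    const arma::mat xm(const_cast<double*>(x.begin()), nvox, cin, false, true);
    arma::mat dwr = xm.t() * dyb;  // cin x 8cout
    NumericVector dw(w.size());
    double* dwp = dw.begin();
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        for (int o = 0; o < 8; ++o)
          dwp[o + 8 * (ci + (long)cin * co)] = dwr(ci, o + 8 * co);
    dw.attr("dim") = IntegerVector::create(2, 2, 2, cin, cout);
    out["dw"] = dw;
  }
  if (need_dx) {
    arma::mat dxm = dyb * wr.t();
    NumericVector dx(dxm.memptr(), dxm.memptr() + nvox * cin);
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  return out;
}

// Group normalization over contiguous channel blocks (channels are the
// trailing array dimension).  Population variance, matching the R-side
// conventions elsewhere in the package.

// [[Rcpp::export(name = ".gn_fwd_cpp")]]
List gn_fwd_cpp(NumericVector x, long nvox, int C, int groups,
                NumericVector gamma, NumericVector beta, double eps) {
  const int cg = C / groups;
  NumericVector y(x.size()), xhat(x.size()), inv_std(groups);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* xhp = xhat.begin();
  const long glen = (long)cg * nvox;
  for (int g = 0; g < groups; ++g) {
    const double* v = xp + g * glen;
    double s = 0, s2 = 0;
    for (long i = 0; i < glen; ++i) { s += v[i]; s2 += v[i] * v[i]; }
    const double mu = s / glen;
    const double istd = 1.0 / std::sqrt(s2 / glen - mu * mu + eps);
    inv_std[g] = istd;
    for (int j = 0; j < cg; ++j) {
      const int c = g * cg + j;
      const double ga = gamma[c], be = beta[c];
      const long off = g * glen + (long)j * nvox;
      for (long i = 0; i < nvox; ++i) {
        const double xh = (v[(long)j * nvox + i] - mu) * istd;
        xhp[off + i] = xh;
        yp[off + i] = xh * ga + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_std"] = inv_std);
}

// [[Rcpp::export(name = ".gn_bwd_cpp")]]
List gn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector inv_std,
                NumericVector gamma, long nvox, int C, int groups) {
  const int cg = C / groups;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  const double* dyp = dy.begin();
  const double* xhp = xhat.begin();
  double* dxp = dx.begin();
  const long glen = (long)cg * nvox;
  std::vector<double> dxh(glen);
  for (int g = 0; g < groups; ++g) {
    const long goff = g * glen;
    double m1 = 0, m2 = 0;
    for (int j = 0; j < cg; ++j) {
      const int c = g * cg + j;
      const long off = goff + (long)j * nvox;
      double sg = 0, sb = 0;
      const double ga = gamma[c];
      for (long i = 0; i < nvox; ++i) {
        const double d = dyp[off + i];
        const double xh = xhp[off + i];
        sg += d * xh;
        sb += d;
        const double t = d * ga;
        dxh[(long)j * nvox + i] = t;
        m1 += t;
        m2 += t * xh;
      }
      dgamma[c] = sg;
      dbeta[c] = sb;
    }
    m1 /= glen;
    m2 /= glen;
    const double istd = inv_std[g];
    for (long i = 0; i < glen; ++i) {
      dxp[goff + i] = istd * (dxh[i] - m1 - xhp[goff + i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long i = 0; i < (long)x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// dy * (act > 0), where act is the post-ReLU activation
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector act) {
  NumericVector dx(dy.size());
  const double* dp = dy.begin();
  const double* ap = act.begin();
  double* xp = dx.begin();
  for (long i = 0; i < (long)dy.size(); ++i) xp[i] = ap[i] > 0 ? dp[i] : 0.0;
  return dx;
}
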