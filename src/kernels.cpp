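// Numerical kernels for the autodiff core: im2col convolution, pooling,
// bilinear resampling and affine warps. Feature tensors are R arrays with
// dim (H, W, C, N), column-major, so element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword off4(int h, int w, int c, int n, int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w + (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// im2col for a single image into a caller-provided (H*W) x (kh*kw*C*?)
// buffer at column offset qoff: zero padding written inline (stride 1,
// pad = (k-1)/2). Row index is the output pixel h + H*w.
static void im2col_fill(const double* x, int H, int W, int C, int n,
                        int kh, int kw, double* colbase, arma::uword ldc) {
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + off4(0, 0, c, n, H, W, C);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int q = dh + kh * (dw + kw * c);
        double* colq = colbase + (arma::uword)q * ldc;
        for (int w = 0; w < W; ++w) {
          int wi = w + dw - pw;
          double* dst = colq + (arma::uword)H * w;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (arma::uword)H * wi;
          int h0 = std::max(0, ph - dh), h1 = std::min(H, H + ph - dh);
          for (int h = 0; h < h0; ++h) dst[h] = 0.0;
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dh - ph];
          for (int h = h1; h < H; ++h) dst[h] = 0.0;
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, double* x, int n) {
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + off4(0, 0, c, n, H, W, C);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int q = dh + kh * (dw + kw * c);
        const double* colq = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          int wi = w + dw - pw;
          if (wi < 0 || wi >= W) continue;
          double* dst = xc + (arma::uword)H * wi;
          const double* src = colq + (arma::uword)H * w;
          int h0 = std::max(0, ph - dh), h1 = std::min(H, H + ph - dh);
          for (int h = h0; h < h1; ++h) dst[h + dh - ph] += src[h];
        }
      }
    }
  }
}

// x: (H,W,Cin,N); w: (kh,kw,Cin,Cout) flattened column-major so that
// reshaping to (kh*kw*Cin, Cout) matches im2col column order; b: (Cout).
// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, IntegerVector xdim,
                                 IntegerVector wdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int K = kh * kw * C;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  arma::mat Wm(w.begin(), (arma::uword)K, (arma::uword)Cout, false);
  arma::vec bv(b.begin(), Cout, false);
  arma::mat col((arma::uword)(H * W), (arma::uword)K);
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin(), H, W, C, n, kh, kw, col.memptr(),
                (arma::uword)(H * W));
    arma::mat Ym(y.begin() + off4(0, 0, 0, n, H, W, Cout),
                 (arma::uword)(H * W), (arma::uword)Cout, false, true);
    Ym = col * Wm;
    Ym.each_row() += bv.t();
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         IntegerVector xdim, IntegerVector wdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int K = kh * kw * C;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)K * Cout);
  NumericVector db((R_xlen_t)Cout);
  arma::mat Wm(w.begin(), (arma::uword)K, (arma::uword)Cout, false);
  arma::mat dWm(dw.begin(), (arma::uword)K, (arma::uword)Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col((arma::uword)(H * W), (arma::uword)K), dcol;
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin(), H, W, C, n, kh, kw, col.memptr(),
                (arma::uword)(H * W));
    arma::mat dYm(dy.begin() + off4(0, 0, 0, n, H, W, Cout),
                  (arma::uword)(H * W), (arma::uword)Cout, false);
    dWm += col.t() * dYm;
    dbv += arma::sum(dYm, 0).t();
    dcol = dYm * Wm.t();
    col2im(dcol, H, W, C, kh, kw, dx.begin(), n);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (0-based into the input array) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  NumericVector idx((R_xlen_t)Ho * Wo * C * N);
  R_xlen_t k = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1e300; arma::uword bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              arma::uword i = off4(2 * h + dh, 2 * w + dw, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          y[k] = best; idx[k] = (double)bi; ++k;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, NumericVector idx,
                                    IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[(R_xlen_t)idx[k]] += dy[k];
  dx.attr("dim") = xdim;
  return dx;
}

// Bilinear x2 upsampling with corner alignment: src = dst * (in-1)/(out-1).
static inline void lin_coef(int o, int in, int out, int& i0, int& i1, double& t) {
  double s = (out > 1) ? (double)o * (in - 1) / (out - 1) : 0.0;
  i0 = (int)std::floor(s);
  if (i0 > in - 2) i0 = std::max(0, in - 2);
  i1 = std::min(in - 1, i0 + 1);
  t = s - i0;
  if (in == 1) { i0 = i1 = 0; t = 0.0; }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + off4(0, 0, c, n, H, W, C);
      double* yc = y.begin() + off4(0, 0, c, n, Ho, Wo, C);
      for (int w = 0; w < Wo; ++w) {
        int w0, w1; double tw; lin_coef(w, W, Wo, w0, w1, tw);
        for (int h = 0; h < Ho; ++h) {
          int h0, h1; double th; lin_coef(h, H, Ho, h0, h1, th);
          yc[h + (arma::uword)Ho * w] =
            (1 - th) * (1 - tw) * xc[h0 + (arma::uword)H * w0] +
            th * (1 - tw) * xc[h1 + (arma::uword)H * w0] +
            (1 - th) * tw * xc[h0 + (arma::uword)H * w1] +
            th * tw * xc[h1 + (arma::uword)H * w1];
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + off4(0, 0, c, n, H, W, C);
      const double* yc = dy.begin() + off4(0, 0, c, n, Ho, Wo, C);
      for (int w = 0; w < Wo; ++w) {
        int w0, w1; double tw; lin_coef(w, W, Wo, w0, w1, tw);
        for (int h = 0; h < Ho; ++h) {
          int h0, h1; double th; lin_coef(h, H, Ho, h0, h1, th);
          double g = yc[h + (arma::uword)Ho * w];
          xc[h0 + (arma::uword)H * w0] += (1 - th) * (1 - tw) * g;
          xc[h1 + (arma::uword)H * w0] += th * (1 - tw) * g;
          xc[h0 + (arma::uword)H * w1] += (1 - th) * tw * g;
          xc[h1 + (arma::uword)H * w1] += th * tw * g;
        }
      }
    }
  dx.attr("dim") = xdim;
  return dx;
}

// Affine warp of a single-channel image. m = (a,b,c,d,e,f) maps OUTPUT pixel
// coordinates (x, y), 0-based, to input coordinates: xs = a*x + b*y + c,
// ys = d*x + e*y + f. bilinear=FALSE gives nearest-neighbour (for masks).
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector m,
                              int Ho, int Wo, bool bilinear, double fill) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Ho, Wo);
  double a = m[0], b = m[1], c = m[2], d = m[3], e = m[4], f = m[5];
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h) {
      double xs = a * w + b * h + c;
      double ys = d * w + e * h + f;
      if (bilinear) {
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        double tx = xs - x0, ty = ys - y0;
        double acc = 0.0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dyy = 0; dyy < 2; ++dyy) {
            int xi = x0 + dx, yi = y0 + dyy;
            double wgt = (dx ? tx : 1 - tx) * (dyy ? ty : 1 - ty);
            double v = (xi >= 0 && xi < W && yi >= 0 && yi < H) ? img(yi, xi) : fill;
            acc += wgt * v;
          }
        out(h, w) = acc;
      } else {
        int xi = (int)std::lround(xs), yi = (int)std::lround(ys);
        out(h, w) = (xi >= 0 && xi < W && yi >= 0 && yi < H) ? img(yi, xi) : fill;
      }
    }
  return out;
}

// 1-D zero-padded convolution over the channel axis (one shared kernel),
// used by the channel-attention unit. x: (C, N); k odd.
// [[Rcpp::export]]
NumericMatrix cpp_conv1d_channels(NumericMatrix x, NumericVector k) {
  int C = x.nrow(), N = x.ncol(), K = k.size(), p = (K - 1) / 2;
  NumericMatrix y(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) {
        int ci = c + j - p;
        if (ci >= 0 && ci < C) acc += k[j] * x(ci, n);
      }
      y(c, n) = acc;
    }
  return y;
}

// Backward of the above: returns dx (C,N) and dk (K).
// [[Rcpp::export]]
List cpp_conv1d_channels_backward(NumericMatrix x, NumericVector k,
                                  NumericMatrix dy) {
  int C = x.nrow(), N = x.ncol(), K = k.size(), p = (K - 1) / 2;
  NumericMatrix dx(C, N);
  NumericVector dk(K);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double g = dy(c, n);
      for (int j = 0; j < K; ++j) {
        int ci = c + j - p;
        if (ci >= 0 && ci < C) {
          dx(ci, n) += k[j] * g;
          dk[j] += x(ci, n) * g;
        }
      }
    }
  return List::create(_["dx"] = dx, _["dk"] = dk);
}

// y[i] = x[i] * scale[c] + shift[c] over an (H,W,C,N) array - one pass,
// used by batch normalization.
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector scale,
                              NumericVector shift, IntegerVector xdim) {
  int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y(no_init(x.size()));
  const double* xp = x.begin(); double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double a = scale[c], b = shift[c];
      R_xlen_t o = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      for (int i = 0; i < HW; ++i) yp[o + i] = a * xp[o + i] + b;
    }
  y.attr("dim") = xdim;
  return y;
}

// Training-mode batchnorm input gradient in one pass:
// dx[i] = coef[c] * (M * dy[i] - db[c] - xhat[i] * dg[c]).
// [[Rcpp::export]]
NumericVector cpp_bn_dx(NumericVector dy, NumericVector xhat,
                        NumericVector db, NumericVector dg,
                        NumericVector coef, double M, IntegerVector xdim) {
  int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx(no_init(dy.size()));
  const double* dyp = dy.begin(); const double* xh = xhat.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double k = coef[c], b = db[c], g = dg[c];
      R_xlen_t o = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      for (int i = 0; i < HW; ++i)
        dxp[o + i] = k * (M * dyp[o + i] - b - xh[o + i] * g);
    }
  dx.attr("dim") = xdim;
  return dx;
}
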