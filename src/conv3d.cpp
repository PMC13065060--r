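// 3-D convolution primitives for the spectral-preserving network.
//
// Tensors are R arrays with dim c(B, C, F, H, W) in R's column-major order,
// i.e. linear index b + B*(c + C*(f + F*(h + H*w))), all 0-based here.
// The energy axis F is the first "depth" axis of the 3-D convolution; strides
// along it are always 1 in the network, but the kernels are generic.
//
// Forward and both backward passes go through an explicit im2col buffer and a
// single BLAS gemm per batch item.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline void dims5(const IntegerVector &d, int &B, int &C, int &F,
                         int &H, int &W) {
  B = d[0]; C = d[1]; F = d[2]; H = d[3]; W = d[4];
}

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Reusable scratch buffers: conv workspaces are tens of MB and re-allocating
// them on every call costs more than the gemm itself.
static arma::mat &scratch(int which, std::size_t nr, std::size_t nc) {
  static arma::mat bufs[3];
  arma::mat &m = bufs[which];
  if (m.n_rows != nr || m.n_cols != nc) m.set_size(nr, nc);
  return m;
}

// B == 1 specialization: the (C, F, H, W) layout is channel-contiguous at a
// fixed voxel, so each tap copies one contiguous Cin block.
static void im2col_b1(const double *x, int Cin, int F, int H, int W,
                      int kf, int kh, int kw, int sf, int sh, int sw,
                      int pf, int ph, int pw, int Fo, int Ho, int Wo,
                      arma::mat &col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int fo = 0; fo < Fo; ++fo) {
        double *cp = col.colptr(fo + Fo * (ho + Ho * wo));
        for (int l = 0; l < kw; ++l) {
          const int wv = wo * sw - pw + l;
          const bool wok = wv >= 0 && wv < W;
          for (int j = 0; j < kh; ++j) {
            const int hv = ho * sh - ph + j;
            const bool hok = wok && hv >= 0 && hv < H;
            for (int i = 0; i < kf; ++i) {
              const int fv = fo * sf - pf + i;
              double *dst = cp + (std::size_t)Cin * (i + kf * (j + kh * l));
              if (!hok || fv < 0 || fv >= F) {
                std::memset(dst, 0, sizeof(double) * Cin);
              } else {
                const double *xp = x + (std::size_t)Cin *
                  (fv + (std::size_t)F * (hv + (std::size_t)H * wv));
                std::memcpy(dst, xp, sizeof(double) * Cin);
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_add_b1(double *dx, int Cin, int F, int H, int W,
                          int kf, int kh, int kw, int sf, int sh, int sw,
                          int pf, int ph, int pw, int Fo, int Ho, int Wo,
                          const arma::mat &col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int fo = 0; fo < Fo; ++fo) {
        const double *cp = col.colptr(fo + Fo * (ho + Ho * wo));
        for (int l = 0; l < kw; ++l) {
          const int wv = wo * sw - pw + l;
          if (wv < 0 || wv >= W) continue;
          for (int j = 0; j < kh; ++j) {
            const int hv = ho * sh - ph + j;
            if (hv < 0 || hv >= H) continue;
            for (int i = 0; i < kf; ++i) {
              const int fv = fo * sf - pf + i;
              if (fv < 0 || fv >= F) continue;
              double *xp = dx + (std::size_t)Cin *
                (fv + (std::size_t)F * (hv + (std::size_t)H * wv));
              const double *s = cp + (std::size_t)Cin * (i + kf * (j + kh * l));
              for (int cin = 0; cin < Cin; ++cin) xp[cin] += s[cin];
            }
          }
        }
      }
    }
  }
}

// Fill col (K x Npos) from x[b, ...]; K = Cin*kf*kh*kw, Npos = Fo*Ho*Wo.
static void im2col(const double *x, int b, int B, int Cin, int F, int H, int W,
                   int kf, int kh, int kw, int sf, int sh, int sw,
                   int pf, int ph, int pw, int Fo, int Ho, int Wo,
                   arma::mat &col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int fo = 0; fo < Fo; ++fo) {
        const int pos = fo + Fo * (ho + Ho * wo);
        double *cp = col.colptr(pos);
        for (int l = 0; l < kw; ++l) {
          const int wv = wo * sw - pw + l;
          const bool wok = wv >= 0 && wv < W;
          for (int j = 0; j < kh; ++j) {
            const int hv = ho * sh - ph + j;
            const bool hok = wok && hv >= 0 && hv < H;
            for (int i = 0; i < kf; ++i) {
              const int fv = fo * sf - pf + i;
              double *dst = cp + (std::size_t)Cin * (i + kf * (j + kh * l));
              if (!hok || fv < 0 || fv >= F) {
                for (int cin = 0; cin < Cin; ++cin) dst[cin] = 0.0;
                continue;
              }
              const double *xp = x + b + (std::size_t)B *
                (std::size_t)Cin * (fv + (std::size_t)F * (hv + (std::size_t)H * wv));
              // stride between consecutive cin at fixed (f,h,w) is B in x
              for (int cin = 0; cin < Cin; ++cin)
                dst[cin] = xp[(std::size_t)B * cin];
            }
          }
        }
      }
    }
  }
}

// Scatter-add col (K x Npos) back into dx[b, ...] (inverse of im2col).
static void col2im_add(double *dx, int b, int B, int Cin, int F, int H, int W,
                       int kf, int kh, int kw, int sf, int sh, int sw,
                       int pf, int ph, int pw, int Fo, int Ho, int Wo,
                       const arma::mat &col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int fo = 0; fo < Fo; ++fo) {
        const int pos = fo + Fo * (ho + Ho * wo);
        const double *cp = col.colptr(pos);
        for (int l = 0; l < kw; ++l) {
          const int wv = wo * sw - pw + l;
          if (wv < 0 || wv >= W) continue;
          for (int j = 0; j < kh; ++j) {
            const int hv = ho * sh - ph + j;
            if (hv < 0 || hv >= H) continue;
            for (int i = 0; i < kf; ++i) {
              const int fv = fo * sf - pf + i;
              if (fv < 0 || fv >= F) continue;
              double *xp = dx + b + (std::size_t)B *
                (0 + (std::size_t)Cin * (fv + (std::size_t)F * (hv + (std::size_t)H * wv)));
              const double *src = cp + (std::size_t)Cin * (i + kf * (j + kh * l));
              for (int cin = 0; cin < Cin; ++cin)
                xp[(std::size_t)B * cin] += src[cin];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector bias, IntegerVector stride,
                         IntegerVector pad) {
  int B, Cin, F, H, W;
  dims5(xdim, B, Cin, F, H, W);
  const int Cout = wdim[0], kf = wdim[2], kh = wdim[3], kw = wdim[4];
  if (wdim[1] != Cin) stop("conv3d: channel mismatch");
  const int sf = stride[0], sh = stride[1], sw = stride[2];
  const int pf = pad[0], ph = pad[1], pw = pad[2];
  const int Fo = out_extent(F, kf, sf, pf);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  const int K = Cin * kf * kh * kw;
  const std::size_t Npos = (std::size_t)Fo * Ho * Wo;

  NumericVector y((std::size_t)B * Cout * Npos);
  y.attr("dim") = IntegerVector::create(B, Cout, Fo, Ho, Wo);
  arma::mat Wm(const_cast<double *>(w.begin()), Cout, K, false, true);
  arma::mat &col = scratch(0, K, Npos);
  if (B == 1) {
    // batch-1 tensors are (C, F, H, W)-contiguous: gemm straight into y
    im2col_b1(x.begin(), Cin, F, H, W, kf, kh, kw, sf, sh, sw,
              pf, ph, pw, Fo, Ho, Wo, col);
    arma::mat Ydirect(y.begin(), Cout, Npos, false, true);
    Ydirect = Wm * col;  // gemm
    double *yp = y.begin();
    for (std::size_t pos = 0; pos < Npos; ++pos)
      for (int cout = 0; cout < Cout; ++cout)
        yp[cout + (std::size_t)Cout * pos] += bias[cout];
    return y;
  }
  arma::mat &Y = scratch(1, Cout, Npos);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin(), b, B, Cin, F, H, W, kf, kh, kw, sf, sh, sw,
           pf, ph, pw, Fo, Ho, Wo, col);
    Y = Wm * col;  // gemm
    double *yp = y.begin();
    for (std::size_t pos = 0; pos < Npos; ++pos) {
      const double *yc = Y.colptr(pos);
      for (int cout = 0; cout < Cout; ++cout)
        yp[b + (std::size_t)B * (cout + (std::size_t)Cout * pos)] =
          yc[cout] + bias[cout];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd_data")]]
NumericVector conv3d_bwd_data(NumericVector dy, IntegerVector ydim,
                              NumericVector w, IntegerVector wdim,
                              IntegerVector xdim, IntegerVector stride,
                              IntegerVector pad) {
  int B, Cout, Fo, Ho, Wo;
  dims5(ydim, B, Cout, Fo, Ho, Wo);
  int Bx, Cin, F, H, W;
  dims5(xdim, Bx, Cin, F, H, W);
  const int kf = wdim[2], kh = wdim[3], kw = wdim[4];
  const int sf = stride[0], sh = stride[1], sw = stride[2];
  const int pf = pad[0], ph = pad[1], pw = pad[2];
  const int K = Cin * kf * kh * kw;
  const std::size_t Npos = (std::size_t)Fo * Ho * Wo;

  NumericVector dx((std::size_t)B * Cin * F * H * W);
  dx.attr("dim") = xdim;
  arma::mat Wm(const_cast<double *>(w.begin()), Cout, K, false, true);
  arma::mat &dcol = scratch(1, K, Npos);
  if (B == 1) {
    arma::mat dYdirect(const_cast<double *>(dy.begin()), Cout, Npos, false, true);
    dcol = Wm.t() * dYdirect;  // gemm
    col2im_add_b1(dx.begin(), Cin, F, H, W, kf, kh, kw, sf, sh, sw,
                  pf, ph, pw, Fo, Ho, Wo, dcol);
    return dx;
  }
  arma::mat &dYm = scratch(0, Cout, Npos);
  for (int b = 0; b < B; ++b) {
    const double *dyp = dy.begin();
    for (std::size_t pos = 0; pos < Npos; ++pos) {
      double *dc = dYm.colptr(pos);
      for (int cout = 0; cout < Cout; ++cout)
        dc[cout] = dyp[b + (std::size_t)B * (cout + (std::size_t)Cout * pos)];
    }
    dcol = Wm.t() * dYm;  // gemm
    col2im_add(dx.begin(), b, B, Cin, F, H, W, kf, kh, kw, sf, sh, sw,
               pf, ph, pw, Fo, Ho, Wo, dcol);
  }
  return dx;
}

// [[Rcpp::export(name = ".conv3d_bwd_filter")]]
List conv3d_bwd_filter(NumericVector x, IntegerVector xdim,
                       NumericVector dy, IntegerVector ydim,
                       IntegerVector wdim, IntegerVector stride,
                       IntegerVector pad) {
  int B, Cin, F, H, W;
  dims5(xdim, B, Cin, F, H, W);
  int By, Cout, Fo, Ho, Wo;
  dims5(ydim, By, Cout, Fo, Ho, Wo);
  const int kf = wdim[2], kh = wdim[3], kw = wdim[4];
  const int sf = stride[0], sh = stride[1], sw = stride[2];
  const int pf = pad[0], ph = pad[1], pw = pad[2];
  const int K = Cin * kf * kh * kw;
  const std::size_t Npos = (std::size_t)Fo * Ho * Wo;

  NumericVector dw((std::size_t)Cout * K);
  dw.attr("dim") = wdim;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), Cout, K, false, true);
  arma::mat &col = scratch(0, K, Npos);
  arma::vec dbv(db.begin(), Cout, false, true);
  if (B == 1) {
    im2col_b1(x.begin(), Cin, F, H, W, kf, kh, kw, sf, sh, sw,
              pf, ph, pw, Fo, Ho, Wo, col);
    arma::mat dYdirect(const_cast<double *>(dy.begin()), Cout, Npos, false, true);
    dWm += dYdirect * col.t();
    dbv += arma::sum(dYdirect, 1);
    return List::create(_["dw"] = dw, _["db"] = db);
  }
  arma::mat &dYm = scratch(1, Cout, Npos);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin(), b, B, Cin, F, H, W, kf, kh, kw, sf, sh, sw,
           pf, ph, pw, Fo, Ho, Wo, col);
    const double *dyp = dy.begin();
    for (std::size_t pos = 0; pos < Npos; ++pos) {
      double *dc = dYm.colptr(pos);
      for (int cout = 0; cout < Cout; ++cout)
        dc[cout] = dyp[b + (std::size_t)B * (cout + (std::size_t)Cout * pos)];
    }
    dWm += dYm * col.t();
    dbv += arma::sum(dYm, 1);
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}
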