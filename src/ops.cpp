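// Low-level numerical kernels for the DenseNet engine and image geometry.
// Tensors use R's column-major layout: feature stacks are (H, W, C, N)
// arrays, convolution weights are (kh, kw, C, F).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold one (H, W, C) sample into a (kh*kw*C) x (Ho*Wo) patch matrix.
// Row index r = khi + kh*(kwi + kw*c) matches the column-major reshape of
// the (kh, kw, C, F) weight array, so convolution becomes a single GEMM.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kwi;
          double* colp = col.colptr(0) + r; // stride between columns = K
          const int K = col.n_rows;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              colp[(R_xlen_t)K * (ho + (R_xlen_t)Ho * wo)] = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + khi;
            double v = (hi >= 0 && hi < H) ? xc[hi + (R_xlen_t)H * wi] : 0.0;
            colp[(R_xlen_t)K * (ho + (R_xlen_t)Ho * wo)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of a patch matrix back onto the (H, W, C) input gradient.
static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  const int K = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (R_xlen_t)H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        const double* colp = col.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kwi;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + khi;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (R_xlen_t)H * wi] +=
              colp[(R_xlen_t)K * (ho + (R_xlen_t)Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("conv2d: weight channel mismatch");
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: spatial underflow");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat wmat(w.begin(), K, F, false, true);
  arma::rowvec bv(b.begin(), F, false, true);
  NumericVector y((R_xlen_t)P * F * N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat ymat(y.begin() + (R_xlen_t)P * F * n, P, F, false, true);
    ymat = col.t() * wmat;
    ymat.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat wmat(w.begin(), K, F, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)K * F);
  NumericVector db(F);
  arma::mat dwmat(dw.begin(), K, F, false, true);
  arma::vec dbv(db.begin(), F, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat dymat(dy.begin() + (R_xlen_t)P * F * n, P, F, false, true);
    dwmat += col * dymat;
    dbv += arma::sum(dymat, 0).t();
    arma::mat dcol = wmat * dymat.t(); // K x P
    col2im_add(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dx.begin() + (R_xlen_t)H * W * C * n);
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling; out-of-frame positions act as -Inf padding. Returns the
// pooled stack plus 0-based argmax linear indices for the backward pass.
// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  R_xlen_t M = (R_xlen_t)Ho * Wo * C * N;
  NumericVector y(M);
  NumericVector idx(M);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (R_xlen_t)H * wi];
              if (v > best) { best = v; bi = base + hi + (R_xlen_t)H * wi; }
            }
          }
          o = (R_xlen_t)(ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n)));
          y[o] = best;
          idx[o] = (double)bi;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector idx, NumericVector dy,
                                   IntegerVector xdim) {
  R_xlen_t M = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(M);
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    R_xlen_t j = (R_xlen_t)idx[i];
    if (j >= 0) dx[j] += dy[i];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// 2x2 stride-2 average pooling (transition layers); input sides must be even.
// [[Rcpp::export]]
NumericVector avgpool2_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  R_xlen_t o = 0;
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* xs = x.begin() + (R_xlen_t)H * W * s;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = xs + (R_xlen_t)H * (2 * wo);
      const double* c1 = xs + (R_xlen_t)H * (2 * wo + 1);
      for (int ho = 0; ho < Ho; ++ho) {
        y[o++] = 0.25 * (c0[2 * ho] + c0[2 * ho + 1] +
                         c1[2 * ho] + c1[2 * ho + 1]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_backward_cpp(NumericVector dy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1];
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t S = (R_xlen_t)xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)H * W * S);
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < S; ++s) {
    double* dxs = dx.begin() + (R_xlen_t)H * W * s;
    for (int wo = 0; wo < Wo; ++wo) {
      double* c0 = dxs + (R_xlen_t)H * (2 * wo);
      double* c1 = dxs + (R_xlen_t)H * (2 * wo + 1);
      for (int ho = 0; ho < Ho; ++ho) {
        double g = 0.25 * dy[i++];
        c0[2 * ho] += g; c0[2 * ho + 1] += g;
        c1[2 * ho] += g; c1[2 * ho + 1] += g;
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Rotate a matrix about the geometric centre of its pixel grid by `angle`
// radians (counter-clockwise in row/column coordinates), bilinear sampling,
// same-size canvas; exposed corners take the `bg` fill value.
// [[Rcpp::export]]
NumericMatrix rotate_bilinear_cpp(NumericMatrix x, double angle, double bg) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  double ca = std::cos(angle), sa = std::sin(angle);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // inverse mapping: rotate destination offset by -angle
      double di = i - ch, dj = j - cw;
      double si = ca * di + sa * dj + ch;
      double sj = -sa * di + ca * dj + cw;
      if (si < 0 || si > H - 1 || sj < 0 || sj > W - 1) {
        y(i, j) = bg;
        continue;
      }
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      double fi = si - i0, fj = sj - j0;
      y(i, j) = (1 - fi) * (1 - fj) * x(i0, j0) + fi * (1 - fj) * x(i1, j0) +
                (1 - fi) * fj * x(i0, j1) + fi * fj * x(i1, j1);
    }
  }
  return y;
}
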