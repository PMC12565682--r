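// Minimal CNN kernels: 'same'-padded stride-1 2-D convolution (forward and
// backward) via im2col + BLAS, 2x2 max pooling and 2x2 nearest upsampling.
// Tensors are R arrays in column-major (H, W, C, N) layout; convolution
// weights are (K, K, C, F) with K odd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-D array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Gather the im2col matrix (S x K*K*C) for image n of x.
static void im2col(const double *xn, int H, int W, int C, int K, arma::mat &M) {
  const int pad = K / 2;
  int q = 0;
  for (int c = 0; c < C; ++c) {
    const double *xc = xn + (std::size_t)H * W * c;
    for (int dx = 0; dx < K; ++dx) {
      for (int dy = 0; dy < K; ++dy, ++q) {
        double *col = M.colptr(q);
        for (int x0 = 0; x0 < W; ++x0) {
          const int xi = x0 + dx - pad;
          double *dst = col + (std::size_t)H * x0;
          if (xi < 0 || xi >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double *src = xc + (std::size_t)H * xi;
          for (int y0 = 0; y0 < H; ++y0) {
            const int yi = y0 + dy - pad;
            dst[y0] = (yi < 0 || yi >= H) ? 0.0 : src[yi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4);
  get_dims4(w, dw4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int K = dw4[0], F = dw4[3];
  if (dw4[1] != K || K % 2 == 0) stop("kernel must be square with odd size");
  if (dw4[2] != C) stop("weight channel count does not match input");
  if (b.size() != F) stop("bias length does not match filter count");

  const int S = H * W, KKC = K * K * C;
  arma::mat Wm(const_cast<double *>(w.begin()), KKC, F, false, true);
  NumericVector y((std::size_t)S * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);

  arma::mat M(S, KKC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)S * C * n, H, W, C, K, M);
    arma::mat Y = M * Wm;  // S x F
    double *yn = y.begin() + (std::size_t)S * F * n;
    for (int f = 0; f < F; ++f) {
      const double *src = Y.colptr(f);
      double *dst = yn + (std::size_t)S * f;
      const double bf = b[f];
      for (int s = 0; s < S; ++s) dst[s] = src[s] + bf;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4);
  get_dims4(w, dw4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int K = dw4[0], F = dw4[3], pad = K / 2;
  const int S = H * W, KKC = K * K * C;

  arma::mat Wm(const_cast<double *>(w.begin()), KKC, F, false, true);
  NumericVector dxv((std::size_t)S * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((std::size_t)KKC * F);
  dwv.attr("dim") = IntegerVector::create(K, K, C, F);
  NumericVector dbv(F);
  arma::mat dWm(dwv.begin(), KKC, F, false, true);

  arma::mat M(S, KKC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)S * C * n, H, W, C, K, M);
    arma::mat dY(const_cast<double *>(dy.begin()) + (std::size_t)S * F * n,
                 S, F, false, true);
    dWm += M.t() * dY;
    for (int f = 0; f < F; ++f) dbv[f] += arma::accu(dY.col(f));
    arma::mat dM = dY * Wm.t();  // S x KKC
    double *dxn = dxv.begin() + (std::size_t)S * C * n;
    int q = 0;
    for (int c = 0; c < C; ++c) {
      double *dxc = dxn + (std::size_t)S * c;
      for (int ddx = 0; ddx < K; ++ddx) {
        for (int ddy = 0; ddy < K; ++ddy, ++q) {
          const double *col = dM.colptr(q);
          for (int x0 = 0; x0 < W; ++x0) {
            const int xi = x0 + ddx - pad;
            if (xi < 0 || xi >= W) continue;
            double *dst = dxc + (std::size_t)H * xi;
            const double *src = col + (std::size_t)H * x0;
            for (int y0 = 0; y0 < H; ++y0) {
              const int yi = y0 + ddy - pad;
              if (yi >= 0 && yi < H) dst[yi] += src[y0];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int d4[4];
  get_dims4(x, d4);
  const int H = d4[0], W = d4[1], C = d4[2], N = d4[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector am((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  am.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *pl = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo, ++o) {
          int best = 0;
          double v = pl[(2 * yo) + (std::size_t)H * (2 * xo)];
          const int oy[4] = {0, 1, 0, 1}, ox[4] = {0, 0, 1, 1};
          for (int k = 1; k < 4; ++k) {
            double u = pl[(2 * yo + oy[k]) + (std::size_t)H * (2 * xo + ox[k])];
            if (u > v) { v = u; best = k; }
          }
          y[o] = v;
          am[o] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector am, int H, int W) {
  int d4[4];
  get_dims4(dy, d4);
  const int Ho = d4[0], Wo = d4[1], C = d4[2], N = d4[3];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const int oy[4] = {0, 1, 0, 1}, ox[4] = {0, 0, 1, 1};
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *pl = dx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo, ++o) {
          const int k = am[o];
          pl[(2 * yo + oy[k]) + (std::size_t)H * (2 * xo + ox[k])] += dy[o];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  int d4[4];
  get_dims4(x, d4);
  const int H = d4[0], W = d4[1], C = d4[2], N = d4[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::size_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *pl = y.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int x0 = 0; x0 < W; ++x0) {
        for (int y0 = 0; y0 < H; ++y0, ++i) {
          const double v = x[i];
          double *p = pl + (2 * y0) + (std::size_t)Ho * (2 * x0);
          p[0] = v; p[1] = v; p[Ho] = v; p[Ho + 1] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy) {
  int d4[4];
  get_dims4(dy, d4);
  const int Ho = d4[0], Wo = d4[1], C = d4[2], N = d4[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::size_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *pl = dy.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int x0 = 0; x0 < W; ++x0) {
        for (int y0 = 0; y0 < H; ++y0, ++i) {
          const double *p = pl + (2 * y0) + (std::size_t)Ho * (2 * x0);
          dx[i] = p[0] + p[1] + p[Ho] + p[Ho + 1];
        }
      }
    }
  }
  return dx;
}
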