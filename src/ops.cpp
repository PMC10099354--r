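// Low-level tensor kernels for the segmentation-network engine.
// Tensors are R arrays with dim (H, W, C, N), column-major, double precision.
// Convolution weights are stored as a (k*k*cin) x cout matrix whose row index
// is di + k*dj + k*k*ci (matching the column-major flattening of a
// (k, k, cin, cout) array), so im2col rows line up with weight rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill A ((k*k*cin) x (Ho*Wo*N)) with patches of x; zero padding.
static void im2col(const double* x, int H, int W, int C, int N,
                   int k, int stride, int pad, arma::mat& A) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  A.zeros(k * k * C, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wbase = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hbase = ho * stride - pad;
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* acol = A.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)H * W * c;
          for (int dj = 0; dj < k; ++dj) {
            const int w = wbase + dj;
            if (w < 0 || w >= W) continue;
            const double* xcw = xc + (size_t)H * w;
            double* arow = acol + (size_t)k * (dj + (size_t)k * c);
            for (int di = 0; di < k; ++di) {
              const int h = hbase + di;
              if (h >= 0 && h < H) arow[di] = xcw[h];
            }
          }
        }
      }
    }
  }
}

// Scatter-add columns of A back into dx (reverse of im2col).
static void col2im(const arma::mat& A, int H, int W, int C, int N,
                   int k, int stride, int pad, double* dx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int n = 0; n < N; ++n) {
    double* xn = dx + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wbase = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hbase = ho * stride - pad;
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double* acol = A.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)H * W * c;
          for (int dj = 0; dj < k; ++dj) {
            const int w = wbase + dj;
            if (w < 0 || w >= W) continue;
            double* xcw = xc + (size_t)H * w;
            const double* arow = acol + (size_t)k * (dj + (size_t)k * c);
            for (int di = 0; di < k; ++di) {
              const int h = hbase + di;
              if (h >= 0 && h < H) xcw[h] += arow[di];
            }
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) tensor");
  return d;
}

// ---- fast paths -----------------------------------------------------------
// 1x1 stride-1 convolution is a plain GEMM per sample; 3x3 stride-1 pad-1
// convolution is nine shifted tap-GEMMs on the (H*W) x C channel matrix with
// explicit correction of the rows that wrap across image-column boundaries.

static void conv1x1_fwd(const double* x, int H, int W, int C, int N,
                        const arma::mat& Wa, const double* b, double* out) {
  const size_t HW = (size_t)H * W;
  const int O = Wa.n_cols;
  for (int n = 0; n < N; ++n) {
    const arma::mat Xn(const_cast<double*>(x) + HW * C * n, HW, C, false);
    arma::mat Yn(out + HW * O * n, HW, O, false, true);
    Yn = Xn * Wa;
    for (int o = 0; o < O; ++o) Yn.col(o) += b[o];
  }
}

static void conv1x1_bwd(const double* x, int H, int W, int C, int N,
                        const arma::mat& Wa, const double* dy,
                        arma::mat& dW, arma::vec& db, double* dx) {
  const size_t HW = (size_t)H * W;
  const int O = Wa.n_cols;
  for (int n = 0; n < N; ++n) {
    const arma::mat Xn(const_cast<double*>(x) + HW * C * n, HW, C, false);
    const arma::mat Gn(const_cast<double*>(dy) + HW * O * n, HW, O, false);
    arma::mat dXn(dx + HW * C * n, HW, C, false, true);
    dW += Xn.t() * Gn;
    db += arma::sum(Gn, 0).t();
    dXn += Gn * Wa.t();
  }
}

// extract the (C x O) weight slice for tap (di, dj) of a 3x3 kernel
static arma::mat tap_weight(const arma::mat& Wa, int C, int di, int dj) {
  const int O = Wa.n_cols;
  arma::mat T(C, O);
  for (int c = 0; c < C; ++c)
    for (int o = 0; o < O; ++o)
      T(c, o) = Wa((di + 1) + 3 * (dj + 1) + 9 * c, o);
  return T;
}

static void conv3_fwd(const double* x, int H, int W, int C, int N,
                      const arma::mat& Wa, const double* b, double* out) {
  const size_t HW = (size_t)H * W;
  const int O = Wa.n_cols;
  for (int n = 0; n < N; ++n) {
    arma::mat Yn(out + HW * O * n, HW, O, false, true);
    Yn.zeros();
    for (int o = 0; o < O; ++o) Yn.col(o) += b[o];
  }
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      const arma::mat T = tap_weight(Wa, C, di, dj);
      const long off = di + (long)H * dj;
      const long a = off < 0 ? -off : 0;
      const long bnd = (long)HW - (off > 0 ? off : 0);
      if (a >= bnd) continue;
      for (int n = 0; n < N; ++n) {
        const arma::mat Xn(const_cast<double*>(x) + HW * C * n, HW, C, false);
        arma::mat Yn(out + HW * O * n, HW, O, false, true);
        Yn.rows(a, bnd - 1) += Xn.rows(a + off, bnd - 1 + off) * T;
        if (di != 0) { // undo rows that wrapped across an image column
          const int hbad = di > 0 ? H - 1 : 0;
          for (long w = 0; w < W; ++w) {
            const long r = (long)hbad + (long)H * w;
            if (r < a || r >= bnd) continue;
            Yn.row(r) -= Xn.row(r + off) * T;
          }
        }
      }
    }
}

static void conv3_bwd(const double* x, int H, int W, int C, int N,
                      const arma::mat& Wa, const double* dy,
                      arma::mat& dW, arma::vec& db, double* dx) {
  const size_t HW = (size_t)H * W;
  const int O = Wa.n_cols;
  for (int n = 0; n < N; ++n) {
    const arma::mat Gn(const_cast<double*>(dy) + HW * O * n, HW, O, false);
    db += arma::sum(Gn, 0).t();
  }
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      const arma::mat T = tap_weight(Wa, C, di, dj);
      arma::mat dT(C, O, arma::fill::zeros);
      const long off = di + (long)H * dj;
      const long a = off < 0 ? -off : 0;
      const long bnd = (long)HW - (off > 0 ? off : 0);
      if (a >= bnd) continue;
      for (int n = 0; n < N; ++n) {
        const arma::mat Xn(const_cast<double*>(x) + HW * C * n, HW, C, false);
        const arma::mat Gn(const_cast<double*>(dy) + HW * O * n, HW, O, false);
        arma::mat dXn(dx + HW * C * n, HW, C, false, true);
        dT += Xn.rows(a + off, bnd - 1 + off).t() * Gn.rows(a, bnd - 1);
        dXn.rows(a + off, bnd - 1 + off) += Gn.rows(a, bnd - 1) * T.t();
        if (di != 0) {
          const int hbad = di > 0 ? H - 1 : 0;
          for (long w = 0; w < W; ++w) {
            const long r = (long)hbad + (long)H * w;
            if (r < a || r >= bnd) continue;
            dT -= Xn.row(r + off).t() * Gn.row(r);
            dXn.row(r + off) -= Gn.row(r) * T.t();
          }
        }
      }
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < O; ++o)
          dW((di + 1) + 3 * (dj + 1) + 9 * c, o) += dT(c, o);
    }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                       int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int cout = Wm.ncol();
  if (Wm.nrow() != k * k * C) stop("weight rows do not match k*k*cin");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), cout, false);
  if (k == 1 && stride == 1 && pad == 0) {
    NumericVector out((size_t)H * W * cout * N);
    out.attr("dim") = IntegerVector::create(H, W, cout, N);
    conv1x1_fwd(REAL(x), H, W, C, N, Wa, b.begin(), REAL(out));
    return out;
  }
  if (k == 3 && stride == 1 && pad == 1) {
    NumericVector out((size_t)H * W * cout * N);
    out.attr("dim") = IntegerVector::create(H, W, cout, N);
    conv3_fwd(REAL(x), H, W, C, N, Wa, b.begin(), REAL(out));
    return out;
  }
  arma::mat A;
  im2col(REAL(x), H, W, C, N, k, stride, pad, A);
  arma::mat Y = Wa.t() * A;                  // cout x (Ho*Wo*N)
  NumericVector out((size_t)Ho * Wo * cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  double* o = REAL(out);
  const double* bb = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c) {
      double* oc = o + (size_t)Ho * Wo * (c + (size_t)cout * n);
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        oc[p] = Y(c, p + (size_t)Ho * Wo * n) + bb[c];
    }
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy,
              int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int cout = Wm.ncol();
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const arma::mat Wfast(Wm.begin(), Wm.nrow(), cout, false);
  if ((k == 1 && stride == 1 && pad == 0) ||
      (k == 3 && stride == 1 && pad == 1)) {
    arma::mat dW(Wm.nrow(), cout, arma::fill::zeros);
    arma::vec db(cout, arma::fill::zeros);
    NumericVector dx((size_t)H * W * C * N);
    dx.attr("dim") = d;
    if (k == 1)
      conv1x1_bwd(REAL(x), H, W, C, N, Wfast, REAL(dy), dW, db, REAL(dx));
    else
      conv3_bwd(REAL(x), H, W, C, N, Wfast, REAL(dy), dW, db, REAL(dx));
    return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
  }
  // repack dy (Ho,Wo,cout,N) as cout x (Ho*Wo*N)
  arma::mat dY(cout, (size_t)Ho * Wo * N);
  const double* g = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c) {
      const double* gc = g + (size_t)Ho * Wo * (c + (size_t)cout * n);
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        dY(c, p + (size_t)Ho * Wo * n) = gc[p];
    }
  arma::mat A;
  im2col(REAL(x), H, W, C, N, k, stride, pad, A);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), cout, false);
  arma::mat dW = A * dY.t();                 // (k*k*cin) x cout
  arma::vec db = arma::sum(dY, 1);
  arma::mat dA = Wa * dY;                    // (k*k*cin) x (Ho*Wo*N)
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  col2im(dA, H, W, C, N, k, stride, pad, REAL(dx));
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}

// Batch normalization over (H, W, N) per channel, layout (H, W, C, N).
// Training mode computes batch statistics and returns them for backward;
// inference mode uses the supplied running statistics.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar, double eps,
            bool training) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double* xp = REAL(x);
  NumericVector out((size_t)HW * C * N);
  out.attr("dim") = d;
  double* o = REAL(out);
  NumericVector mu(C), ivar(C);
  for (int c = 0; c < C; ++c) {
    double m, iv;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + HW * (c + (size_t)C * n);
        for (size_t p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
      }
      const double M = (double)HW * N;
      m = s / M;
      double v = s2 / M - m * m;
      if (v < 0) v = 0;
      iv = 1.0 / std::sqrt(v + eps);
      mu[c] = m; ivar[c] = iv;
    } else {
      m = rmean[c];
      iv = 1.0 / std::sqrt(rvar[c] + eps);
    }
    const double a = gamma[c] * iv;
    const double b = beta[c] - a * m;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      double* oc = o + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) oc[p] = a * xc[p] + b;
    }
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["ivar"] = ivar);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector gamma, NumericVector mu,
            NumericVector ivar, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  const double* xp = REAL(x);
  const double* g = REAL(dy);
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = d;
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], iv = ivar[c];
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const double* gc = g + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) {
        const double xh = (xc[p] - m) * iv;
        s1 += gc[p];
        s2 += gc[p] * xh;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double ga = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const double* gc = g + HW * (c + (size_t)C * n);
      double* dc = dxp + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) {
        const double xh = (xc[p] - m) * iv;
        dc[p] = ga * iv * (gc[p] - s1 / M - xh * s2 / M);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Transposed 2x2 stride-2 convolution: out(2h+di, 2w+dj, co) =
// sum_ci x(h, w, ci) * W[di + 2*dj + 4*ci, co].
// [[Rcpp::export(name = ".upconv2_fwd")]]
NumericVector upconv2_fwd(NumericVector x, NumericMatrix Wm, NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int cout = Wm.ncol();
  if (Wm.nrow() != 4 * C) stop("weight rows do not match 4*cin");
  const arma::mat Wa(Wm.begin(), Wm.nrow(), cout, false); // (4*cin) x cout
  NumericVector out((size_t)4 * H * W * cout * N);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, cout, N);
  double* o = REAL(out);
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W;
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      arma::mat T(C, cout);
      for (int c = 0; c < C; ++c)
        for (int co = 0; co < cout; ++co)
          T(c, co) = Wa(di + 2 * dj + 4 * c, co);
      for (int n = 0; n < N; ++n) {
        const arma::mat Xn(const_cast<double*>(REAL(x)) + HW * C * n,
                           HW, C, false);
        arma::mat Y = Xn * T; // (H*W) x cout
        for (int co = 0; co < cout; ++co) {
          double* oc = o + (size_t)Ho * Wo * (co + (size_t)cout * n);
          const double bc = b[co];
          const double* yc = Y.colptr(co);
          // each output pixel belongs to exactly one (di, dj) tap
          for (int w = 0; w < W; ++w) {
            const double* ysrc = yc + (size_t)H * w;
            double* od = oc + (size_t)di + (size_t)Ho * (2 * w + dj);
            for (int h = 0; h < H; ++h) od[2 * h] = ysrc[h] + bc;
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".upconv2_bwd")]]
List upconv2_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int cout = Wm.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W;
  const double* g = REAL(dy);
  arma::mat dW(4 * C, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = d;
  const arma::mat Wa(Wm.begin(), Wm.nrow(), cout, false);
  arma::mat Gtap(HW, cout);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      arma::mat T(C, cout);
      for (int c = 0; c < C; ++c)
        for (int co = 0; co < cout; ++co)
          T(c, co) = Wa(di + 2 * dj + 4 * c, co);
      arma::mat dT(C, cout, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        for (int co = 0; co < cout; ++co) {
          const double* gc = g + (size_t)Ho * Wo * (co + (size_t)cout * n);
          double* gt = Gtap.colptr(co);
          for (int w = 0; w < W; ++w) {
            const double* gs = gc + (size_t)di + (size_t)Ho * (2 * w + dj);
            double* gd = gt + (size_t)H * w;
            for (int h = 0; h < H; ++h) gd[h] = gs[2 * h];
          }
        }
        const arma::mat Xn(const_cast<double*>(REAL(x)) + HW * C * n,
                           HW, C, false);
        arma::mat dXn(REAL(dx) + HW * C * n, HW, C, false, true);
        dT += Xn.t() * Gtap;
        dXn += Gtap * T.t();
        db += arma::sum(Gtap, 0).t();
      }
      for (int c = 0; c < C; ++c)
        for (int co = 0; co < cout; ++co)
          dW(di + 2 * dj + 4 * c, co) = dT(c, co);
    }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}

// Max pooling with argmax bookkeeping. Returns out and 1-based linear
// indices into x of each selected element.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector arg((size_t)Ho * Wo * C * N); // double to allow >2^31 later
  const double* xp = REAL(x);
  double* o = REAL(out);
  double* ap = REAL(arg);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dj = 0; dj < k; ++dj) {
            const int w = wo * stride - pad + dj;
            if (w < 0 || w >= W) continue;
            for (int di = 0; di < k; ++di) {
              const int h = ho * stride - pad + di;
              if (h < 0 || h >= H) continue;
              const size_t xi = (size_t)h + (size_t)H * w;
              if (xc[xi] > best) { best = xc[xi]; bi = xi; }
            }
          }
          const size_t oi = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          o[oi] = best;
          ap[oi] = (double)((size_t)H * W * (c + (size_t)C * n) + bi + 1);
          ++q;
        }
    }
  (void)q;
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, NumericVector argmax,
                          IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* g = REAL(dy);
  const double* ap = REAL(argmax);
  const size_t M = dy.size();
  for (size_t i = 0; i < M; ++i) dxp[(size_t)ap[i] - 1] += g[i];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".up2_fwd")]]
NumericVector up2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out((size_t)4 * H * W * C * N);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* xp = REAL(x);
  double* o = REAL(out);
  const int Ho = 2 * H;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + (size_t)H * W * cn;
    double* oc = o + (size_t)4 * H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xc[(size_t)h + (size_t)H * w];
        double* p = oc + (size_t)2 * h + (size_t)Ho * 2 * w;
        p[0] = v; p[1] = v; p[Ho] = v; p[Ho + 1] = v;
      }
  }
  return out;
}

// [[Rcpp::export(name = ".up2_bwd")]]
NumericVector up2_bwd(NumericVector dy) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* g = REAL(dy);
  double* o = REAL(dx);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gc = g + (size_t)Ho * Wo * cn;
    double* oc = o + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* p = gc + (size_t)2 * h + (size_t)Ho * 2 * w;
        oc[(size_t)h + (size_t)H * w] = p[0] + p[1] + p[Ho] + p[Ho + 1];
      }
  }
  return dx;
}
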