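// Minimal convolutional building blocks for the feature-extraction U-Net.
// Layout convention: activations are (H, W, C, N) arrays (R column-major),
// 3x3 conv weights are (3, 3, Cin, Cout), 2x2 transposed-conv weights are
// (2, 2, Cin, Cout).  3x3 convolutions go through im2col + GEMM so the heavy
// lifting is BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void im2col3(const double *x, int H, int W, int C, arma::mat &Xcol) {
  // Xcol is (9*C, H*W); row = ki + 3*kj + 9*c (ki, kj in 0..2, offset -1)
  Xcol.zeros(9 * C, H * W);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int row = ki + 3 * kj + 9 * c;
        const int dh = ki - 1, dw = kj - 1;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          double *dst = Xcol.colptr(0) + row;  // element (row, col)
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) {
            Xcol(row, h + (size_t)H * w) = xc[(h + dh) + (size_t)H * sw];
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im3(const arma::mat &Xcol, int H, int W, int C, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int row = ki + 3 * kj + 9 * c;
        const int dh = ki - 1, dw = kj - 1;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) {
            xc[(h + dh) + (size_t)H * sw] += Xcol(row, h + (size_t)H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  arma::mat Wm(const_cast<double *>(w.begin()), 9 * Cin, Cout, false);
  NumericVector out = num4(H, W, Cout, N);
  arma::mat Xcol;
  arma::vec bv(const_cast<double *>(b.begin()), Cout, false);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, Xcol);
    arma::mat Y = Xcol.t() * Wm;  // (H*W, Cout)
    Y.each_row() += bv.t();
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  arma::mat Wm(const_cast<double *>(w.begin()), 9 * Cin, Cout, false);
  NumericVector dx = num4(H, W, Cin, N);
  NumericVector dw = num4(3, 3, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), 9 * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat Xcol;
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, Xcol);
    arma::mat dY(dy.begin() + (size_t)H * W * Cout * n, H * W, Cout, false);
    dWm += Xcol * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dXcol = Wm * dY.t();  // (9Cin, H*W)
    col2im3(dXcol, H, W, Cin, dx.begin() + (size_t)H * W * Cin * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx stores the flat within-sample argmax.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)H * W * C * n;
    double *ys = y.begin() + (size_t)Ho * Wo * C * n;
    int *is = idx.begin() + (size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          int besti = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int h = 2 * ho + di, w2 = 2 * wo + dj;
              const int flat = h + H * w2 + H * W * c;
              if (xs[flat] > best) { best = xs[flat]; besti = flat; }
            }
          }
          ys[ho + Ho * wo + Ho * Wo * c] = best;
          is[ho + Ho * wo + Ho * Wo * c] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy, int H,
                             int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = num4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double *ds = dy.begin() + (size_t)Ho * Wo * C * n;
    const int *is = idx.begin() + (size_t)Ho * Wo * C * n;
    double *xs = dx.begin() + (size_t)H * W * C * n;
    const size_t m = (size_t)Ho * Wo * C;
    for (size_t i = 0; i < m; ++i) xs[is[i]] += ds[i];
  }
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (doubles H and W).
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = num4(Ho, Wo, Cout, N);
  const double *wp = w.begin();
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)H * W * Cin * n;
    double *ys = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double *yc = ys + (size_t)Ho * Wo * co;
      const double bias = b[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xs + (size_t)H * W * ci;
        const double *wk = wp + 4 * (ci + (size_t)Cin * co);
        for (int w2 = 0; w2 < W; ++w2) {
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * w2];
            double *base = yc + 2 * h + (size_t)Ho * 2 * w2;
            base[0] += v * wk[0];          // (di=0, dj=0)
            base[1] += v * wk[1];          // (di=1, dj=0)
            base[Ho] += v * wk[2];         // (di=0, dj=1)
            base[Ho + 1] += v * wk[3];     // (di=1, dj=1)
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = num4(H, W, Cin, N);
  NumericVector dw = num4(2, 2, Cin, Cout);
  NumericVector db(Cout);
  const double *wp = w.begin();
  double *dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)H * W * Cin * n;
    const double *ds = dy.begin() + (size_t)Ho * Wo * Cout * n;
    double *dxs = dx.begin() + (size_t)H * W * Cin * n;
    for (int co = 0; co < Cout; ++co) {
      const double *dc = ds + (size_t)Ho * Wo * co;
      double acc = 0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) acc += dc[i];
      db[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xs + (size_t)H * W * ci;
        double *dxc = dxs + (size_t)H * W * ci;
        const double *wk = wp + 4 * (ci + (size_t)Cin * co);
        double *dwk = dwp + 4 * (ci + (size_t)Cin * co);
        for (int w2 = 0; w2 < W; ++w2) {
          for (int h = 0; h < H; ++h) {
            const double *base = dc + 2 * h + (size_t)Ho * 2 * w2;
            const double v = xc[h + (size_t)H * w2];
            dxc[h + (size_t)H * w2] += wk[0] * base[0] + wk[1] * base[1] +
                                       wk[2] * base[Ho] + wk[3] * base[Ho + 1];
            dwk[0] += v * base[0];
            dwk[1] += v * base[1];
            dwk[2] += v * base[Ho];
            dwk[3] += v * base[Ho + 1];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
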