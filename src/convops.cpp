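#include <Rcpp.h>
using namespace Rcpp;

// Activation layout: a (B*H*W) x C matrix; row index r = b + B*i + B*H*j
// (image b, row i, column j; all 0-based).  This matches an R array with
// dim c(B, H, W) flattened column-major, so R code can move between the
// matrix and array views without copying per element.

static inline int out_dim(int n, int s) { return (n + 2 - 3) / s + 1; } // pad 1, kernel 3

// Depthwise 3x3 convolution, padding 1, stride s.
// K: 9 x C, row index di + 3*dj with offsets (di-1, dj-1).
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fwd(NumericMatrix X, int B, int H, int W,
                             NumericMatrix K, int s) {
  const int C = X.ncol();
  const int Ho = out_dim(H, s), Wo = out_dim(W, s);
  NumericMatrix Y(B * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
      const double w = K(di + 3 * dj, c);
      if (w == 0.0) continue;
      for (int jo = 0; jo < Wo; ++jo) {
        const int j = jo * s + dj - 1;
        if (j < 0 || j >= W) continue;
        for (int io = 0; io < Ho; ++io) {
          const int i = io * s + di - 1;
          if (i < 0 || i >= H) continue;
          const double* xs = x + B * (i + H * j);
          double* ys = y + B * (io + Ho * jo);
          for (int b = 0; b < B; ++b) ys[b] += w * xs[b];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericMatrix dY, NumericMatrix X, int B, int H, int W,
                    NumericMatrix K, int s) {
  const int C = X.ncol();
  const int Ho = out_dim(H, s), Wo = out_dim(W, s);
  NumericMatrix dX(B * H * W, C);
  NumericMatrix dK(9, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    const double* dy = &dY(0, c);
    double* dx = &dX(0, c);
    for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
      const double w = K(di + 3 * dj, c);
      double acc = 0.0;
      for (int jo = 0; jo < Wo; ++jo) {
        const int j = jo * s + dj - 1;
        if (j < 0 || j >= W) continue;
        for (int io = 0; io < Ho; ++io) {
          const int i = io * s + di - 1;
          if (i < 0 || i >= H) continue;
          const double* xs = x + B * (i + H * j);
          const double* dys = dy + B * (io + Ho * jo);
          double* dxs = dx + B * (i + H * j);
          for (int b = 0; b < B; ++b) {
            acc += xs[b] * dys[b];
            dxs[b] += w * dys[b];
          }
        }
      }
      dK(di + 3 * dj, c) += acc;
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK);
}

// Dense 3x3 convolution, padding 1, stride 1 (used by the stem).
// K: (Cin*9) x Cout, row index ci + Cin*(di + 3*dj).
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(NumericMatrix X, int B, int H, int W,
                            NumericMatrix K, int Cin) {
  const int Cout = K.ncol();
  NumericMatrix Y(B * H * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* y = &Y(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x = &X(0, ci);
      for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
        const double w = K(ci + Cin * (di + 3 * dj), co);
        if (w == 0.0) continue;
        for (int jo = 0; jo < W; ++jo) {
          const int j = jo + dj - 1;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < H; ++io) {
            const int i = io + di - 1;
            if (i < 0 || i >= H) continue;
            const double* xs = x + B * (i + H * j);
            double* ys = y + B * (io + H * jo);
            for (int b = 0; b < B; ++b) ys[b] += w * xs[b];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericMatrix dY, NumericMatrix X, int B, int H, int W,
                   NumericMatrix K, int Cin) {
  const int Cout = K.ncol();
  NumericMatrix dX(B * H * W, Cin);
  NumericMatrix dK(Cin * 9, Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dy = &dY(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x = &X(0, ci);
      double* dx = &dX(0, ci);
      for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
        const double w = K(ci + Cin * (di + 3 * dj), co);
        double acc = 0.0;
        for (int jo = 0; jo < W; ++jo) {
          const int j = jo + dj - 1;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < H; ++io) {
            const int i = io + di - 1;
            if (i < 0 || i >= H) continue;
            const double* xs = x + B * (i + H * j);
            const double* dys = dy + B * (io + H * jo);
            double* dxs = dx + B * (i + H * j);
            for (int b = 0; b < B; ++b) {
              acc += xs[b] * dys[b];
              dxs[b] += w * dys[b];
            }
          }
        }
        dK(ci + Cin * (di + 3 * dj), co) += acc;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK);
}

// Transposed 3x3 convolution, stride 2, padding 1, output padding 1:
// maps H x W to 2H x 2W.  K: (Cin*9) x Cout, row index ci + Cin*(di + 3*dj);
// input position (i, j) scatters to output (2i + di - 1, 2j + dj - 1).
// [[Rcpp::export]]
NumericMatrix cpp_tconv_fwd(NumericMatrix X, int B, int H, int W,
                            NumericMatrix K, int Cin) {
  const int Cout = K.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix Y(B * Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* y = &Y(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x = &X(0, ci);
      for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
        const double w = K(ci + Cin * (di + 3 * dj), co);
        if (w == 0.0) continue;
        for (int j = 0; j < W; ++j) {
          const int jo = 2 * j + dj - 1;
          if (jo < 0 || jo >= Wo) continue;
          for (int i = 0; i < H; ++i) {
            const int io = 2 * i + di - 1;
            if (io < 0 || io >= Ho) continue;
            const double* xs = x + B * (i + H * j);
            double* ys = y + B * (io + Ho * jo);
            for (int b = 0; b < B; ++b) ys[b] += w * xs[b];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericMatrix dY, NumericMatrix X, int B, int H, int W,
                   NumericMatrix K, int Cin) {
  const int Cout = K.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix dX(B * H * W, Cin);
  NumericMatrix dK(Cin * 9, Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dy = &dY(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x = &X(0, ci);
      double* dx = &dX(0, ci);
      for (int dj = 0; dj < 3; ++dj) for (int di = 0; di < 3; ++di) {
        const double w = K(ci + Cin * (di + 3 * dj), co);
        double acc = 0.0;
        for (int j = 0; j < W; ++j) {
          const int jo = 2 * j + dj - 1;
          if (jo < 0 || jo >= Wo) continue;
          for (int i = 0; i < H; ++i) {
            const int io = 2 * i + di - 1;
            if (io < 0 || io >= Ho) continue;
            const double* xs = x + B * (i + H * j);
            const double* dys = dy + B * (io + Ho * jo);
            double* dxs = dx + B * (i + H * j);
            for (int b = 0; b < B; ++b) {
              acc += xs[b] * dys[b];
              dxs[b] += w * dys[b];
            }
          }
        }
        dK(ci + Cin * (di + 3 * dj), co) += acc;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK);
}

// Gray-scale flat erosion (op = 0) or dilation (op = 1) with an arbitrary
// binary structuring element centred on its middle cell.  Neighbourhoods are
// restricted to the image domain, so flat regions stay flat at the border.
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, LogicalMatrix se, int op) {
  const int H = img.nrow(), W = img.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int ci = sh / 2, cj = sw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = (op == 0) ? R_PosInf : R_NegInf;
      for (int b = 0; b < sw; ++b) {
        const int jj = j + b - cj;
        if (jj < 0 || jj >= W) continue;
        for (int a = 0; a < sh; ++a) {
          if (!se(a, b)) continue;
          const int ii = i + a - ci;
          if (ii < 0 || ii >= H) continue;
          const double x = img(ii, jj);
          if (op == 0) { if (x < v) v = x; } else { if (x > v) v = x; }
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}
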