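#include <Rcpp.h>
using namespace Rcpp;

// Column-wise (per-channel) batch-norm helpers operating on the
// (B*H*W) x C activation layout.  These replace sweep()-based R code on
// the training hot path.

// [[Rcpp::export]]
List cpp_bn_stats(NumericMatrix X) {
  const int n = X.nrow(), C = X.ncol();
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    mu[c] = s / n;
    var[c] = s2 / n - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// xhat = (X - mu) * ivar; Y = g * xhat + b
// [[Rcpp::export]]
List cpp_bn_apply(NumericMatrix X, NumericVector mu, NumericVector ivar,
                  NumericVector g, NumericVector b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix xhat(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* xh = &xhat(0, c);
    double* y = &Y(0, c);
    const double m = mu[c], iv = ivar[c], gg = g[c], bb = b[c];
    for (int i = 0; i < n; ++i) {
      xh[i] = (x[i] - m) * iv;
      y[i] = gg * xh[i] + bb;
    }
  }
  return List::create(_["xhat"] = xhat, _["Y"] = Y);
}

// Y only (evaluation mode)
// [[Rcpp::export]]
NumericMatrix cpp_bn_eval(NumericMatrix X, NumericVector mu, NumericVector ivar,
                          NumericVector g, NumericVector b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    const double m = mu[c], iv = ivar[c], gg = g[c], bb = b[c];
    for (int i = 0; i < n; ++i) y[i] = gg * (x[i] - m) * iv + bb;
  }
  return Y;
}

// dX = ivar * (g*dY - mean(g*dY) - xhat * mean(g*dY * xhat)); also dg, db.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dY, NumericMatrix xhat, NumericVector g,
                NumericVector ivar) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double* dx = &dX(0, c);
    double s1 = 0.0, s2 = 0.0, sg = 0.0, sb = 0.0;
    const double gg = g[c];
    for (int i = 0; i < n; ++i) {
      const double dxh = gg * dy[i];
      s1 += dxh;
      s2 += dxh * xh[i];
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dg[c] = sg; db[c] = sb;
    const double m1 = s1 / n, m2 = s2 / n, iv = ivar[c];
    for (int i = 0; i < n; ++i) {
      dx[i] = (gg * dy[i] - m1 - xh[i] * m2) * iv;
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// ReLU6 forward: Y = min(max(x, 0), 6), plus the pass-through mask.
// [[Rcpp::export]]
List cpp_relu6_fwd(NumericMatrix X) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  LogicalMatrix mask(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    int* mk = &mask(0, c);
    for (int i = 0; i < n; ++i) {
      const double v = x[i];
      mk[i] = (v > 0.0) && (v < 6.0);
      y[i] = v < 0.0 ? 0.0 : (v > 6.0 ? 6.0 : v);
    }
  }
  return List::create(_["Y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu6_bwd(NumericMatrix dY, LogicalMatrix mask) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const int* mk = &mask(0, c);
    double* dx = &dX(0, c);
    for (int i = 0; i < n; ++i) dx[i] = mk[i] ? dy[i] : 0.0;
  }
  return dX;
}

// Per-image channel means over the interleaved row blocks (SE squeeze):
// out(b, c) = mean over rows {b, b+B, ...} of X(., c).
// [[Rcpp::export]]
NumericMatrix cpp_rowblock_means(NumericMatrix X, int B) {
  const int n = X.nrow(), C = X.ncol();
  const int HW = n / B;
  NumericMatrix out(B, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) o[i % B] += x[i];
    for (int b = 0; b < B; ++b) o[b] /= HW;
  }
  return out;
}

// out(b, c) = sum over image-b rows of A * B2 (SE gate gradient).
// [[Rcpp::export]]
NumericMatrix cpp_rowblock_dots(NumericMatrix A, NumericMatrix B2, int B) {
  const int n = A.nrow(), C = A.ncol();
  NumericMatrix out(B, C);
  for (int c = 0; c < C; ++c) {
    const double* a = &A(0, c);
    const double* b2 = &B2(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) o[i % B] += a[i] * b2[i];
  }
  return out;
}

// Y = X scaled per (image, channel): Y(r, c) = X(r, c) * S(r mod B, c).
// [[Rcpp::export]]
NumericMatrix cpp_rowblock_scale(NumericMatrix X, NumericMatrix S, int B) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    const double* s = &S(0, c);
    double* y = &Y(0, c);
    for (int i = 0; i < n; ++i) y[i] = x[i] * s[i % B];
  }
  return Y;
}

// dX for the SE block: dY scaled by the gate plus the broadcast squeeze
// gradient, dX(r, c) = dY(r, c) * S(b, c) + DZ(b, c) / HW.
// [[Rcpp::export]]
NumericMatrix cpp_rowblock_scale_add(NumericMatrix dY, NumericMatrix S,
                                     NumericMatrix DZ, int B) {
  const int n = dY.nrow(), C = dY.ncol();
  const int HW = n / B;
  NumericMatrix dX(n, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* s = &S(0, c);
    const double* dz = &DZ(0, c);
    double* dx = &dX(0, c);
    for (int i = 0; i < n; ++i) {
      const int b = i % B;
      dx[i] = dy[i] * s[b] + dz[b] / HW;
    }
  }
  return dX;
}

// Fused batch-norm + ReLU6 forward: computes batch statistics, normalizes,
// scales/shifts, clamps to [0, 6] and records the pass-through mask in one
// sweep.  Returns the statistics so the caller can update running buffers;
// backprop recomputes xhat from X to avoid caching it.
// [[Rcpp::export]]
List cpp_bnrelu6_fwd(NumericMatrix X, NumericVector g, NumericVector b,
                     double eps) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  LogicalMatrix mask(n, C);
  NumericVector mu(C), var(C), ivar(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const double iv = 1.0 / std::sqrt(v + eps);
    ivar[c] = iv;
    const double gg = g[c], bb = b[c];
    double* y = &Y(0, c);
    int* mk = &mask(0, c);
    for (int i = 0; i < n; ++i) {
      const double z = gg * (x[i] - m) * iv + bb;
      mk[i] = (z > 0.0) && (z < 6.0);
      y[i] = z < 0.0 ? 0.0 : (z > 6.0 ? 6.0 : z);
    }
  }
  return List::create(_["Y"] = Y, _["mask"] = mask, _["mean"] = mu,
                      _["var"] = var, _["ivar"] = ivar);
}

// Fused backward for batch-norm + ReLU6, given the gradient at the ReLU
// output, the mask, the layer input X and the saved statistics.
// [[Rcpp::export]]
List cpp_bnrelu6_bwd(NumericMatrix dR, LogicalMatrix mask, NumericMatrix X,
                     NumericVector mu, NumericVector ivar, NumericVector g) {
  const int n = dR.nrow(), C = dR.ncol();
  NumericMatrix dX(n, C);
  NumericVector dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* dr = &dR(0, c);
    const int* mk = &mask(0, c);
    const double* x = &X(0, c);
    double* dx = &dX(0, c);
    const double m = mu[c], iv = ivar[c], gg = g[c];
    double s1 = 0.0, s2 = 0.0, sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dy = mk[i] ? dr[i] : 0.0;
      const double xh = (x[i] - m) * iv;
      s1 += gg * dy;
      s2 += gg * dy * xh;
      sg += dy * xh;
      sb += dy;
    }
    dg[c] = sg; db[c] = sb;
    const double m1 = s1 / n, m2 = s2 / n;
    for (int i = 0; i < n; ++i) {
      const double dy = mk[i] ? dr[i] : 0.0;
      const double xh = (x[i] - m) * iv;
      dx[i] = (gg * dy - m1 - xh * m2) * iv;
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}
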