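#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Internal tensor layout is (H, W, C, B), column-major ("hwcb"): spatial
// scans are contiguous, so the direct convolution kernels below stream
// through memory. Element (h,w,c,b) sits at h + H*(w + W*(c + C*b)).
// Weights keep the field convention (Co, Ci, kh, kw).

static inline double wget(const double* wp, int co, int ci, int i, int j,
                          int Co, int C, int k) {
  return wp[co + (R_xlen_t)Co * (ci + (R_xlen_t)C * (i + (R_xlen_t)k * j))];
}

// y += 3x3 conv of one (H,W) plane, stride 1, pad 1: all nine taps applied
// in one streaming pass (w9[i + 3*j], offsets i,j in {-1,0,1} order 0,1,2)
static void conv3x3_plane_acc(const double* x, double* y, const double* w9,
                              int H, int W) {
  for (int wc = 0; wc < W; ++wc) {
    const double* xm = (wc > 0) ? x + (R_xlen_t)H * (wc - 1) : nullptr;
    const double* x0 = x + (R_xlen_t)H * wc;
    const double* xp = (wc < W - 1) ? x + (R_xlen_t)H * (wc + 1) : nullptr;
    double* yc = y + (R_xlen_t)H * wc;
    // h = 0
    {
      double acc = 0;
      if (xm) acc += w9[1] * xm[0] + w9[2] * xm[1];
      acc += w9[4] * x0[0] + w9[5] * x0[1];
      if (xp) acc += w9[7] * xp[0] + w9[8] * xp[1];
      yc[0] += acc;
    }
    if (xm && xp) {
      for (int h = 1; h < H - 1; ++h) {
        yc[h] += w9[0] * xm[h - 1] + w9[1] * xm[h] + w9[2] * xm[h + 1] +
                 w9[3] * x0[h - 1] + w9[4] * x0[h] + w9[5] * x0[h + 1] +
                 w9[6] * xp[h - 1] + w9[7] * xp[h] + w9[8] * xp[h + 1];
      }
    } else {
      for (int h = 1; h < H - 1; ++h) {
        double acc = w9[3] * x0[h - 1] + w9[4] * x0[h] + w9[5] * x0[h + 1];
        if (xm) acc += w9[0] * xm[h - 1] + w9[1] * xm[h] + w9[2] * xm[h + 1];
        if (xp) acc += w9[6] * xp[h - 1] + w9[7] * xp[h] + w9[8] * xp[h + 1];
        yc[h] += acc;
      }
    }
    if (H > 1) {
      const int h = H - 1;
      double acc = 0;
      if (xm) acc += w9[0] * xm[h - 1] + w9[1] * xm[h];
      acc += w9[3] * x0[h - 1] + w9[4] * x0[h];
      if (xp) acc += w9[6] * xp[h - 1] + w9[7] * xp[h];
      yc[h] += acc;
    }
  }
}

// nine-tap weight-gradient correlation over one plane: acc9[i+3*j] +=
// sum_{oh,ow} gy[oh,ow] * x[oh+i-1, ow+j-1]
static void corr3x3_plane_acc(const double* x, const double* gy, double* acc9,
                              int H, int W) {
  for (int wc = 0; wc < W; ++wc) {
    const double* xm = (wc > 0) ? x + (R_xlen_t)H * (wc - 1) : nullptr;
    const double* x0 = x + (R_xlen_t)H * wc;
    const double* xp = (wc < W - 1) ? x + (R_xlen_t)H * (wc + 1) : nullptr;
    const double* gc = gy + (R_xlen_t)H * wc;
    double a0 = 0, a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0, a7 = 0,
           a8 = 0;
    for (int h = 1; h < H - 1; ++h) {
      const double g = gc[h];
      if (xm) { a0 += g * xm[h - 1]; a1 += g * xm[h]; a2 += g * xm[h + 1]; }
      a3 += g * x0[h - 1]; a4 += g * x0[h]; a5 += g * x0[h + 1];
      if (xp) { a6 += g * xp[h - 1]; a7 += g * xp[h]; a8 += g * xp[h + 1]; }
    }
    // edge rows h = 0 and h = H-1
    {
      const double g = gc[0];
      if (xm) { a1 += g * xm[0]; a2 += g * xm[1]; }
      a4 += g * x0[0]; a5 += g * x0[1];
      if (xp) { a7 += g * xp[0]; a8 += g * xp[1]; }
    }
    if (H > 1) {
      const int h = H - 1;
      const double g = gc[h];
      if (xm) { a0 += g * xm[h - 1]; a1 += g * xm[h]; }
      a3 += g * x0[h - 1]; a4 += g * x0[h];
      if (xp) { a6 += g * xp[h - 1]; a7 += g * xp[h]; }
    }
    acc9[0] += a0; acc9[1] += a1; acc9[2] += a2;
    acc9[3] += a3; acc9[4] += a4; acc9[5] += a5;
    acc9[6] += a6; acc9[7] += a7; acc9[8] += a8;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wt,
                             NumericVector bias, int H, int W, int C, int B,
                             int Co, int k, int s, int p) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericVector y((R_xlen_t)OH * OW * Co * B);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(wt);
  const double* bp = bias.size() ? REAL(bias) : nullptr;
  if (k == 3 && s == 1 && p == 1) {
    for (int b = 0; b < B; ++b) {
      const double* xb = xp + (R_xlen_t)H * W * C * b;
      double* yb = yp + (R_xlen_t)OH * OW * Co * b;
      for (int co = 0; co < Co; ++co) {
        double* yc = yb + (R_xlen_t)OH * OW * co;
        const double b0 = bp ? bp[co] : 0.0;
        for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) yc[t] = b0;
        for (int ci = 0; ci < C; ++ci) {
          double w9[9];
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i)
              w9[i + 3 * j] = wget(wp, co, ci, i, j, Co, C, 3);
          conv3x3_plane_acc(xb + (R_xlen_t)H * W * ci, yc, w9, H, W);
        }
      }
    }
    return y;
  }
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)H * W * C * b;
    double* yb = yp + (R_xlen_t)OH * OW * Co * b;
    for (int co = 0; co < Co; ++co) {
      double* yc = yb + (R_xlen_t)OH * OW * co;
      const double b0 = bp ? bp[co] : 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) yc[t] = b0;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xb + (R_xlen_t)H * W * ci;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wget(wp, co, ci, i, j, Co, C, k);
            if (wv == 0.0) continue;
            for (int ow = 0; ow < OW; ++ow) {
              const int w = ow * s + j - p;
              if (w < 0 || w >= W) continue;
              const double* xcol = xc + (R_xlen_t)H * w;
              double* ycol = yc + (R_xlen_t)OH * ow;
              int oh0 = 0, oh1 = OH;
              while (oh0 < OH && oh0 * s + i - p < 0) ++oh0;
              while (oh1 > oh0 && (oh1 - 1) * s + i - p >= H) --oh1;
              const double* xr = xcol + (oh0 * s + i - p);
              if (s == 1) {
                for (int oh = oh0; oh < oh1; ++oh)
                  ycol[oh] += wv * xr[oh - oh0];
              } else {
                for (int oh = oh0; oh < oh1; ++oh)
                  ycol[oh] += wv * xr[(R_xlen_t)(oh - oh0) * s];
              }
            }
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wt, NumericVector gy,
                    int H, int W, int C, int B, int Co, int k, int s, int p,
                    bool has_bias) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericVector gx((R_xlen_t)H * W * C * B);
  NumericVector gw((R_xlen_t)Co * C * k * k);
  NumericVector gb(has_bias ? Co : 0);
  const double* xp = REAL(x);
  const double* wp = REAL(wt);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = has_bias ? REAL(gb) : nullptr;
  if (k == 3 && s == 1 && p == 1) {
    for (int b = 0; b < B; ++b) {
      const double* xb = xp + (R_xlen_t)H * W * C * b;
      const double* gyb = gyp + (R_xlen_t)OH * OW * Co * b;
      double* gxb = gxp + (R_xlen_t)H * W * C * b;
      for (int co = 0; co < Co; ++co) {
        const double* gc = gyb + (R_xlen_t)OH * OW * co;
        if (gbp) {
          double acc = 0;
          for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) acc += gc[t];
          gbp[co] += acc;
        }
        for (int ci = 0; ci < C; ++ci) {
          double f9[9], a9[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i)
              f9[(2 - i) + 3 * (2 - j)] = wget(wp, co, ci, i, j, Co, C, 3);
          conv3x3_plane_acc(gc, gxb + (R_xlen_t)H * W * ci, f9, H, W);
          corr3x3_plane_acc(xb + (R_xlen_t)H * W * ci, gc, a9, H, W);
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i)
              gwp[co + (R_xlen_t)Co * (ci + (R_xlen_t)C * (i + 3 * j))] +=
                a9[i + 3 * j];
        }
      }
    }
    return List::create(Named("gx") = gx, Named("gw") = gw,
                        Named("gb") = gb);
  }
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)H * W * C * b;
    const double* gyb = gyp + (R_xlen_t)OH * OW * Co * b;
    double* gxb = gxp + (R_xlen_t)H * W * C * b;
    for (int co = 0; co < Co; ++co) {
      const double* gc = gyb + (R_xlen_t)OH * OW * co;
      if (gbp) {
        double acc = 0;
        for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) acc += gc[t];
        gbp[co] += acc;
      }
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xb + (R_xlen_t)H * W * ci;
        double* gxc = gxb + (R_xlen_t)H * W * ci;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wget(wp, co, ci, i, j, Co, C, k);
            double gwacc = 0;
            for (int ow = 0; ow < OW; ++ow) {
              const int w = ow * s + j - p;
              if (w < 0 || w >= W) continue;
              const double* xcol = xc + (R_xlen_t)H * w;
              double* gxcol = gxc + (R_xlen_t)H * w;
              const double* gcol = gc + (R_xlen_t)OH * ow;
              int oh0 = 0, oh1 = OH;
              while (oh0 < OH && oh0 * s + i - p < 0) ++oh0;
              while (oh1 > oh0 && (oh1 - 1) * s + i - p >= H) --oh1;
              const int base = oh0 * s + i - p;
              if (s == 1) {
                for (int oh = oh0; oh < oh1; ++oh) {
                  const double g = gcol[oh];
                  gwacc += g * xcol[base + oh - oh0];
                  gxcol[base + oh - oh0] += wv * g;
                }
              } else {
                for (int oh = oh0; oh < oh1; ++oh) {
                  const double g = gcol[oh];
                  gwacc += g * xcol[base + (R_xlen_t)(oh - oh0) * s];
                  gxcol[base + (R_xlen_t)(oh - oh0) * s] += wv * g;
                }
              }
            }
            gwp[co + (R_xlen_t)Co * (ci + (R_xlen_t)C * (i + (R_xlen_t)k * j))] += gwacc;
          }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// Transposed convolution with kernel == stride (disjoint output tiles).
// Weight layout (Ci, Co, k, k).
// [[Rcpp::export]]
NumericVector cpp_tconv2d_fwd(NumericVector x, NumericVector wt,
                              NumericVector bias, int H, int W, int C, int B,
                              int Co, int k) {
  const int OH = H * k, OW = W * k;
  NumericVector y((R_xlen_t)OH * OW * Co * B);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(wt);
  const double* bp = bias.size() ? REAL(bias) : nullptr;
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)H * W * C * b;
    double* yb = yp + (R_xlen_t)OH * OW * Co * b;
    for (int co = 0; co < Co; ++co) {
      double* yc = yb + (R_xlen_t)OH * OW * co;
      const double b0 = bp ? bp[co] : 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) yc[t] = b0;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xb + (R_xlen_t)H * W * ci;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wp[ci + (R_xlen_t)C * (co + (R_xlen_t)Co * (i + (R_xlen_t)k * j))];
            if (wv == 0.0) continue;
            for (int w = 0; w < W; ++w) {
              const double* xcol = xc + (R_xlen_t)H * w;
              double* ycol = yc + (R_xlen_t)OH * (w * k + j) + i;
              for (int h = 0; h < H; ++h)
                ycol[(R_xlen_t)h * k] += wv * xcol[h];
            }
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2d_bwd(NumericVector x, NumericVector wt, NumericVector gy,
                     int H, int W, int C, int B, int Co, int k) {
  const int OH = H * k, OW = W * k;
  NumericVector gx((R_xlen_t)H * W * C * B);
  NumericVector gw((R_xlen_t)C * Co * k * k);
  NumericVector gb(Co);
  const double* xp = REAL(x);
  const double* wp = REAL(wt);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)H * W * C * b;
    const double* gyb = gyp + (R_xlen_t)OH * OW * Co * b;
    double* gxb = gxp + (R_xlen_t)H * W * C * b;
    for (int co = 0; co < Co; ++co) {
      const double* gc = gyb + (R_xlen_t)OH * OW * co;
      double acc = 0;
      for (R_xlen_t t = 0; t < (R_xlen_t)OH * OW; ++t) acc += gc[t];
      gbp[co] += acc;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xb + (R_xlen_t)H * W * ci;
        double* gxc = gxb + (R_xlen_t)H * W * ci;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wp[ci + (R_xlen_t)C * (co + (R_xlen_t)Co * (i + (R_xlen_t)k * j))];
            double gwacc = 0;
            for (int w = 0; w < W; ++w) {
              const double* xcol = xc + (R_xlen_t)H * w;
              double* gxcol = gxc + (R_xlen_t)H * w;
              const double* gcol = gc + (R_xlen_t)OH * (w * k + j) + i;
              for (int h = 0; h < H; ++h) {
                const double g = gcol[(R_xlen_t)h * k];
                gwacc += g * xcol[h];
                gxcol[h] += wv * g;
              }
            }
            gwp[ci + (R_xlen_t)C * (co + (R_xlen_t)Co * (i + (R_xlen_t)k * j))] += gwacc;
          }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// im2col for the wide-layer GEMM path: returns (OH*OW*B, C*k*k) with row
// index oh + OH*(ow + OW*b) and column index i + k*(j + k*c); both source
// reads and destination writes are contiguous in h.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int B,
                         int k, int s, int p) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericMatrix out((R_xlen_t)OH * OW * B, (R_xlen_t)C * k * k);
  double* op = REAL(out);
  const double* xp = REAL(x);
  const R_xlen_t nrow = (R_xlen_t)OH * OW * B;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        double* col = op + nrow * (i + (R_xlen_t)k * (j + (R_xlen_t)k * c));
        for (int b = 0; b < B; ++b) {
          const double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * s + j - p;
            double* dst = col + (R_xlen_t)OH * (ow + (R_xlen_t)OW * b);
            if (w < 0 || w >= W) {
              for (int oh = 0; oh < OH; ++oh) dst[oh] = 0.0;
              continue;
            }
            const double* xcol = xc + (R_xlen_t)H * w;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * s + i - p;
              dst[oh] = (h >= 0 && h < H) ? xcol[h] : 0.0;
            }
          }
        }
      }
  return out;
}

// adjoint of cpp_im2col (scatter-add)
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int B,
                         int k, int s, int p) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericVector x((R_xlen_t)H * W * C * B);
  double* xp = REAL(x);
  const double* op = REAL(cols);
  const R_xlen_t nrow = (R_xlen_t)OH * OW * B;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const double* col = op + nrow * (i + (R_xlen_t)k * (j + (R_xlen_t)k * c));
        for (int b = 0; b < B; ++b) {
          double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * s + j - p;
            if (w < 0 || w >= W) continue;
            const double* src = col + (R_xlen_t)OH * (ow + (R_xlen_t)OW * b);
            double* xcol = xc + (R_xlen_t)H * w;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * s + i - p;
              if (h >= 0 && h < H) xcol[h] += src[oh];
            }
          }
        }
      }
  return x;
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void edt1d(const double* f, double* d, int* v, double* z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (pixel units) from every pixel to the nearest
// nonzero pixel of `mask` (H x W). Pixels of an all-zero mask get +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d(H, W);
  const double BIG = 1e30;
  std::vector<double> f(std::max(H, W)), dtmp(std::max(H, W));
  std::vector<int> v(std::max(H, W));
  std::vector<double> z(std::max(H, W) + 1);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = (mask(h, w) != 0.0) ? 0.0 : BIG;
    edt1d(f.data(), dtmp.data(), v.data(), z.data(), H);
    for (int h = 0; h < H; ++h) d(h, w) = dtmp[h];
  }
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) f[w] = d(h, w);
    edt1d(f.data(), dtmp.data(), v.data(), z.data(), W);
    for (int w = 0; w < W; ++w) d(h, w) = (dtmp[w] >= BIG) ? R_PosInf : dtmp[w];
  }
  return d;
}
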