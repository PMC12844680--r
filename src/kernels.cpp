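// Numeric kernels for the segmentation network and the annotation
// rasterizer. Array layout convention throughout: feature maps are R
// arrays of dim (H, W, C, N), column-major, so each (channel, image)
// plane of H*W values is contiguous with H fastest.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather one (image, group) into a column matrix: rows index output
// positions (ho fastest), columns index (kh, kw, c) with kh fastest —
// the same ordering as the weight array (Kh, Kw, Cg, Cout).
static void im2col(const double* x, int H, int W, int cbase, int Cg,
                   int Kh, int Kw, int s, int p, int Ho, int Wo,
                   arma::mat& col) {
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + (size_t)(cbase + c) * H * W;
    for (int kw = 0; kw < Kw; ++kw) {
      for (int kh = 0; kh < Kh; ++kh) {
        double* cc = col.colptr(kh + Kh * (kw + Kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s + kw - p;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) cc[ho + Ho * wo] = 0.0;
            continue;
          }
          const double* xw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s + kh - p;
            cc[ho + Ho * wo] = (hi >= 0 && hi < H) ? xw[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-accumulate a column matrix back onto the
// (already image-offset) input-gradient pointer.
static void col2im_acc(const arma::mat& col, double* dx, int H, int W,
                       int cbase, int Cg, int Kh, int Kw, int s, int p,
                       int Ho, int Wo) {
  for (int c = 0; c < Cg; ++c) {
    double* xc = dx + (size_t)(cbase + c) * H * W;
    for (int kw = 0; kw < Kw; ++kw) {
      for (int kh = 0; kh < Kh; ++kh) {
        const double* cc = col.colptr(kh + Kh * (kw + Kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s + kw - p;
          if (wi < 0 || wi >= W) continue;
          double* xw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s + kh - p;
            if (hi >= 0 && hi < H) xw[hi] += cc[ho + Ho * wo];
          }
        }
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector& x) {
  if (x.attr("dim") == R_NilValue) stop("input must be a dim-ed array");
  return IntegerVector(x.attr("dim"));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int groups) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Kh = wd[0], Kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: input channels %d != %d x groups %d", C, Cg, groups);
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Coutg = Cout / groups;
  int Ho = conv_out(H, Kh, stride, pad), Wo = conv_out(W, Kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)Kh * Kw * Cg, Cout, false, true);
  bool has_b = b.size() > 0;
  bool pointwise = (Kh == 1 && Kw == 1 && stride == 1 && pad == 0);
  arma::mat col(pointwise ? 1 : (size_t)Ho * Wo,
                pointwise ? 1 : (size_t)Kh * Kw * Cg);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* on = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      arma::mat om(on + (size_t)g * Coutg * Ho * Wo, (size_t)Ho * Wo, Coutg, false, true);
      if (pointwise) {
        arma::mat xm(const_cast<double*>(xn) + (size_t)g * Cg * H * W,
                     (size_t)H * W, Cg, false, true);
        om = xm * Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
      } else {
        im2col(xn, H, W, g * Cg, Cg, Kh, Kw, stride, pad, Ho, Wo, col);
        om = col * Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
      }
      if (has_b)
        for (int j = 0; j < Coutg; ++j) om.col(j) += b[g * Coutg + j];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad, int groups, bool need_dx) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), od = dims_of(dout);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Kh = wd[0], Kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Ho = od[0], Wo = od[1];
  int Coutg = Cout / groups;
  NumericVector dw((size_t)Kh * Kw * Cg * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = xd;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)Kh * Kw * Cg, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)Kh * Kw * Cg, Cout, false, true);
  bool pointwise = (Kh == 1 && Kw == 1 && stride == 1 && pad == 0);
  arma::mat col(pointwise ? 1 : (size_t)Ho * Wo,
                pointwise ? 1 : (size_t)Kh * Kw * Cg);
  arma::mat dcol(col.n_rows, col.n_cols);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dn = dout.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      arma::mat dm(const_cast<double*>(dn) + (size_t)g * Coutg * Ho * Wo,
                   (size_t)Ho * Wo, Coutg, false, true);
      for (int j = 0; j < Coutg; ++j) db[g * Coutg + j] += arma::accu(dm.col(j));
      if (pointwise) {
        arma::mat xm(const_cast<double*>(xn) + (size_t)g * Cg * H * W,
                     (size_t)H * W, Cg, false, true);
        dWm.cols(g * Coutg, (g + 1) * Coutg - 1) += xm.t() * dm;
        if (need_dx) {
          arma::mat dxm(dx.begin() + (size_t)n * H * W * C +
                            (size_t)g * Cg * H * W,
                        (size_t)H * W, Cg, false, true);
          dxm += dm * Wm.cols(g * Coutg, (g + 1) * Coutg - 1).t();
        }
      } else {
        im2col(xn, H, W, g * Cg, Cg, Kh, Kw, stride, pad, Ho, Wo, col);
        dWm.cols(g * Coutg, (g + 1) * Coutg - 1) += col.t() * dm;
        if (need_dx) {
          dcol = dm * Wm.cols(g * Coutg, (g + 1) * Coutg - 1).t();
          col2im_acc(dcol, dx.begin() + (size_t)n * H * W * C, H, W, g * Cg,
                     Cg, Kh, Kw, stride, pad, Ho, Wo);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution with kernel 2, stride 2 (checker-free learnable
// 2x upsampling variant). Weight dim: (2, 2, Cin, Cout).
// [[Rcpp::export]]
NumericVector cpp_deconv2x(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("deconv2x: channel mismatch");
  NumericVector out((size_t)4 * H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    for (int kw = 0; kw < 2; ++kw)
      for (int kh = 0; kh < 2; ++kh) {
        arma::mat Wk(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wk(ci, co) = w[kh + 2 * (kw + 2 * (ci + Cin * co))];
        arma::mat om = xm * Wk;  // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          double* op = out.begin() + (size_t)n * 4 * H * W * Cout +
                       (size_t)co * 4 * H * W;
          const double* sp = om.colptr(co);
          double bb = b.size() > 0 ? b[co] : 0.0;
          for (int wi = 0; wi < W; ++wi)
            for (int hi = 0; hi < H; ++hi)
              op[(2 * hi + kh) + (size_t)2 * H * (2 * wi + kw)] +=
                  sp[hi + H * wi] + bb;
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_deconv2x_bwd(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat dxm(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    for (int kw = 0; kw < 2; ++kw)
      for (int kh = 0; kh < 2; ++kh) {
        // gather strided slice of dout: (H*W) x Cout
        arma::mat dm((size_t)H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* dp = dout.begin() + (size_t)n * 4 * H * W * Cout +
                             (size_t)co * 4 * H * W;
          double* dst = dm.colptr(co);
          for (int wi = 0; wi < W; ++wi)
            for (int hi = 0; hi < H; ++hi)
              dst[hi + H * wi] = dp[(2 * hi + kh) + (size_t)2 * H * (2 * wi + kw)];
        }
        arma::mat Wk(C, Cout), dWk;
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wk(ci, co) = w[kh + 2 * (kw + 2 * (ci + C * co))];
        dxm += dm * Wk.t();
        dWk = xm.t() * dm;
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            dw[kh + 2 * (kw + 2 * (ci + C * co))] += dWk(ci, co);
        if (kh == 0 && kw == 0) { /* bias gradient uses all positions */ }
      }
    // bias: sum over all output positions
  }
  // db = sum of dout per output channel
  IntegerVector od = dims_of(dout);
  size_t plane = (size_t)od[0] * od[1];
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dp = dout.begin() + ((size_t)n * Cout + co) * plane;
      double s = 0;
      for (size_t i = 0; i < plane; ++i) s += dp[i];
      db[co] += s;
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear resize (half-pixel-center convention, like common DL
// frameworks with align_corners = FALSE). x: (H, W, planes).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1];
  size_t P = 1;
  for (int i = 2; i < xd.size(); ++i) P *= xd[i];
  NumericVector out((size_t)Ho * Wo * P);
  IntegerVector od(xd.size());
  od[0] = Ho; od[1] = Wo;
  for (int i = 2; i < xd.size(); ++i) od[i] = xd[i];
  out.attr("dim") = od;
  std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
  std::vector<double> fi(Ho), fj(Wo);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = s - i0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    fj[j] = s - j0[j];
  }
  for (size_t p = 0; p < P; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* op = out.begin() + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xp + (size_t)j0[j] * H;
      const double* c1 = xp + (size_t)j1[j] * H;
      double wj = fj[j];
      for (int i = 0; i < Ho; ++i) {
        double a = c0[i0[i]] * (1 - fi[i]) + c0[i1[i]] * fi[i];
        double b = c1[i0[i]] * (1 - fi[i]) + c1[i1[i]] * fi[i];
        op[i + (size_t)Ho * j] = a * (1 - wj) + b * wj;
      }
    }
  }
  return out;
}

// Adjoint of cpp_resize_bilinear: scatter gradients back to (H, W).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_adj(NumericVector dout, int H, int W) {
  IntegerVector od = dims_of(dout);
  int Ho = od[0], Wo = od[1];
  size_t P = 1;
  for (int i = 2; i < od.size(); ++i) P *= od[i];
  NumericVector dx((size_t)H * W * P);
  IntegerVector xd(od.size());
  xd[0] = H; xd[1] = W;
  for (int i = 2; i < od.size(); ++i) xd[i] = od[i];
  dx.attr("dim") = xd;
  std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
  std::vector<double> fi(Ho), fj(Wo);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = s - i0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    fj[j] = s - j0[j];
  }
  for (size_t p = 0; p < P; ++p) {
    const double* dp = dout.begin() + p * Ho * Wo;
    double* xp = dx.begin() + p * H * W;
    for (int j = 0; j < Wo; ++j) {
      double wj = fj[j];
      for (int i = 0; i < Ho; ++i) {
        double g = dp[i + (size_t)Ho * j];
        xp[i0[i] + (size_t)j0[j] * H] += g * (1 - fi[i]) * (1 - wj);
        xp[i1[i] + (size_t)j0[j] * H] += g * fi[i] * (1 - wj);
        xp[i0[i] + (size_t)j1[j] * H] += g * (1 - fi[i]) * wj;
        xp[i1[i] + (size_t)j1[j] * H] += g * fi[i] * wj;
      }
    }
  }
  return dx;
}

// Nearest-neighbour resize (for binary masks; keeps values in {0,1}).
// [[Rcpp::export]]
NumericVector cpp_resize_nearest(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1];
  size_t P = 1;
  for (int i = 2; i < xd.size(); ++i) P *= xd[i];
  NumericVector out((size_t)Ho * Wo * P);
  IntegerVector od(xd.size());
  od[0] = Ho; od[1] = Wo;
  for (int i = 2; i < xd.size(); ++i) od[i] = xd[i];
  out.attr("dim") = od;
  std::vector<int> ii(Ho), jj(Wo);
  for (int i = 0; i < Ho; ++i)
    ii[i] = std::min(H - 1, (int)std::floor((i + 0.5) * H / Ho));
  for (int j = 0; j < Wo; ++j)
    jj[j] = std::min(W - 1, (int)std::floor((j + 0.5) * W / Wo));
  for (size_t p = 0; p < P; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* op = out.begin() + p * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        op[i + (size_t)Ho * j] = xp[ii[i] + (size_t)jj[j] * H];
  }
  return out;
}

// Per-position LayerNorm over the channel axis (ConvNeXt style).
// x: (H, W, C, N); gamma, beta: length C.
// [[Rcpp::export]]
List cpp_ln_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(HW * N), invstd(HW * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* yn = y.begin() + (size_t)n * HW * C;
    double* mun = mu.begin() + (size_t)n * HW;
    double* isn = invstd.begin() + (size_t)n * HW;
    for (size_t m = 0; m < HW; ++m) {
      double s = 0, s2 = 0;
      for (int c = 0; c < C; ++c) {
        double v = xn[m + HW * c];
        s += v;
        s2 += v * v;
      }
      double mm = s / C;
      double var = s2 / C - mm * mm;
      if (var < 0) var = 0;
      double is = 1.0 / std::sqrt(var + eps);
      mun[m] = mm;
      isn[m] = is;
      for (int c = 0; c < C; ++c)
        yn[m + HW * c] = gamma[c] * (xn[m + HW * c] - mm) * is + beta[c];
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_ln_bwd(NumericVector x, NumericVector gamma, NumericVector mu,
                NumericVector invstd, NumericVector dy) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> xhat(C), dxh(C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    const double* dyn = dy.begin() + (size_t)n * HW * C;
    double* dxn = dx.begin() + (size_t)n * HW * C;
    const double* mun = mu.begin() + (size_t)n * HW;
    const double* isn = invstd.begin() + (size_t)n * HW;
    for (size_t m = 0; m < HW; ++m) {
      double mdxh = 0, mdxx = 0;
      for (int c = 0; c < C; ++c) {
        xhat[c] = (xn[m + HW * c] - mun[m]) * isn[m];
        dxh[c] = dyn[m + HW * c] * gamma[c];
        dgamma[c] += dyn[m + HW * c] * xhat[c];
        dbeta[c] += dyn[m + HW * c];
        mdxh += dxh[c];
        mdxx += dxh[c] * xhat[c];
      }
      mdxh /= C;
      mdxx /= C;
      for (int c = 0; c < C; ++c)
        dxn[m + HW * c] = isn[m] * (dxh[c] - mdxh - xhat[c] * mdxx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Even-odd (crossing number) polygon rasterization at pixel centers.
// polys: list of n x 2 matrices of (x, y) vertices in pixel coordinates;
// pixel (row i, col j), 0-based, has center (j + 0.5, i + 0.5).
// Returns H x W matrix of 0/1 (union over polygons).
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polys(List polys, int height, int width) {
  IntegerMatrix mask(height, width);
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix v = polys[p];
    int nv = v.nrow();
    if (nv < 3) stop("polygon %d has fewer than 3 vertices", p + 1);
    for (int i = 0; i < height; ++i) {
      double py = i + 0.5;
      for (int j = 0; j < width; ++j) {
        double px = j + 0.5;
        bool inside = false;
        for (int a = 0, b = nv - 1; a < nv; b = a++) {
          double x1 = v(a, 0), y1 = v(a, 1), x2 = v(b, 0), y2 = v(b, 1);
          if ((y1 > py) != (y2 > py) &&
              px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
            inside = !inside;
        }
        if (inside) mask(i, j) = 1;
      }
    }
  }
  return mask;
}

// Exact GELU x * Phi(x) and its derivative, vectorized in C++ to keep
// the activation off the R allocation path.
// [[Rcpp::export]]
NumericVector cpp_gelu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.70710678118654752440;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] * 0.5 * (1.0 + std::erf(x[i] * inv_sqrt2));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.70710678118654752440;
  const double inv_sqrt2pi = 0.39894228040143267794;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double phi = 0.5 * (1.0 + std::erf(x[i] * inv_sqrt2));
    double pdf = inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]);
    dx[i] = dy[i] * (phi + x[i] * pdf);
  }
  return dx;
}

// One Adam update. m and v are modified in place (they are owned by
// the optimizer state and never aliased); the updated parameter vector
// is returned fresh.
// [[Rcpp::export]]
NumericVector cpp_adam_step(NumericVector p, NumericVector g,
                            NumericVector m, NumericVector v, double lr,
                            double beta1, double beta2, double eps,
                            double wd, int t) {
  NumericVector out(p.size());
  out.attr("dim") = p.attr("dim");
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    double gi = g[i] + wd * p[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    double mh = m[i] / bc1;
    double vh = v[i] / bc2;
    out[i] = p[i] - lr * mh / (std::sqrt(vh) + eps);
  }
  return out;
}
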