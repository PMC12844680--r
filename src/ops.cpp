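// Broadcast, pooling and concatenation helpers on (H, W, C, N) arrays.
// These sit on the training hot path; each is a single fused pass with
// no intermediate allocations.
#include <Rcpp.h>
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d(x.attr("dim"));
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// y = x * s[c]  (per-channel scale, e.g. layer scale)
// [[Rcpp::export]]
NumericVector cpp_scale_chan(NumericVector x, NumericVector s) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      double sc = s[c];
      for (size_t m = 0; m < HW; ++m, ++i) y[i] = x[i] * sc;
    }
  return y;
}

// dx = dy * s[c]; ds[c] = sum over (h, w, n) of dy * x
// [[Rcpp::export]]
List cpp_scale_chan_bwd(NumericVector x, NumericVector dy,
                        NumericVector s) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector ds(d[2]);
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      double sc = s[c], acc = 0;
      for (size_t m = 0; m < HW; ++m, ++i) {
        dx[i] = dy[i] * sc;
        acc += dy[i] * x[i];
      }
      ds[c] += acc;
    }
  return List::create(_["dx"] = dx, _["ds"] = ds);
}

// y = x * mc[c, n]  (channel-attention broadcast)
// [[Rcpp::export]]
NumericVector cpp_mul_chan(NumericVector x, NumericVector mc) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  size_t i = 0, j = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c, ++j) {
      double sc = mc[j];
      for (size_t m = 0; m < HW; ++m, ++i) y[i] = x[i] * sc;
    }
  return y;
}

// y = x * ms[h, w, 1, n]  (spatial-attention broadcast)
// [[Rcpp::export]]
NumericVector cpp_mul_spat(NumericVector x, NumericVector ms) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n) {
    const double* msn = ms.begin() + (size_t)n * HW;
    for (int c = 0; c < d[2]; ++c)
      for (size_t m = 0; m < HW; ++m, ++i) y[i] = x[i] * msn[m];
  }
  return y;
}

// out[c, n] = sum over (h, w) of a * b   (both (H,W,C,N))
// [[Rcpp::export]]
NumericMatrix cpp_mulsum_chan(NumericVector a, NumericVector b) {
  IntegerVector d = dims4(a);
  size_t HW = (size_t)d[0] * d[1];
  NumericMatrix out(d[2], d[3]);
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      double acc = 0;
      for (size_t m = 0; m < HW; ++m, ++i) acc += a[i] * b[i];
      out(c, n) = acc;
    }
  return out;
}

// out[h, w, 1, n] = sum over c of a * b
// [[Rcpp::export]]
NumericVector cpp_mulsum_spat(NumericVector a, NumericVector b) {
  IntegerVector d = dims4(a);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector out((size_t)HW * d[3]);
  out.attr("dim") = IntegerVector::create(d[0], d[1], 1, d[3]);
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n) {
    double* on = out.begin() + (size_t)n * HW;
    for (int c = 0; c < d[2]; ++c)
      for (size_t m = 0; m < HW; ++m, ++i) on[m] += a[i] * b[i];
  }
  return out;
}

// global average + max pooling over spatial positions, with argmax
// [[Rcpp::export]]
List cpp_gpool(NumericVector x) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericMatrix avg(d[2], d[3]), mx(d[2], d[3]);
  IntegerMatrix idx(d[2], d[3]);
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      double acc = 0, best = x[i];
      int bi = 0;
      for (size_t m = 0; m < HW; ++m, ++i) {
        acc += x[i];
        if (x[i] > best) { best = x[i]; bi = (int)m; }
      }
      avg(c, n) = acc / HW;
      mx(c, n) = best;
      idx(c, n) = bi + 1;  // 1-based position within the plane
    }
  return List::create(_["avg"] = avg, _["max"] = mx, _["idx"] = idx);
}

// backward of the two global pools: davg spread uniformly, dmax routed
// to the argmax position
// [[Rcpp::export]]
NumericVector cpp_gpool_bwd(NumericVector davg, NumericVector dmax,
                            IntegerVector idx, IntegerVector d) {
  size_t HW = (size_t)d[0] * d[1];
  NumericVector dx((size_t)HW * d[2] * d[3]);
  dx.attr("dim") = d;
  size_t i = 0, j = 0;
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c, ++j) {
      double u = davg[j] / HW;
      for (size_t m = 0; m < HW; ++m, ++i) dx[i] = u;
      dx[i - HW + (idx[j] - 1)] += dmax[j];
    }
  return dx;
}

// channel-wise mean and max planes (spatial attention input), with
// argmax channel per position
// [[Rcpp::export]]
List cpp_cpool(NumericVector x) {
  IntegerVector d = dims4(x);
  size_t HW = (size_t)d[0] * d[1];
  NumericVector mean((size_t)HW * d[3]), mx((size_t)HW * d[3]);
  IntegerVector cdim = IntegerVector::create(d[0], d[1], 1, d[3]);
  mean.attr("dim") = cdim;
  mx.attr("dim") = cdim;
  IntegerVector idx((size_t)HW * d[3]);
  for (int n = 0; n < d[3]; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * d[2];
    double* mn = mean.begin() + (size_t)n * HW;
    double* xm = mx.begin() + (size_t)n * HW;
    int* in = idx.begin() + (size_t)n * HW;
    for (size_t m = 0; m < HW; ++m) {
      double acc = 0, best = xn[m];
      int bc = 0;
      for (int c = 0; c < d[2]; ++c) {
        double v = xn[m + HW * c];
        acc += v;
        if (v > best) { best = v; bc = c; }
      }
      mn[m] = acc / d[2];
      xm[m] = best;
      in[m] = bc + 1;
    }
  }
  return List::create(_["mean"] = mean, _["max"] = mx, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_cpool_bwd(NumericVector dmean, NumericVector dmax,
                            IntegerVector idx, IntegerVector d) {
  size_t HW = (size_t)d[0] * d[1];
  NumericVector dx((size_t)HW * d[2] * d[3]);
  dx.attr("dim") = d;
  for (int n = 0; n < d[3]; ++n) {
    double* xn = dx.begin() + (size_t)n * HW * d[2];
    const double* dmn = dmean.begin() + (size_t)n * HW;
    const double* dxm = dmax.begin() + (size_t)n * HW;
    const int* in = idx.begin() + (size_t)n * HW;
    for (size_t m = 0; m < HW; ++m) {
      double u = dmn[m] / d[2];
      for (int c = 0; c < d[2]; ++c) xn[m + HW * c] = u;
      xn[m + HW * (size_t)(in[m] - 1)] += dxm[m];
    }
  }
  return dx;
}

// channel concatenation and its split (adjoint)
// [[Rcpp::export]]
NumericVector cpp_concat_chan(NumericVector a, NumericVector b) {
  IntegerVector da = dims4(a), db = dims4(b);
  if (da[0] != db[0] || da[1] != db[1] || da[3] != db[3])
    stop("concat: incompatible shapes");
  size_t HW = (size_t)da[0] * da[1];
  int C = da[2] + db[2];
  NumericVector y((size_t)HW * C * da[3]);
  y.attr("dim") = IntegerVector::create(da[0], da[1], C, da[3]);
  for (int n = 0; n < da[3]; ++n) {
    std::copy(a.begin() + (size_t)n * HW * da[2],
              a.begin() + (size_t)(n + 1) * HW * da[2],
              y.begin() + (size_t)n * HW * C);
    std::copy(b.begin() + (size_t)n * HW * db[2],
              b.begin() + (size_t)(n + 1) * HW * db[2],
              y.begin() + (size_t)n * HW * C + HW * da[2]);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_split_chan(NumericVector y, int c1) {
  IntegerVector d = dims4(y);
  size_t HW = (size_t)d[0] * d[1];
  int c2 = d[2] - c1;
  NumericVector a((size_t)HW * c1 * d[3]), b((size_t)HW * c2 * d[3]);
  a.attr("dim") = IntegerVector::create(d[0], d[1], c1, d[3]);
  b.attr("dim") = IntegerVector::create(d[0], d[1], c2, d[3]);
  for (int n = 0; n < d[3]; ++n) {
    std::copy(y.begin() + (size_t)n * HW * d[2],
              y.begin() + (size_t)n * HW * d[2] + HW * c1,
              a.begin() + (size_t)n * HW * c1);
    std::copy(y.begin() + (size_t)n * HW * d[2] + HW * c1,
              y.begin() + (size_t)(n + 1) * HW * d[2],
              b.begin() + (size_t)n * HW * c2);
  }
  return List::create(_["a"] = a, _["b"] = b);
}
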