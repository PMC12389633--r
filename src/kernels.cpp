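// Low-level numeric kernels for the detection stack.
//
// Tensor convention: rank-4 arrays come in as flat NumericVectors with an
// explicit dim vector c(B, C, H, W); R stores column-major, so the linear
// index of (b, c, h, w) (all 0-based) is b + B*(c + C*(h + H*w)).

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int ix4(int b, int c, int h, int w, int B, int C, int H) {
  return b + B * (c + C * (h + H * w));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias, int stride, int pad,
                            int groups) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], CIG = wd[1], KH = wd[2], KW = wd[3];
  const int HO = (H + 2 * pad - KH) / stride + 1;
  const int WO = (W + 2 * pad - KW) / stride + 1;
  const int cog = CO / groups;
  const bool has_bias = bias.size() == CO;
  NumericVector y(B * CO * HO * WO);

  for (int b = 0; b < B; ++b)
    for (int co = 0; co < CO; ++co) {
      const int g = co / cog;
      const double b0 = has_bias ? bias[co] : 0.0;
      for (int ho = 0; ho < HO; ++ho)
        for (int wo = 0; wo < WO; ++wo) {
          double acc = b0;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < CIG; ++ci) {
            const int cin = g * CIG + ci;
            for (int kh = 0; kh < KH; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              for (int kw = 0; kw < KW; ++kw) {
                const int wx = w0 + kw;
                if (wx < 0 || wx >= W) continue;
                acc += x[ix4(b, cin, h, wx, B, C, H)] *
                       w[co + CO * (ci + CIG * (kh + KH * kw))];
              }
            }
          }
          y[ix4(b, co, ho, wo, B, CO, HO)] = acc;
        }
    }
  y.attr("dim") = IntegerVector::create(B, CO, HO, WO);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gy, bool has_bias, int stride, int pad,
                   int groups) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], CIG = wd[1], KH = wd[2], KW = wd[3];
  const int HO = (H + 2 * pad - KH) / stride + 1;
  const int WO = (W + 2 * pad - KW) / stride + 1;
  const int cog = CO / groups;
  NumericVector dx(x.size()), dw(w.size());
  NumericVector db(has_bias ? CO : 0);

  for (int b = 0; b < B; ++b)
    for (int co = 0; co < CO; ++co) {
      const int g = co / cog;
      for (int ho = 0; ho < HO; ++ho)
        for (int wo = 0; wo < WO; ++wo) {
          const double go = gy[ix4(b, co, ho, wo, B, CO, HO)];
          if (go == 0.0) continue;
          if (has_bias) db[co] += go;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < CIG; ++ci) {
            const int cin = g * CIG + ci;
            for (int kh = 0; kh < KH; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              for (int kw = 0; kw < KW; ++kw) {
                const int wx = w0 + kw;
                if (wx < 0 || wx >= W) continue;
                const int xi = ix4(b, cin, h, wx, B, C, H);
                const int wi = co + CO * (ci + CIG * (kh + KH * kw));
                dx[xi] += w[wi] * go;
                dw[wi] += x[xi] * go;
              }
            }
          }
        }
    }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, floor output-size convention; padded cells act as -Inf.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xd, int k, int stride,
                    int pad) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int HO = (H + 2 * pad - k) / stride + 1;
  const int WO = (W + 2 * pad - k) / stride + 1;
  NumericVector y(B * C * HO * WO);
  IntegerVector arg(B * C * HO * WO);

  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int ho = 0; ho < HO; ++ho)
        for (int wo = 0; wo < WO; ++wo) {
          double best = -DBL_MAX;
          int besti = -1;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wx = wo * stride - pad + kw;
              if (wx < 0 || wx >= W) continue;
              const int xi = ix4(b, c, h, wx, B, C, H);
              if (x[xi] > best) { best = x[xi]; besti = xi; }
            }
          }
          const int yi = ix4(b, c, ho, wo, B, C, HO);
          y[yi] = best;
          arg[yi] = besti + 1;  // 1-based, 0 = empty window
        }
  y.attr("dim") = IntegerVector::create(B, C, HO, WO);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector arg, NumericVector gy, int xlen) {
  NumericVector dx(xlen);
  for (int i = 0; i < arg.size(); ++i)
    if (arg[i] > 0) dx[arg[i] - 1] += gy[i];
  return dx;
}

// RoI max pooling. rois: n x 5 matrix (batch index 0-based, x1, y1, x2, y2)
// in continuous 0-based feature-map coordinates, half-open boxes.
// [[Rcpp::export]]
List cpp_roipool_fw(NumericVector x, IntegerVector xd, NumericMatrix rois,
                    int P) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int N = rois.nrow();
  NumericVector y(N * C * P * P);
  IntegerVector arg(N * C * P * P);

  for (int n = 0; n < N; ++n) {
    const int b = (int)rois(n, 0);
    int x1 = (int)floor(rois(n, 1)), y1 = (int)floor(rois(n, 2));
    int x2 = (int)ceil(rois(n, 3)), y2 = (int)ceil(rois(n, 4));
    x1 = std::min(std::max(x1, 0), W - 1);
    y1 = std::min(std::max(y1, 0), H - 1);
    x2 = std::min(std::max(x2, x1 + 1), W);
    y2 = std::min(std::max(y2, y1 + 1), H);
    const double bw = (double)(x2 - x1) / P, bh = (double)(y2 - y1) / P;
    for (int c = 0; c < C; ++c)
      for (int ph = 0; ph < P; ++ph)
        for (int pw = 0; pw < P; ++pw) {
          int hs = y1 + (int)floor(ph * bh);
          int he = y1 + (int)ceil((ph + 1) * bh);
          int ws = x1 + (int)floor(pw * bw);
          int we = x1 + (int)ceil((pw + 1) * bw);
          hs = std::min(std::max(hs, 0), H - 1);
          ws = std::min(std::max(ws, 0), W - 1);
          he = std::min(std::max(he, hs + 1), H);
          we = std::min(std::max(we, ws + 1), W);
          double best = -DBL_MAX;
          int besti = -1;
          for (int h = hs; h < he; ++h)
            for (int wx = ws; wx < we; ++wx) {
              const int xi = ix4(b, c, h, wx, B, C, H);
              if (x[xi] > best) { best = x[xi]; besti = xi; }
            }
          const int yi = n + N * (c + C * (ph + P * pw));
          y[yi] = best;
          arg[yi] = besti + 1;
        }
  }
  y.attr("dim") = IntegerVector::create(N, C, P, P);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_roipool_bw(IntegerVector arg, NumericVector gy, int xlen) {
  NumericVector dx(xlen);
  for (int i = 0; i < arg.size(); ++i)
    if (arg[i] > 0) dx[arg[i] - 1] += gy[i];
  return dx;
}

// 2-D correlation of a single-channel image with symmetric (mirror,
// edge-including) border reflection; used by the image enhancers.
// [[Rcpp::export]]
NumericMatrix cpp_filter2d_reflect(NumericMatrix img, NumericMatrix kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int KH = kernel.nrow(), KW = kernel.ncol();
  const int oh = KH / 2, ow = KW / 2;
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int ki = 0; ki < KH; ++ki)
        for (int kj = 0; kj < KW; ++kj) {
          int ii = i + ki - oh, jj = j + kj - ow;
          if (ii < 0) ii = -ii - 1;
          if (ii >= H) ii = 2 * H - ii - 1;
          if (jj < 0) jj = -jj - 1;
          if (jj >= W) jj = 2 * W - jj - 1;
          acc += img(ii, jj) * kernel(ki, kj);
        }
      out(i, j) = acc;
    }
  return out;
}
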