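#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are H x W x C arrays stored column-major (h fastest).
// im2col lays out one row per output pixel and one column per
// (kh, kw, c) weight entry, matching R's column-major flattening of a
// (k, k, C, Cout) weight array, so convolution reduces to cols %*% W.

// [[Rcpp::export(name = ".cn_im2col")]]
NumericMatrix cn_im2col(NumericVector x, int H, int W, int C, int k, int pad) {
  const int HW = H * W;
  NumericMatrix cols(HW, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * HW];
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int j = dh + k * dw + k * k * c;
        double* col = &cols(0, j);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          const double* src = xc + (R_xlen_t)sw * H + (h0 + dh - pad);
          double* dst = col + (R_xlen_t)w * H + h0;
          for (int h = h0; h < h1; ++h) *dst++ = *src++;
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".cn_col2im")]]
NumericVector cn_col2im(NumericMatrix cols, int H, int W, int C, int k, int pad) {
  const int HW = H * W;
  NumericVector x((R_xlen_t)HW * C);
  for (int c = 0; c < C; ++c) {
    double* xc = &x[(R_xlen_t)c * HW];
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int j = dh + k * dw + k * k * c;
        const double* col = &cols(0, j);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          double* dst = xc + (R_xlen_t)sw * H + (h0 + dh - pad);
          const double* src = col + (R_xlen_t)w * H + h0;
          for (int h = h0; h < h1; ++h) *dst++ += *src++;
        }
      }
    }
  }
  return x;
}

// 2x2 stride-2 max pooling; returns pooled values and 1-based argmax
// indices into the input vector for the backward pass.

// [[Rcpp::export(name = ".cn_maxpool")]]
List cn_maxpool(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * H * W;
    const R_xlen_t ooff = (R_xlen_t)c * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        R_xlen_t base = xoff + (R_xlen_t)(2 * w) * H + 2 * h;
        R_xlen_t best = base;
        double bv = x[base];
        const R_xlen_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
        out[ooff + (R_xlen_t)w * Ho + h] = bv;
        arg[ooff + (R_xlen_t)w * Ho + h] = (int)(best + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cn_maxpool_bw")]]
NumericVector cn_maxpool_bw(NumericVector dout, IntegerVector argmax, int n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  return dx;
}

// Bilinear resampling of an H x W x C array (half-pixel centers,
// edge-clamped), used for preprocessing and heatmap upsampling.

// [[Rcpp::export(name = ".cn_bilinear")]]
NumericVector cn_bilinear(NumericVector x, int H, int W, int C,
                          int Ho, int Wo) {
  NumericVector out((R_xlen_t)Ho * Wo * C);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    fh[i] = s - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    fw[j] = s - w0[j];
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * H * W];
    double* oc = &out[(R_xlen_t)c * Ho * Wo];
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double a = xc[(R_xlen_t)w0[j] * H + h0[i]];
        const double b = xc[(R_xlen_t)w0[j] * H + h1[i]];
        const double d = xc[(R_xlen_t)w1[j] * H + h0[i]];
        const double e = xc[(R_xlen_t)w1[j] * H + h1[i]];
        const double top = a + (d - a) * fw[j];
        const double bot = b + (e - b) * fw[j];
        oc[(R_xlen_t)j * Ho + i] = top + (bot - top) * fh[i];
      }
    }
  }
  return out;
}
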