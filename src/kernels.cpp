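#include <Rcpp.h>
using namespace Rcpp;

// Feature tensors are stored channel-first: element (c,h,w) of a C x H x W
// map sits at c + C*(h + H*w). Patch matrices use row index
// c + C*(ki + k*kj) and column index ho + Ho*wo so that a plain matrix
// product weight %*% patches performs the convolution.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* dst = &out(0, col);
      for (int kj = 0; kj < k; ++kj) {
        int w = wo * stride - pad + kj;
        for (int ki = 0; ki < k; ++ki) {
          int h = ho * stride - pad + ki;
          int r = C * (ki + k * kj);
          if (h < 0 || h >= H || w < 0 || w >= W) {
            for (int c = 0; c < C; ++c) dst[r + c] = 0.0;
          } else {
            const double* src = &x[C * (h + H * w)];
            for (int c = 0; c < C; ++c) dst[r + c] = src[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(C * H * W);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      const double* src = &cols(0, col);
      for (int kj = 0; kj < k; ++kj) {
        int w = wo * stride - pad + kj;
        if (w < 0 || w >= W) continue;
        for (int ki = 0; ki < k; ++ki) {
          int h = ho * stride - pad + ki;
          if (h < 0 || h >= H) continue;
          int r = C * (ki + k * kj);
          double* dst = &out[C * (h + H * w)];
          for (int c = 0; c < C; ++c) dst[c] += src[r + c];
        }
      }
    }
  }
  return out;
}

// Max pooling over a single C x H x W map; returns pooled values and the
// 1-based linear index of each winning element (for the backward scatter).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int C, int H, int W,
                     int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(C * Ho * Wo);
  IntegerVector idx(C * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf;
        int besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            int lin = c + C * (h + H * w);
            if (x[lin] > best) { best = x[lin]; besti = lin; }
          }
        }
        int o = c + C * (ho + Ho * wo);
        y[o] = best;
        idx[o] = besti + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector scatter_add_cpp(IntegerVector idx, NumericVector dy, int n) {
  NumericVector out(n);
  for (int i = 0; i < idx.size(); ++i) out[idx[i] - 1] += dy[i];
  return out;
}

// Batched im2col over a (C,H,W,N) tensor: output (C*k*k, Ho*Wo*N).
// [[Rcpp::export]]
NumericMatrix im2col_batch_cpp(NumericVector x, int C, int H, int W, int N,
                               int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = &x[(size_t)n * C * H * W];
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * wo + Ho * Wo * n;
        double* dst = &out(0, col);
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            int r = C * (ki + k * kj);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[r + c] = 0.0;
            } else {
              const double* src = &xs[C * (h + H * w)];
              for (int c = 0; c < C; ++c) dst[r + c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_batch_cpp(NumericMatrix cols, int C, int H, int W,
                               int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)C * H * W * N);
  for (int n = 0; n < N; ++n) {
    double* xs = &out[(size_t)n * C * H * W];
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * wo + Ho * Wo * n;
        const double* src = &cols(0, col);
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            int r = C * (ki + k * kj);
            double* dst = &xs[C * (h + H * w)];
            for (int c = 0; c < C; ++c) dst[c] += src[r + c];
          }
        }
      }
    }
  }
  return out;
}

// Batched max pooling over (C,H,W,N); idx is 1-based into the full input.
// [[Rcpp::export]]
List maxpool_fwd_batch_cpp(NumericVector x, int C, int H, int W, int N,
                           int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)C * Ho * Wo * N);
  IntegerVector idx((size_t)C * Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * C * H * W;
    size_t yoff = (size_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t besti = xoff;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              size_t lin = xoff + c + C * (h + H * w);
              if (x[lin] > best) { best = x[lin]; besti = lin; }
            }
          }
          size_t o = yoff + c + C * (ho + Ho * wo);
          y[o] = best;
          idx[o] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Bilinear resize of an H x W x C image array (height-first layout, as
// returned by png::readPNG). Used for letterboxing and Mosaic scaling.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector img, int H, int W, int C,
                                  int Ho, int Wo) {
  NumericVector out(Ho * Wo * C);
  double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int c = 0; c < C; ++c) {
    for (int xo = 0; xo < Wo; ++xo) {
      double xs = (xo + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(xs);
      double fx = xs - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int yo = 0; yo < Ho; ++yo) {
        double ys = (yo + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(ys);
        double fy = ys - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        double v00 = img[y0c + H * (x0c + W * c)];
        double v10 = img[y1c + H * (x0c + W * c)];
        double v01 = img[y0c + H * (x1c + W * c)];
        double v11 = img[y1c + H * (x1c + W * c)];
        out[yo + Ho * (xo + Wo * c)] =
          (1 - fy) * ((1 - fx) * v00 + fx * v01) +
          fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  return out;
}
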