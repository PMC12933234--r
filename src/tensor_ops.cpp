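// Low-level tensor kernels for the detector: im2col convolution (forward,
// input/weight/bias gradients), depthwise convolution, max-pooling with
// argmax, and nearest-neighbour 2x upsampling. Tensors are R arrays with
// dim (H, W, C, N), column-major; conv weights have dim (k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the (k*k*Cin) x (Ho*Wo) patch matrix for one sample.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  // col(row, p): row = kh + kw*k + c*k*k ; p = ho + wo*Ho
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + kw * k + c * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          double* dst = col.colptr(0) + row; // use explicit indexing below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + (size_t)wo * Ho) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            col(row, ho + (size_t)wo * Ho) =
              (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add a column matrix back into an image (adjoint of im2col).
static void col2im(const arma::mat& col, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + kw * k + c * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H)
              xcol[hi] += col(row, ho + (size_t)wo * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: empty output");
  NumericVector y(Ho * (size_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  arma::mat col((size_t)k * k * Cin, (size_t)Ho * Wo);
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = arma::vec(NumericVector(bias).begin(), Cout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat out = Wm.t() * col; // Cout x (Ho*Wo)
    if (has_b) out.each_col() += b;
    // write transposed: y sample layout is (Ho*Wo) x Cout contiguous
    arma::mat ymap(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    ymap = out.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  arma::mat Gw(gw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat col((size_t)k * k * Cin, (size_t)Ho * Wo);
  arma::vec Gb(has_bias ? Cout : 1, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat gymap(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true); // (P x Cout)
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, col);
    Gw += col * gymap;                       // (kkCin x Cout)
    arma::mat gcol = Wm * gymap.t();         // (kkCin x P)
    col2im(gcol, H, W, C, k, stride, pad, Ho, Wo,
           gx.begin() + (size_t)n * H * W * C);
    if (has_bias) Gb += arma::sum(gymap, 0).t();
  }
  if (has_bias) std::copy(Gb.begin(), Gb.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Depthwise convolution: weight dim (k, k, 1, C); each channel convolved
// with its own k x k filter, stride 1 or 2, zero padding.
// [[Rcpp::export]]
NumericVector dwconv_fw(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], k = wd[0];
  if (wd[3] != C) stop("dwconv: weight channel mismatch");
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * k * k;
      double* yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi >= 0 && hi < H)
                acc += xc[hi + (size_t)wi * H] * wc[kh + kw * k];
            }
          }
          yc[ho + (size_t)wo * Ho] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], k = wd[0];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * k * k;
      const double* gyc = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* gxc = gx.begin() + ((size_t)n * C + c) * H * W;
      double* gwc = gw.begin() + (size_t)c * k * k;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gyc[ho + (size_t)wo * Ho];
          if (g == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi >= 0 && hi < H) {
                gxc[hi + (size_t)wi * H] += g * wc[kh + kw * k];
                gwc[kh + kw * k] += g * xc[hi + (size_t)wi * H];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Max pooling with stored argmax (1-based flat index into the input
// sample-channel plane) for the backward pass.
// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t off = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)wi * H];
              if (v > best) { best = v; besti = hi + wi * H; }
            }
          }
          y[off + ho + (size_t)wo * Ho] = best;
          idx[off + ho + (size_t)wo * Ho] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t xoff = ((size_t)n * C + c) * H * W;
      size_t yoff = ((size_t)n * C + c) * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        int i = idx[yoff + p];
        if (i >= 0) gx[xoff + i] += gy[yoff + p];
      }
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsample: each pixel becomes a 2x2 block.
// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t nc = 0; nc < (size_t)N * C; ++nc) {
    const double* xc = x.begin() + nc * H * W;
    double* yc = y.begin() + nc * Ho * Wo;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = xc[h + (size_t)w * H];
        size_t b = 2 * h + (size_t)(2 * w) * Ho;
        yc[b] = v; yc[b + 1] = v; yc[b + Ho] = v; yc[b + Ho + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t nc = 0; nc < (size_t)N * C; ++nc) {
    const double* gyc = gy.begin() + nc * Ho * Wo;
    double* gxc = gx.begin() + nc * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        size_t b = 2 * h + (size_t)(2 * w) * Ho;
        gxc[h + (size_t)w * H] = gyc[b] + gyc[b + 1] + gyc[b + Ho] + gyc[b + Ho + 1];
      }
    }
  }
  return gx;
}
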