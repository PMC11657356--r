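// Low-level kernels for the DMS network.
//
// Tensors follow the R array layout (H, W, C, N), column-major, so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  Convolutions are stride-1
// "same" (zero) padded; odd kernel sizes only.  The whole batch is gathered
// into one (H*W*N) x (k*k*C) patch matrix so a single GEMM per call carries
// the arithmetic.  The forward pass can hand the patch matrix back to R as
// an external pointer so the backward pass reuses it instead of re-gathering.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather patches of image n into rows [n*HW, (n+1)*HW) of cols, writing
// zeros explicitly where the padded window leaves the support.
static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols, size_t row0) {
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* ch = x + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* col = cols.colptr(dh + k * (dw + k * c)) + row0;
        const int hlo = std::max(0, p - dh);
        const int hhi = std::min(H, H + p - dh);
        for (int w0 = 0; w0 < W; ++w0) {
          const int wi = w0 + dw - p;
          double* dst = col + (size_t)H * w0;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          if (hlo > 0) std::fill(dst, dst + hlo, 0.0);
          const double* src = ch + (size_t)H * wi + (hlo + dh - p);
          std::copy(src, src + (hhi - hlo), dst + hlo);
          if (hhi < H) std::fill(dst + hhi, dst + H, 0.0);
        }
      }
    }
  }
}

static void col2im_same(const arma::mat& cols, size_t row0, int H, int W,
                        int C, int k, double* dx) {
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* ch = dx + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* col = cols.colptr(dh + k * (dw + k * c)) + row0;
        for (int w0 = 0; w0 < W; ++w0) {
          const int wi = w0 + dw - p;
          if (wi < 0 || wi >= W) continue;
          const int hlo = std::max(0, p - dh);
          const int hhi = std::min(H, H + p - dh);
          double* dst = ch + (size_t)H * wi + (hlo + dh - p);
          const double* src = col + (size_t)H * w0 + hlo;
          for (int t = 0; t < hhi - hlo; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

struct PatchCache {
  arma::mat cols;
  int H, W, C, N, k;
};

static arma::mat gather_batch(NumericVector x, int H, int W, int C, int N,
                              int k) {
  const size_t HW = (size_t)H * W;
  arma::mat cols(HW * N, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + HW * C * n, H, W, C, k, cols, HW * n);
  }
  return cols;
}

static NumericVector gemm_out(const arma::mat& cols, const arma::mat& Wm,
                              NumericVector b, int H, int W, int N) {
  const size_t HW = (size_t)H * W;
  const int Cout = Wm.n_cols;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat out = cols * Wm;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = out.colptr(co) + HW * n;
      double* dst = y.begin() + HW * Cout * n + HW * co;
      const double bb = b[co];
      for (size_t px = 0; px < HW; ++px) dst[px] = src[px] + bb;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (wd[2] != C) stop("kernel in-channels do not match input");
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout,
                     false, true);
  arma::mat cols = gather_batch(x, H, W, C, N, k);
  return gemm_out(cols, Wm, b, H, W, N);
}

// Forward pass that also returns the patch matrix for backward reuse.
// [[Rcpp::export(name = ".conv2d_fwd_keep_cpp")]]
List conv2d_fwd_keep_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (wd[2] != C) stop("kernel in-channels do not match input");
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout,
                     false, true);
  XPtr<PatchCache> pc(new PatchCache{gather_batch(x, H, W, C, N, k),
                                     H, W, C, N, k});
  NumericVector y = gemm_out(pc->cols, Wm, b, H, W, N);
  return List::create(_["y"] = y, _["cache"] = pc);
}

// Backward against a cached patch matrix.
// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(SEXP cache, NumericVector w, NumericVector dy,
                    bool need_dx = true) {
  XPtr<PatchCache> pc(cache);
  const int H = pc->H, W = pc->W, C = pc->C, N = pc->N, k = pc->k;
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const size_t HW = (size_t)H * W;
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout,
                     false, true);
  arma::mat dY(HW * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + HW * Cout * n + HW * co;
      std::copy(src, src + HW, dY.colptr(co) + HW * n);
    }
  }
  NumericVector dwv((size_t)k * k * C * Cout);
  dwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  {
    arma::mat dW = pc->cols.t() * dY;
    std::copy(dW.begin(), dW.end(), dwv.begin());
  }
  NumericVector db(Cout);
  {
    arma::rowvec dB = arma::sum(dY, 0);
    std::copy(dB.begin(), dB.end(), db.begin());
  }
  NumericVector dx(1);
  if (need_dx) {
    dx = NumericVector(HW * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    arma::mat dcols = dY * Wm.t();
    for (int n = 0; n < N; ++n) {
      col2im_same(dcols, HW * n, H, W, C, k, dx.begin() + HW * C * n);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// y = x * a[c] + b[c], broadcast over a (H, W, C, N) array.
// [[Rcpp::export(name = ".chan_affine_cpp")]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector a,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * ac + bc;
    }
  }
  return y;
}

// Per-channel sums of one or two arrays (sum(x) and optionally sum(x*z)).
// [[Rcpp::export(name = ".chan_sums_cpp")]]
NumericMatrix chan_sums_cpp(NumericVector x, Nullable<NumericVector> z) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const bool two = z.isNotNull();
  NumericVector zz;
  if (two) zz = z.get();
  NumericMatrix out(C, two ? 2 : 1);
  const double* xp = x.begin();
  const double* zp = two ? zz.begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      double s1 = 0.0, s2 = 0.0;
      if (two) {
        for (size_t i = 0; i < HW; ++i) {
          s1 += xp[off + i];
          s2 += xp[off + i] * zp[off + i];
        }
      } else {
        for (size_t i = 0; i < HW; ++i) s1 += xp[off + i];
      }
      out(c, 0) += s1;
      if (two) out(c, 1) += s2;
    }
  }
  return out;
}
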