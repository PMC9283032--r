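// Stride-1 2-D convolution kernels (im2col + BLAS) for the compact
// backbones. Layouts match the R side: images are [H, W, C, N] arrays in
// column-major order; weight rows are ordered (di, dj, channel), di fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather the (P*N) x (k*k*C) column matrix from a [H, W, C, N] array
// into a preallocated R matrix (so it can be returned without a copy)
static void build_cols(const double* x, int H, int W, int C, int N,
                       int k, int pad, int outH, int outW, arma::mat& cols) {
  const int P = outH * outW;
  const size_t planeHW = static_cast<size_t>(H) * W;
  const size_t per_img = planeHW * C;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + dj * k + c * k * k;
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* src = x + n * per_img + c * planeHW;
          for (int oj = 0; oj < outW; ++oj) {
            const int i0 = oj * outH;
            const int jj = oj + dj - pad;   // source column
            const size_t row0 = static_cast<size_t>(n) * P + i0;
            if (jj < 0 || jj >= W) {
              for (int oi = 0; oi < outH; ++oi) dst[row0 + oi] = 0.0;
              continue;
            }
            const double* sc = src + static_cast<size_t>(jj) * H;
            for (int oi = 0; oi < outH; ++oi) {
              const int ii = oi + di - pad; // source row
              dst[row0 + oi] = (ii < 0 || ii >= H) ? 0.0 : sc[ii];
            }
          }
        }
      }
    }
  }
}

// scatter-add the column matrix back into a [H, W, C, N] array (col2im)
static void scatter_cols(const arma::mat& cols, double* x, int H, int W,
                         int C, int N, int k, int pad, int outH, int outW) {
  const int P = outH * outW;
  const size_t planeHW = static_cast<size_t>(H) * W;
  const size_t per_img = planeHW * C;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + dj * k + c * k * k;
        const double* src = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* dst = x + n * per_img + c * planeHW;
          for (int oj = 0; oj < outW; ++oj) {
            const int jj = oj + dj - pad;
            if (jj < 0 || jj >= W) continue;
            const size_t row0 = static_cast<size_t>(n) * P + oj * outH;
            double* dc = dst + static_cast<size_t>(jj) * H;
            for (int oi = 0; oi < outH; ++oi) {
              const int ii = oi + di - pad;
              if (ii >= 0 && ii < H) dc[ii] += src[row0 + oi];
            }
          }
        }
      }
    }
  }
}

// [H, W, C, N] convolved with W ((k*k*C) x cout): returns the output
// [outH, outW, cout, N] together with the im2col matrix (reused backward)
// [[Rcpp::export(rng = false)]]
List conv_fwd_cpp(NumericVector x, IntegerVector dims,
                  NumericMatrix weights, NumericVector bias,
                  int k, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int outH = H + 2 * pad - k + 1;
  const int outW = W + 2 * pad - k + 1;
  const int cout = weights.ncol();
  const int P = outH * outW;
  NumericMatrix cols_r(static_cast<size_t>(P) * N,
                       static_cast<size_t>(k) * k * C);
  arma::mat cols(cols_r.begin(), cols_r.nrow(), cols_r.ncol(), false, true);
  build_cols(x.begin(), H, W, C, N, k, pad, outH, outW, cols);
  arma::mat Wm(weights.begin(), weights.nrow(), cout, false, true);
  arma::mat Y = cols * Wm;                       // (P*N) x cout
  NumericVector out(static_cast<R_xlen_t>(P) * N * cout);
  out.attr("dim") = IntegerVector::create(outH, outW, cout, N);
  double* o = out.begin();
  // rows of Y are (position, image); output wants [pos, cout, image]
  for (int co = 0; co < cout; ++co) {
    const double* yc = Y.colptr(co);
    const double b = bias[co];
    for (int n = 0; n < N; ++n) {
      double* dst = o + (static_cast<size_t>(n) * cout + co) * P;
      const double* src = yc + static_cast<size_t>(n) * P;
      for (int p = 0; p < P; ++p) dst[p] = src[p] + b;
    }
  }
  return List::create(_["out"] = out, _["cols"] = cols_r);
}

// returns list(dx = [H,W,C,N], dW, db) for upstream gradient dout
// [[Rcpp::export(rng = false)]]
List conv_bwd_cpp(NumericMatrix cols_in, IntegerVector dims,
                  NumericMatrix weights, NumericVector dout, int k, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int outH = H + 2 * pad - k + 1;
  const int outW = W + 2 * pad - k + 1;
  const int cout = weights.ncol();
  const int P = outH * outW;
  // dout [outH, outW, cout, N] -> (P*N) x cout, rows (position, image)
  arma::mat dYm(static_cast<size_t>(P) * N, cout);
  const double* dp = dout.begin();
  for (int co = 0; co < cout; ++co) {
    double* dst = dYm.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = dp + (static_cast<size_t>(n) * cout + co) * P;
      std::copy(src, src + P, dst + static_cast<size_t>(n) * P);
    }
  }
  arma::mat cols(cols_in.begin(), cols_in.nrow(), cols_in.ncol(), false, true);
  arma::mat Wm(weights.begin(), weights.nrow(), cout, false, true);
  arma::mat dW = cols.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dcols = dYm * Wm.t();
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  scatter_cols(dcols, dx.begin(), H, W, C, N, k, pad, outH, outW);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(rng = false)]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out = clone(x);
  double* o = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] < 0) o[i] = 0;
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector relu_bwd_cpp(NumericVector x, NumericVector dout) {
  NumericVector dx(x.size());
  const double* xi = x.begin();
  const double* d = dout.begin();
  double* o = dx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = xi[i] > 0 ? d[i] : 0.0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// 2x2 stride-2 max pooling over [H, W, C, N]; records the argmax corner
// (0..3, first-wins ties) for the backward scatter
// [[Rcpp::export(rng = false)]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int oh = H / 2, ow = W / 2;
  const R_xlen_t n_out = static_cast<R_xlen_t>(oh) * ow * C * N;
  NumericVector out(n_out);
  IntegerVector which(n_out);
  const double* xp = x.begin();
  double* op = out.begin();
  int* wp = which.begin();
  R_xlen_t o = 0;
  for (R_xlen_t s = 0; s < static_cast<R_xlen_t>(C) * N; ++s) {
    const double* plane = xp + s * H * W;
    for (int j = 0; j < ow; ++j) {
      const double* c0 = plane + (2 * j) * H;
      const double* c1 = plane + (2 * j + 1) * H;
      for (int i = 0; i < oh; ++i, ++o) {
        const double v[4] = { c0[2 * i], c0[2 * i + 1], c1[2 * i], c1[2 * i + 1] };
        int best = 0;
        for (int q = 1; q < 4; ++q) if (v[q] > v[best]) best = q;
        op[o] = v[best];
        wp[o] = best;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool_bwd_cpp(IntegerVector which, NumericVector dout,
                              IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int oh = H / 2, ow = W / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  double* xp = dx.begin();
  const double* dp = dout.begin();
  const int* wp = which.begin();
  R_xlen_t o = 0;
  for (R_xlen_t s = 0; s < static_cast<R_xlen_t>(C) * N; ++s) {
    double* plane = xp + s * H * W;
    for (int j = 0; j < ow; ++j) {
      double* c0 = plane + (2 * j) * H;
      double* c1 = plane + (2 * j + 1) * H;
      for (int i = 0; i < oh; ++i, ++o) {
        switch (wp[o]) {
          case 0: c0[2 * i] += dp[o]; break;
          case 1: c0[2 * i + 1] += dp[o]; break;
          case 2: c1[2 * i] += dp[o]; break;
          default: c1[2 * i + 1] += dp[o]; break;
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}
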