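// 3x3 "same" convolution kernels on (H, W, N, C) channels-last tensors.
// im2col/col2im run at memcpy speed here; the matrix products go through
// Armadillo (BLAS). Offset ordering (dx outer, dy inner) and the (9*Cin,
// Cout) weight layout are shared with the R-side bookkeeping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3_fill(const double* x, const int H, const int W,
                         const int N, const int C, arma::mat& M) {
  const arma::uword HW = (arma::uword)H * W, HWN = HW * N;
  int k = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++k) {
      const int sh = dy - 1, sw_off = dx - 1;
      for (int c = 0; c < C; ++c) {
        double* dst = M.colptr((arma::uword)k * C + c);
        const double* src = x + (arma::uword)c * HWN;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + sw_off;
            double* drow = dst + (arma::uword)n * HW + (arma::uword)w * H;
            if (sw < 0 || sw >= W) { std::fill(drow, drow + H, 0.0); continue; }
            const double* scol = src + (arma::uword)n * HW + (arma::uword)sw * H;
            const int h0 = std::max(0, -sh), h1 = std::min(H, H - sh);
            if (h0 > 0) std::fill(drow, drow + h0, 0.0);
            if (h1 < H) std::fill(drow + h1, drow + H, 0.0);
            if (h1 > h0) std::copy(scol + h0 + sh, scol + h1 + sh, drow + h0);
          }
        }
      }
    }
  }
}

static void col2im3_acc(const arma::mat& dM, const int H, const int W,
                        const int N, const int C, double* dx_out) {
  const arma::uword HW = (arma::uword)H * W, HWN = HW * N;
  int k = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++k) {
      const int sh = dy - 1, sw_off = dx - 1;
      for (int c = 0; c < C; ++c) {
        const double* src = dM.colptr((arma::uword)k * C + c);
        double* dst = dx_out + (arma::uword)c * HWN;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + sw_off;
            if (sw < 0 || sw >= W) continue;
            const double* srow = src + (arma::uword)n * HW + (arma::uword)w * H;
            double* dcol = dst + (arma::uword)n * HW + (arma::uword)sw * H;
            const int h0 = std::max(0, -sh), h1 = std::min(H, H - sh);
            for (int h = h0; h < h1; ++h) dcol[h + sh] += srow[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector X, const arma::mat& Wm,
                            const arma::vec& b) {
  IntegerVector dm = X.attr("dim");
  const int H = dm[0], W = dm[1], N = dm[2], C = dm[3];
  const arma::uword HWN = (arma::uword)H * W * N;
  arma::mat M(HWN, (arma::uword)9 * C);
  im2col3_fill(X.begin(), H, W, N, C, M);
  arma::mat Y = M * Wm;
  Y.each_row() += b.t();
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, N, (int)Wm.n_cols);
  return out;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector dY, NumericVector X, const arma::mat& Wm) {
  IntegerVector dm = X.attr("dim");
  const int H = dm[0], W = dm[1], N = dm[2], C = dm[3];
  const int Cout = Wm.n_cols;
  const arma::uword HWN = (arma::uword)H * W * N;
  arma::mat M(HWN, (arma::uword)9 * C);
  im2col3_fill(X.begin(), H, W, N, C, M);
  const arma::mat dYm(dY.begin(), HWN, Cout);   // no copy of ownership needed
  arma::mat dW = M.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dM = dYm * Wm.t();
  NumericVector dX((arma::uword)HWN * C);
  col2im3_acc(dM, H, W, N, C, dX.begin());
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  return List::create(_["dX"] = dX,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Column-wise batch normalization on the (H*W*N, C) matrix view: single-pass
// standardization avoids the repeated full-size temporaries an R version
// would allocate.

// [[Rcpp::export]]
List bn_fwd_cpp(const NumericMatrix& M, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& rmean,
                const NumericVector& rvar, const bool training,
                const double momentum, const double eps) {
  const R_xlen_t n = M.nrow(), C = M.ncol();
  NumericMatrix Y(n, C), Xhat(n, C);
  NumericVector inv_std(C), new_mean(clone(rmean)), new_var(clone(rvar));
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* x = &M(0, c);
    double mu, v;
    if (training) {
      double s = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) s += x[i];
      mu = s / n;
      double ss = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) { const double d = x[i] - mu; ss += d * d; }
      v = ss / n;
      new_mean[c] = (1 - momentum) * rmean[c] + momentum * mu;
      new_var[c]  = (1 - momentum) * rvar[c]  + momentum * v;
    } else {
      mu = rmean[c]; v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    inv_std[c] = is;
    const double g = gamma[c], b = beta[c];
    double* xh = &Xhat(0, c); double* y = &Y(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      xh[i] = (x[i] - mu) * is;
      y[i] = g * xh[i] + b;
    }
  }
  return List::create(_["Y"] = Y, _["Xhat"] = Xhat, _["inv_std"] = inv_std,
                      _["mean"] = new_mean, _["var"] = new_var);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Xhat,
                const NumericVector& inv_std, const NumericVector& gamma,
                const bool training) {
  const R_xlen_t n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &Xhat(0, c);
    double s_dy = 0.0, s_dyxh = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { s_dy += dy[i]; s_dyxh += dy[i] * xh[i]; }
    dgamma[c] = s_dyxh; dbeta[c] = s_dy;
    const double g = gamma[c], is = inv_std[c];
    double* dx = &dX(0, c);
    if (training) {
      const double m1 = g * s_dy / n, m2 = g * s_dyxh / n;
      for (R_xlen_t i = 0; i < n; ++i)
        dx[i] = (g * dy[i] - m1 - xh[i] * m2) * is;
    } else {
      for (R_xlen_t i = 0; i < n; ++i) dx[i] = g * dy[i] * is;
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
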