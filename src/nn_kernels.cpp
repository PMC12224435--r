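// Dense compute kernels for the package's neural-network engine:
// im2col convolution, 2x2 max pooling, and the Gaussian mixture
// negative log-likelihood with analytic gradients.
//
// Layout conventions (all 0-based internally):
//  * an image batch is an N x (H*W*C) matrix, pixel (h,w,c) at column
//    h + H*w + H*W*c;
//  * a convolution weight is (K*K*C) x F, entry (kh,kw,c) at row
//    kh + K*kw + K*K*c;
//  * a conv output is N x (OH*OW*F), position (oh,ow,f) at column
//    oh + OH*ow + OH*OW*f, with OH = H + 2P - K + 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void im2col(const mat& X, mat& cols,
                          int H, int W, int C, int K, int P) {
  const int N = X.n_rows;
  const int Hp = H + 2 * P, Wp = W + 2 * P;
  const int OH = Hp - K + 1, OW = Wp - K + 1;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const int j = kh + K * kw + K * K * c;
        double* colj = cols.colptr(j);
        for (int ow = 0; ow < OW; ++ow) {
          const int ws = ow + kw - P;
          for (int oh = 0; oh < OH; ++oh) {
            const int hs = oh + kh - P;
            double* dst = colj + (size_t)N * (oh + OH * ow);
            if (hs < 0 || hs >= H || ws < 0 || ws >= W) {
              std::memset(dst, 0, sizeof(double) * N);
            } else {
              std::memcpy(dst, X.colptr(hs + H * ws + (size_t)H * W * c),
                          sizeof(double) * N);
            }
          }
        }
      }
}

// [[Rcpp::export]]
Rcpp::List conv2d_fwd_cpp(const arma::mat& X, const arma::mat& Wt,
                          const arma::vec& b, int H, int W, int C,
                          int K, int P) {
  const int N = X.n_rows;
  const int OH = H + 2 * P - K + 1, OW = W + 2 * P - K + 1;
  const int KKC = K * K * C, F = Wt.n_cols;
  mat cols((size_t)N * OH * OW, KKC);
  im2col(X, cols, H, W, C, K, P);
  mat out = cols * Wt;               // (N*OH*OW) x F
  out.each_row() += b.t();
  out.reshape(N, (size_t)OH * OW * F);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::mat& cols, const arma::mat& dOut,
                          const arma::mat& Wt, int H, int W, int C,
                          int K, int P, bool need_dx) {
  const int OH = H + 2 * P - K + 1, OW = W + 2 * P - K + 1;
  const int F = Wt.n_cols;
  const int N = dOut.n_rows;
  mat dOutR = dOut;                  // copy, relabel to (N*OH*OW) x F
  dOutR.reshape((size_t)N * OH * OW, F);
  mat dW = cols.t() * dOutR;
  vec db = sum(dOutR, 0).t();
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dcols = dOutR * Wt.t();      // (N*OH*OW) x KKC
    mat dX(N, (size_t)H * W * C, fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int kw = 0; kw < K; ++kw)
        for (int kh = 0; kh < K; ++kh) {
          const int j = kh + K * kw + K * K * c;
          const double* colj = dcols.colptr(j);
          for (int ow = 0; ow < OW; ++ow) {
            const int ws = ow + kw - P;
            if (ws < 0 || ws >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int hs = oh + kh - P;
              if (hs < 0 || hs >= H) continue;
              double* dst = dX.colptr(hs + H * ws + (size_t)H * W * c);
              const double* src = colj + (size_t)N * (oh + OH * ow);
              for (int n = 0; n < N; ++n) dst[n] += src[n];
            }
          }
        }
    res["dX"] = dX;
  }
  return res;
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd_cpp(const arma::mat& X, int H, int W, int C) {
  const int N = X.n_rows;
  const int OH = H / 2, OW = W / 2;
  mat out(N, (size_t)OH * OW * C);
  Rcpp::IntegerMatrix which(N, OH * OW * C);
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t oj = oh + OH * ow + (size_t)OH * OW * c;
        const double* s[4];
        s[0] = X.colptr(2 * oh +     H * (2 * ow)     + (size_t)H * W * c);
        s[1] = X.colptr(2 * oh + 1 + H * (2 * ow)     + (size_t)H * W * c);
        s[2] = X.colptr(2 * oh +     H * (2 * ow + 1) + (size_t)H * W * c);
        s[3] = X.colptr(2 * oh + 1 + H * (2 * ow + 1) + (size_t)H * W * c);
        double* dst = out.colptr(oj);
        int* wj = &which(0, oj);
        for (int n = 0; n < N; ++n) {
          int best = 0;
          double v = s[0][n];
          for (int k = 1; k < 4; ++k)
            if (s[k][n] > v) { v = s[k][n]; best = k; }
          dst[n] = v;
          wj[n] = best;
        }
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("which") = which);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd_cpp(const arma::mat& dOut,
                           const Rcpp::IntegerMatrix& which,
                           int H, int W, int C) {
  const int N = dOut.n_rows;
  const int OH = H / 2, OW = W / 2;
  mat dX(N, (size_t)H * W * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t oj = oh + OH * ow + (size_t)OH * OW * c;
        double* d[4];
        d[0] = dX.colptr(2 * oh +     H * (2 * ow)     + (size_t)H * W * c);
        d[1] = dX.colptr(2 * oh + 1 + H * (2 * ow)     + (size_t)H * W * c);
        d[2] = dX.colptr(2 * oh +     H * (2 * ow + 1) + (size_t)H * W * c);
        d[3] = dX.colptr(2 * oh + 1 + H * (2 * ow + 1) + (size_t)H * W * c);
        const double* src = dOut.colptr(oj);
        const int* wj = &which(0, oj);
        for (int n = 0; n < N; ++n) d[wj[n]][n] += src[n];
      }
  return dX;
}

// Gaussian mixture negative log-likelihood and gradients.
//
// X:      N x d target vectors (standardized parameters alpha).
// logits: N x m unnormalized mixture weight logits.
// Mu:     N x (m*d) component means, component-major blocks.
// Lp:     N x (m*dtri) packed lower-triangular covariance factors
//         (Sigma = L L'), packed column-major within the triangle,
//         diagonal already strictly positive.
// Returns per-sample nll (to be averaged by the caller) and gradients
// of sum(nll) w.r.t. logits, Mu and Lp.
// [[Rcpp::export]]
Rcpp::List mdn_nll_grad_cpp(const arma::mat& X, const arma::mat& logits,
                            const arma::mat& Mu, const arma::mat& Lp,
                            int m, bool want_grad) {
  const int N = X.n_rows, d = X.n_cols;
  const int dtri = d * (d + 1) / 2;
  const double log2pi = std::log(2.0 * M_PI);
  vec nll(N);
  mat dlogits, dMu, dLp;
  if (want_grad) {
    dlogits.zeros(N, m);
    dMu.zeros(N, (size_t)m * d);
    dLp.zeros(N, (size_t)m * dtri);
  }
  // triangle packing index: (p,q) p>=q  ->  offset
  umat packidx(d, d, fill::zeros);
  {
    int t = 0;
    for (int q = 0; q < d; ++q)
      for (int p = q; p < d; ++p) packidx(p, q) = t++;
  }
  mat L(d, d);
  vec z(d), a(d), loglik(m), lw(m);
  mat Zs(d, m), As(d, m);
  for (int n = 0; n < N; ++n) {
    // log softmax of logits
    rowvec lg = logits.row(n);
    double mx = lg.max();
    double se = accu(exp(lg - mx));
    lw = (lg.t() - mx) - std::log(se);
    for (int i = 0; i < m; ++i) {
      L.zeros();
      for (int q = 0; q < d; ++q)
        for (int p = q; p < d; ++p)
          L(p, q) = Lp(n, (size_t)i * dtri + packidx(p, q));
      vec r = X.row(n).t() - Mu.row(n).subvec((size_t)i * d,
                                              (size_t)i * d + d - 1).t();
      z = solve(trimatl(L), r);
      a = solve(trimatu(L.t()), z);
      double ld = accu(log(L.diag()));
      loglik(i) = -ld - 0.5 * dot(z, z) - 0.5 * d * log2pi;
      Zs.col(i) = z;
      As.col(i) = a;
    }
    vec lj = lw + loglik;
    double mj = lj.max();
    double lse = mj + std::log(accu(exp(lj - mj)));
    nll(n) = -lse;
    if (want_grad) {
      vec resp = exp(lj - lse);       // responsibilities
      vec w = exp(lw);
      for (int i = 0; i < m; ++i) {
        dlogits(n, i) = -(resp(i) - w(i));
        for (int p = 0; p < d; ++p)
          dMu(n, (size_t)i * d + p) = -resp(i) * As(p, i);
        // dlogN/dL = tril(a z^T) - diag(1/L_kk)
        for (int q = 0; q < d; ++q) {
          for (int p = q; p < d; ++p) {
            double g = As(p, i) * Zs(q, i);
            if (p == q) {
              double lkk = Lp(n, (size_t)i * dtri + packidx(p, q));
              g -= 1.0 / lkk;
            }
            dLp(n, (size_t)i * dtri + packidx(p, q)) = -resp(i) * g;
          }
        }
      }
    }
  }
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("nll") = nll);
  if (want_grad) {
    res["dlogits"] = dlogits;
    res["dMu"] = dMu;
    res["dLp"] = dLp;
  }
  return res;
}
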