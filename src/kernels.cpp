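// Dense kernels for the convolutional factorization core.
// W is an N x K x L cube (channels x factors x lags); H is K x T.
// All time shifts zero-pad: entries sliding past the edge are dropped.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Stacked lagged copies of H: row (l*K + k), col t holds H(k, t - l),
// zero where t < l.  One KL x T matrix turns the L skinny products of
// the convolution into a single well-shaped GEMM.
static mat lag_stack(const mat& H, uword L) {
  const uword K = H.n_rows, T = H.n_cols;
  mat S(K * L, T, fill::zeros);
  for (uword l = 0; l < L && l < T; ++l)
    S.submat(l * K, l, (l + 1) * K - 1, T - 1) = H.cols(0, T - 1 - l);
  return S;
}

// W as an N x (K*L) matrix, column (l*K + k) = W(:, k, l)
static mat flatten_W(const cube& W) {
  const uword N = W.n_rows, K = W.n_cols, L = W.n_slices;
  mat F(N, K * L);
  for (uword l = 0; l < L; ++l)
    F.cols(l * K, (l + 1) * K - 1) = W.slice(l);
  return F;
}

// X~ = sum_l W[,,l] %*% (H shifted right by l)
// [[Rcpp::export]]
arma::mat cpp_reconstruct(const arma::cube& W, const arma::mat& H) {
  return flatten_W(W) * lag_stack(H, W.n_slices);
}

// the lag stack itself, for reuse across several products with one H
// [[Rcpp::export]]
arma::mat cpp_lag_stack(const arma::mat& H, int L) {
  return lag_stack(H, (uword)L);
}

// reconstruction from a precomputed lag stack
// [[Rcpp::export]]
arma::mat cpp_reconstruct_st(const arma::cube& W, const arma::mat& SH) {
  return flatten_W(W) * SH;
}

// (W transpose-conv X)_{kt} = sum_l sum_n W[n,k,l] X[n,t+l]
// [[Rcpp::export]]
arma::mat cpp_transconv(const arma::cube& W, const arma::mat& X) {
  const uword K = W.n_cols, L = W.n_slices, T = X.n_cols;
  mat G = flatten_W(W).t() * X;        // (K*L) x T
  mat out(K, T, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    if (l >= T) break;
    out.cols(0, T - 1 - l) += G.submat(l * K, l, (l + 1) * K - 1, T - 1);
  }
  return out;
}

// slice l = A %*% t(H shifted right by l); used for the W-update
// numerator (A = X) and denominator (A = X~).
// [[Rcpp::export]]
arma::cube cpp_lag_outer(const arma::mat& A, const arma::mat& H, int L) {
  const uword N = A.n_rows, K = H.n_rows;
  mat P = A * lag_stack(H, (uword)L).t();   // N x (K*L)
  cube out(N, K, (uword)L);
  for (uword l = 0; l < (uword)L; ++l)
    out.slice(l) = P.cols(l * K, (l + 1) * K - 1);
  return out;
}

// both W-update ingredients with one lag stack and one stacked GEMM:
// slice l of [0] = Z t(H_l->), slice l of [1] = Xhat t(H_l->)
// [[Rcpp::export]]
Rcpp::List cpp_lag_outer2(const arma::mat& Z, const arma::mat& Xhat,
                          const arma::mat& SH, int K_, int L) {
  const uword N = Z.n_rows, K = (uword)K_;
  mat St = SH.t();                          // T x (K*L)
  mat ZX = join_cols(Z, Xhat);              // 2N x T
  mat P = ZX * St;                          // 2N x (K*L)
  cube num(N, K, (uword)L), den(N, K, (uword)L);
  for (uword l = 0; l < (uword)L; ++l) {
    num.slice(l) = P.submat(0, l * K, N - 1, (l + 1) * K - 1);
    den.slice(l) = P.submat(N, l * K, 2 * N - 1, (l + 1) * K - 1);
  }
  return Rcpp::List::create(Rcpp::Named("num") = num,
                            Rcpp::Named("den") = den);
}

// slice l = (X shifted left by l) %*% M, with M a T x K matrix
// (the smoothed-loadings term S H' of the x-ortho W-update).
// [[Rcpp::export]]
arma::cube cpp_lag_left_prod(const arma::mat& X, const arma::mat& M, int L) {
  const uword N = X.n_rows, K = M.n_cols, T = X.n_cols;
  cube out(N, K, (uword)L, fill::zeros);
  for (uword l = 0; l < (uword)L; ++l) {
    if (l >= T) break;
    out.slice(l) = X.cols(l, T - 1) * M.rows(0, T - 1 - l);
  }
  return out;
}

// moving sum over a centered window of width 2L-1, per row,
// truncated (zero padded) at the edges
// [[Rcpp::export]]
arma::mat cpp_smooth_rows(const arma::mat& A, int L) {
  const uword K = A.n_rows, T = A.n_cols;
  if (L <= 1) return A;
  const int h = L - 1;
  mat out(K, T);
  rowvec cs(T + 1);
  for (uword k = 0; k < K; ++k) {
    cs(0) = 0.0;
    for (uword t = 0; t < T; ++t) cs(t + 1) = cs(t) + A(k, t);
    for (uword t = 0; t < T; ++t) {
      const uword lo = (t >= (uword)h) ? t - h : 0;
      const uword hi = std::min<uword>(t + h, T - 1);
      out(k, t) = cs(hi + 1) - cs(lo);
    }
  }
  return out;
}

static double skew_g1_adj(const vec& x) {
  const double n = (double)x.n_elem;
  if (n < 3.0) return datum::nan;
  const double mu = mean(x);
  const vec d = x - mu;
  const double m2 = mean(square(d));
  if (m2 <= 0.0) return datum::nan;
  const double m3 = mean(d % d % d);
  const double g1 = m3 / std::pow(m2, 1.5);
  return g1 * std::sqrt(n * (n - 1.0)) / (n - 2.0);
}

// [[Rcpp::export]]
double cpp_skewness(const arma::vec& x) { return skew_g1_adj(x); }

// Null distribution of overlap-trace skewness for one factor.
// Wk is the factor's N x L exemplar, X the held-out data, shifts an
// N x n_null matrix of circular lag shifts in [0, L).  Each null factor
// circularly rotates every channel's lag profile independently; its
// overlap trace is assembled from precomputed per-channel traces.
// [[Rcpp::export]]
arma::vec cpp_null_skews(const arma::mat& Wk, const arma::mat& X,
                         const arma::imat& shifts) {
  const uword N = Wk.n_rows, L = Wk.n_cols, T = X.n_cols;
  const uword n_null = shifts.n_cols;
  // traces(s, t, n): overlap of channel n rotated by s with X row n
  cube traces(L, T, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    for (uword s = 0; s < L; ++s) {
      for (uword l = 0; l < L; ++l) {
        const double w = Wk(n, (l + s) % L);
        if (w == 0.0) continue;
        const uword tmax = (l < T) ? T - l : 0;
        for (uword t = 0; t < tmax; ++t)
          traces(s, t, n) += w * X(n, t + l);
      }
    }
  }
  vec out(n_null);
  vec acc(T);
  for (uword j = 0; j < n_null; ++j) {
    acc.zeros();
    for (uword n = 0; n < N; ++n) {
      const uword s = (uword)shifts(n, j);
      acc += traces.slice(n).row(s).t();
    }
    out(j) = skew_g1_adj(acc);
  }
  return out;
}
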