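// 1-D convolution over time for multichannel segments, im2col + GEMM.
// Batches are cubes (channels x time x segment). "Same" padding for odd
// kernels; stride shortens the time axis as floor((T + 2p - K)/s) + 1.
// A single-precision path (used by the larger training configurations)
// halves memory traffic; the double path is bit-faithful for the small
// analytically-checked models.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline uword out_len(uword T, uword K, uword pad, uword stride) {
  return (T + 2 * pad - K) / stride + 1;
}

template <typename MT>
static void im2col(const MT& X, uword K, uword pad, uword stride, MT& M) {
  // X: C x T, M: (C*K) x T_out
  const uword C = X.n_rows, T = X.n_cols, To = M.n_cols;
  for (uword t = 0; t < To; ++t) {
    const sword start = (sword)(t * stride) - (sword)pad;
    for (uword k = 0; k < K; ++k) {
      const sword src = start + (sword)k;
      if (src >= 0 && src < (sword)T) {
        M.submat(k * C, t, (k + 1) * C - 1, t) = X.col((uword)src);
      } else {
        M.submat(k * C, t, (k + 1) * C - 1, t).zeros();
      }
    }
  }
}

template <typename eT>
static Cube<eT> conv_fw_impl(const cube& X, const mat& W, const vec& b,
                             int stride) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword K = W.n_cols / C, Co = W.n_rows;
  const uword pad = (K - 1) / 2;
  const uword To = out_len(T, K, pad, (uword)stride);
  Mat<eT> Wf = conv_to<Mat<eT>>::from(W);
  Col<eT> bf = conv_to<Col<eT>>::from(b);
  Cube<eT> Y(Co, To, B);
  Mat<eT> M(C * K, To);
  for (uword s = 0; s < B; ++s) {
    Mat<eT> Xs = conv_to<Mat<eT>>::from(X.slice(s));
    im2col<Mat<eT>>(Xs, K, pad, (uword)stride, M);
    Y.slice(s) = Wf * M;
    Y.slice(s).each_col() += bf;
  }
  return Y;
}

// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, int stride, bool single = false) {
  if (!single) return conv_fw_impl<double>(X, W, b, stride);
  fcube Y = conv_fw_impl<float>(X, W, b, stride);
  return conv_to<cube>::from(Y);
}

template <typename eT>
static Rcpp::List conv_bw_impl(const cube& X, const mat& W, const cube& dY,
                               int stride, bool need_dx) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword K = W.n_cols / C;
  const uword pad = (K - 1) / 2;
  const uword To = dY.n_cols;
  Mat<eT> Wf = conv_to<Mat<eT>>::from(W);
  Mat<eT> dW(W.n_rows, W.n_cols, fill::zeros);
  Col<eT> db(W.n_rows, fill::zeros);
  Cube<eT> dX;
  if (need_dx) dX.zeros(C, T, B);
  Mat<eT> M(C * K, To);
  for (uword s = 0; s < B; ++s) {
    Mat<eT> Xs = conv_to<Mat<eT>>::from(X.slice(s));
    Mat<eT> dYs = conv_to<Mat<eT>>::from(dY.slice(s));
    im2col<Mat<eT>>(Xs, K, pad, (uword)stride, M);
    dW += dYs * M.t();
    db += sum(dYs, 1);
    if (need_dx) {
      Mat<eT> dM = Wf.t() * dYs;  // (C*K) x To
      Mat<eT>& dXs = dX.slice(s);
      for (uword t = 0; t < To; ++t) {
        const sword start = (sword)(t * (uword)stride) - (sword)pad;
        for (uword k = 0; k < K; ++k) {
          const sword dst = start + (sword)k;
          if (dst >= 0 && dst < (sword)T)
            dXs.col((uword)dst) += dM.submat(k * C, t, (k + 1) * C - 1, t);
        }
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = conv_to<vec>::from(db),
      Rcpp::Named("dX") = need_dx ? Rcpp::wrap(conv_to<cube>::from(dX))
                                  : Rcpp::wrap(cube()));
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& dY, int stride, bool need_dx,
                     bool single = false) {
  if (single) return conv_bw_impl<float>(X, W, dY, stride, need_dx);
  return conv_bw_impl<double>(X, W, dY, stride, need_dx);
}
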