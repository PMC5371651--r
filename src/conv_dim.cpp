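// Convolutional PC/BC-DIM dynamics.
//
// Cross-correlations are evaluated by accumulating shifted, scaled
// submatrix additions (one AXPY per kernel tap), which avoids the memory
// traffic of an im2col expansion and is fast for the small kernels used
// here.  All maps keep the input's spatial size (zero padding outside the
// image).  Kernel anchors are passed in explicitly; the feedback pass
// uses the mirrored anchor so that it is the exact adjoint of the
// feedforward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// out.slice(j) += sum over taps of K(u,v) * shift(in.slice(i)) for one
// (kernel, input map) pair.  K is the kh x kw kernel, anchored at
// (ar, ac): out(r, c) += K(u, v) * in(r + u - ar, c + v - ac).
static void xcorr_accum(const mat& in, const mat& K, int ar, int ac,
                        mat& out) {
  const int h = in.n_rows, w = in.n_cols;
  const int kh = K.n_rows, kw = K.n_cols;
  for (int v = 0; v < kw; ++v) {
    for (int u = 0; u < kh; ++u) {
      const double wt = K(u, v);
      if (wt == 0.0) continue;
      const int dr = u - ar, dc = v - ac;
      const int r0 = std::max(0, -dr), r1 = std::min(h, h - dr) - 1;
      const int c0 = std::max(0, -dc), c1 = std::min(w, w - dc) - 1;
      if (r1 < r0 || c1 < c0) continue;
      out.submat(r0, c0, r1, c1) +=
          wt * in.submat(r0 + dr, c0 + dc, r1 + dr, c1 + dc);
    }
  }
}

// Apply a bank of multi-channel cross-correlation kernels to the stack M.
// kernels is an (n_out x n_in) field of kh x kw kernels.
static cube xcorr_bank(const cube& M, const field<mat>& kernels, int ar,
                       int ac) {
  const uword n_out = kernels.n_rows, n_in = kernels.n_cols;
  cube out(M.n_rows, M.n_cols, n_out, fill::zeros);
  for (uword j = 0; j < n_out; ++j) {
    for (uword i = 0; i < n_in; ++i) {
      xcorr_accum(M.slice(i), kernels(j, i), ar, ac, out.slice(j));
    }
  }
  return out;
}

static field<mat> unpack_kernels(const Rcpp::List& kl, int n_in) {
  const int n_out = kl.size();
  field<mat> out(n_out, n_in);
  for (int j = 0; j < n_out; ++j) {
    cube kj = Rcpp::as<cube>(kl[j]);
    for (int i = 0; i < n_in; ++i) out(j, i) = kj.slice(i);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat xcorr_same_cpp(const arma::mat& A, const arma::mat& K,
                         int ar, int ac) {
  mat out(A.n_rows, A.n_cols, fill::zeros);
  xcorr_accum(A, K, ar, ac, out);
  return out;
}

// Iterate Y <- max(eps1, Y) % sum_i(w_ji * E_i) with E derived from the
// reconstruction R = sum_j(v_ji * Y_j).  An empty Y0 means a cold start
// from Y = 0.  If floor_ > 0, responses below it are zeroed after the
// last iteration and R, E recomputed for consistency.  kernels_w is a
// list of kh x kw x k cubes (one per prediction class); kernels_v the
// matching feedback kernels (180-degree rotated, max-normalized).
// [[Rcpp::export]]
Rcpp::List conv_solve_cpp(const arma::cube& X, const Rcpp::List& kernels_w,
                          const Rcpp::List& kernels_v, int ar, int ac,
                          int arv, int acv, int n_iter, double eps1,
                          double eps2, double floor_,
                          const arma::cube& Y0) {
  const uword k = X.n_slices;
  const field<mat> Wk = unpack_kernels(kernels_w, k);
  field<mat> Vk(k, Wk.n_rows);  // transposed indexing: (channel, class)
  {
    const field<mat> Vt = unpack_kernels(kernels_v, k);
    for (uword j = 0; j < Vt.n_rows; ++j) {
      for (uword i = 0; i < k; ++i) Vk(i, j) = Vt(j, i);
    }
  }
  cube Y = Y0, R, E;
  if (Y.n_elem == 0) Y.zeros(X.n_rows, X.n_cols, Wk.n_rows);
  const cube eps2c(X.n_rows, X.n_cols, k, fill::value(eps2));
  const cube eps1c(X.n_rows, X.n_cols, Wk.n_rows, fill::value(eps1));
  for (int t = 0; t < n_iter; ++t) {
    R = xcorr_bank(Y, Vk, arv, acv);
    E = X / max(R, eps2c);
    Y = max(Y, eps1c) % xcorr_bank(E, Wk, ar, ac);
  }
  if (floor_ > 0) {
    Y.transform([floor_](double v) { return v < floor_ ? 0.0 : v; });
    R = xcorr_bank(Y, Vk, arv, acv);
    E = X / max(R, eps2c);
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("R") = R,
                            Rcpp::Named("E") = E);
}
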