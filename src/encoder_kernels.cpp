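// Hot inner kernels of the mask-self-attention encoder: per-example,
// per-head masked attention (forward and backward) and layer
// normalization. The surrounding orchestration (embeddings, large
// matmuls, Adam) stays in R; these kernels remove the small-matrix
// overhead of the per-example loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void softmax_rows_inplace(arma::mat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    S.row(i) = arma::exp(S.row(i) - m);
    S.row(i) /= arma::accu(S.row(i));
  }
}

// Q, K, V: (B*L) x H, example-major rows; masks: list of B additive
// L x L matrices. Returns the context matrix and, optionally, the
// attention weights per (example, head) for the backward pass.
// [[Rcpp::export(name = ".attn_forward")]]
List attn_forward(const arma::mat& Q, const arma::mat& K,
                  const arma::mat& V, List masks, int B, int L,
                  int nh, bool keep_weights) {
  const int H = Q.n_cols;
  const int dh = H / nh;
  const double scale = 1.0 / std::sqrt((double) dh);
  arma::mat ctx(Q.n_rows, H, arma::fill::zeros);
  List A_out(keep_weights ? B * nh : 0);
  for (int e = 0; e < B; ++e) {
    const arma::mat M = as<arma::mat>(masks[e]);
    const arma::uword r0 = (arma::uword) e * L;
    for (int h = 0; h < nh; ++h) {
      const arma::uword c0 = (arma::uword) h * dh;
      arma::mat Qe = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat Ke = K.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat S = Qe * Ke.t() * scale + M;
      softmax_rows_inplace(S);
      ctx.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        S * V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      if (keep_weights) A_out[e * nh + h] = S;
    }
  }
  return List::create(_["ctx"] = ctx, _["A"] = A_out);
}

// [[Rcpp::export(name = ".attn_backward")]]
List attn_backward(const arma::mat& dctx, const arma::mat& Q,
                   const arma::mat& K, const arma::mat& V, List A,
                   int B, int L, int nh) {
  const int H = Q.n_cols;
  const int dh = H / nh;
  const double scale = 1.0 / std::sqrt((double) dh);
  arma::mat dQ(Q.n_rows, H, arma::fill::zeros);
  arma::mat dK(Q.n_rows, H, arma::fill::zeros);
  arma::mat dV(Q.n_rows, H, arma::fill::zeros);
  for (int e = 0; e < B; ++e) {
    const arma::uword r0 = (arma::uword) e * L;
    for (int h = 0; h < nh; ++h) {
      const arma::uword c0 = (arma::uword) h * dh;
      const arma::mat Ae = as<arma::mat>(A[e * nh + h]);
      arma::mat dC = dctx.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat Ve = V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat dA = dC * Ve.t();
      dV.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = Ae.t() * dC;
      // softmax backward: dS = A * (dA - rowsum(dA % A))
      arma::vec rs = arma::sum(dA % Ae, 1);
      arma::mat dS = Ae % (dA - arma::repmat(rs, 1, L));
      dQ.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        dS * K.submat(r0, c0, r0 + L - 1, c0 + dh - 1) * scale;
      dK.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        dS.t() * Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1) * scale;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// [[Rcpp::export(name = ".ln_forward")]]
List ln_forward_cpp(const arma::mat& X, const arma::vec& g,
                    const arma::vec& b, double eps) {
  const double Hn = (double) X.n_cols;
  arma::vec mu = arma::mean(X, 1);
  arma::mat xhat = X.each_col() - mu;
  arma::vec invstd =
    1.0 / arma::sqrt(arma::sum(xhat % xhat, 1) / Hn + eps);
  xhat.each_col() %= invstd;
  arma::mat Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return List::create(_["Y"] = Y, _["xhat"] = xhat,
                      _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".ln_backward")]]
List ln_backward_cpp(const arma::mat& dY, const arma::mat& xhat,
                     const arma::vec& invstd, const arma::vec& g) {
  const double Hn = (double) dY.n_cols;
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec rs1 = arma::sum(dxhat, 1) / Hn;
  arma::vec rs2 = arma::sum(dxhat % xhat, 1) / Hn;
  arma::mat dX = dxhat.each_col() - rs1;
  dX -= xhat.each_col() % rs2;
  dX.each_col() %= invstd;
  arma::vec dg = arma::sum(dY % xhat, 0).t();
  arma::vec db = arma::sum(dY, 0).t();
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// X + one bias row per column, without an R-level matrix allocation
// [[Rcpp::export(name = ".add_bias")]]
arma::mat add_bias_cpp(const arma::mat& X, const arma::vec& b) {
  arma::mat Y = X;
  Y.each_row() += b.t();
  return Y;
}
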