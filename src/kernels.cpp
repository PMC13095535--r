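// Hot numerical kernels: scalar-token self-attention core and causal
// dilated 1-d convolution, forward and backward. Layout conventions match
// the R callers: time-major flat representations order rows with the
// instance index fastest, so a causal shift of s time steps is a shift of
// s*m rows. Left padding replicates the first time step (so a series that
// is constant in time stays constant through every convolution).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
Rcpp::List attn_core_fwd_cpp(const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V) {
  const uword m = Q.n_rows, w = Q.n_cols;
  mat O(m, w);
  cube A(w, w, m);
  for (uword i = 0; i < m; ++i) {
    const rowvec q = Q.row(i), k = K.row(i), v = V.row(i);
    mat L = q.t() * k;                      // logits: outer product (w x w)
    vec mx = max(L, 1);
    L.each_col() -= mx;
    L = exp(L);
    vec rs = sum(L, 1);
    L.each_col() /= rs;                     // row softmax
    A.slice(i) = L;
    O.row(i) = (L * v.t()).t();
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
Rcpp::List attn_core_bwd_cpp(const arma::mat& dO, const arma::cube& A,
                             const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V) {
  const uword m = Q.n_rows, w = Q.n_cols;
  mat dQ(m, w), dK(m, w), dV(m, w);
  for (uword i = 0; i < m; ++i) {
    const mat& Ai = A.slice(i);
    const rowvec doi = dO.row(i);
    dV.row(i) = doi * Ai;
    mat dA = doi.t() * V.row(i);            // dA(j,l) = dO(j) * v(l)
    vec rs = sum(dA % Ai, 1);
    mat dL = Ai % (dA.each_col() - rs);
    dQ.row(i) = (dL * K.row(i).t()).t();
    dK.row(i) = Q.row(i) * dL;
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// causal dilated conv with replicate left padding
static mat conv_f(const mat& X, const Rcpp::List& W, const rowvec& b,
                  int m, int mT, int dilation) {
  mat Y(mT, b.n_elem);
  Y.each_row() = b;
  const mat X0 = X.rows(0, m - 1);          // first time step
  for (int k = 0; k < W.size(); ++k) {
    const mat Wk = Rcpp::as<mat>(W[k]);
    const int s = k * dilation * m;
    if (s == 0) {
      Y += X * Wk;
      continue;
    }
    if (s < mT) Y.rows(s, mT - 1) += X.rows(0, mT - 1 - s) * Wk;
    const mat P = X0 * Wk;
    const int nblk = std::min(s, mT) / m;
    for (int j = 0; j < nblk; ++j) Y.rows(j * m, j * m + m - 1) += P;
  }
  return Y;
}

static void conv_b(const mat& dY, const mat& X, const Rcpp::List& W,
                   int m, int mT, int dilation, mat& dX, Rcpp::List& dW,
                   rowvec& db) {
  dX.zeros(mT, X.n_cols);
  for (int k = 0; k < W.size(); ++k) {
    const mat Wk = Rcpp::as<mat>(W[k]);
    const int s = k * dilation * m;
    mat dWk(X.n_cols, Wk.n_cols, fill::zeros);
    if (s == 0) {
      dX += dY * Wk.t();
      dWk = X.t() * dY;
    } else {
      if (s < mT) {
        dX.rows(0, mT - 1 - s) += dY.rows(s, mT - 1) * Wk.t();
        dWk = X.rows(0, mT - 1 - s).t() * dY.rows(s, mT - 1);
      }
      const int nblk = std::min(s, mT) / m;
      mat dsum(m, dY.n_cols, fill::zeros);
      for (int j = 0; j < nblk; ++j) dsum += dY.rows(j * m, j * m + m - 1);
      dX.rows(0, m - 1) += dsum * Wk.t();
      dWk += X.rows(0, m - 1).t() * dsum;
    }
    dW[k] = dWk;
  }
  db = sum(dY, 0);
}

// [[Rcpp::export]]
arma::mat conv_causal_fwd_cpp(const arma::mat& flat, int m, int T_len,
                              const Rcpp::List& W, const arma::rowvec& b,
                              int dilation) {
  return conv_f(flat, W, b, m, m * T_len, dilation);
}

// [[Rcpp::export]]
Rcpp::List conv_causal_bwd_cpp(const arma::mat& dY, const arma::mat& flat,
                               int m, int T_len, const Rcpp::List& W,
                               int dilation) {
  mat dX;
  Rcpp::List dW(W.size());
  rowvec db;
  conv_b(dY, flat, W, m, m * T_len, dilation, dX, dW, db);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// residual block forward: relu(conv2(relu(conv1(x))) + proj(x));
// proj is a {W, b} linear (1x1 conv) when channel counts differ, else NULL
// [[Rcpp::export]]
Rcpp::List tcn_block_fwd_cpp(const arma::mat& flat, int m, int T_len,
                             const Rcpp::List& blk, int dilation) {
  const int mT = m * T_len;
  const Rcpp::List conv1 = blk["conv1"], conv2 = blk["conv2"];
  mat c1 = conv_f(flat, conv1["W"], Rcpp::as<rowvec>(conv1["b"]), m, mT,
                  dilation);
  mat mask1 = conv_to<mat>::from(c1 > 0);
  mat r1 = c1 % mask1;
  mat pre = conv_f(r1, conv2["W"], Rcpp::as<rowvec>(conv2["b"]), m, mT,
                   dilation);
  if (!Rf_isNull(blk["proj"])) {
    const Rcpp::List proj = blk["proj"];
    pre += flat * Rcpp::as<mat>(proj["W"]);
    pre.each_row() += Rcpp::as<rowvec>(proj["b"]);
  } else {
    pre += flat;
  }
  mat maskp = conv_to<mat>::from(pre > 0);
  mat out = pre % maskp;
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("r1") = r1,
                            Rcpp::Named("mask1") = mask1,
                            Rcpp::Named("maskp") = maskp);
}

// [[Rcpp::export]]
Rcpp::List tcn_block_bwd_cpp(const arma::mat& dOut, const arma::mat& flat,
                             const arma::mat& r1, const arma::mat& mask1,
                             const arma::mat& maskp, const Rcpp::List& blk,
                             int m, int T_len, int dilation) {
  const int mT = m * T_len;
  const Rcpp::List conv1 = blk["conv1"], conv2 = blk["conv2"];
  const Rcpp::List W1 = conv1["W"], W2 = conv2["W"];
  mat dPre = dOut % maskp;
  mat dR1;
  Rcpp::List dW2(W2.size());
  rowvec db2;
  conv_b(dPre, r1, W2, m, mT, dilation, dR1, dW2, db2);
  mat dC1 = dR1 % mask1;
  mat dFlat;
  Rcpp::List dW1(W1.size());
  rowvec db1;
  conv_b(dC1, flat, W1, m, mT, dilation, dFlat, dW1, db1);
  Rcpp::List proj_grads = R_NilValue;
  if (!Rf_isNull(blk["proj"])) {
    const Rcpp::List proj = blk["proj"];
    dFlat += dPre * Rcpp::as<mat>(proj["W"]).t();
    proj_grads = Rcpp::List::create(Rcpp::Named("W") = flat.t() * dPre,
                                    Rcpp::Named("b") = sum(dPre, 0));
  } else {
    dFlat += dPre;
  }
  return Rcpp::List::create(
    Rcpp::Named("dFlat") = dFlat,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("conv1") = Rcpp::List::create(Rcpp::Named("W") = dW1,
                                                Rcpp::Named("b") = db1),
      Rcpp::Named("conv2") = Rcpp::List::create(Rcpp::Named("W") = dW2,
                                                Rcpp::Named("b") = db2),
      Rcpp::Named("proj") = proj_grads));
}
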