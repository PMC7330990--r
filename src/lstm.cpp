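// Single-layer LSTM core shared by the peptide language model and the
// binding-affinity regressor. All dropout is realised OUTSIDE this file:
// callers pass pre-masked weights (weight-drop on the recurrent matrix,
// row-drop on the embedding) and pre-scaled input/output masks, so every
// function here is deterministic. Gradients are exact and are verified
// against central finite differences in the test suite.
//
// Shapes (B batch, T max time, E embedding, H hidden, V vocabulary):
//   X       B x T   1-based token indices, <pad>-filled on the right
//   lengths B       true sequence lengths (positions t <= len are valid)
//   Wemb    V x E   (effective) embedding matrix
//   inmask  B x E   variational input-dropout mask, same at every t
//   Wx      E x 4H  input-to-gate weights, gate order [i f g o]
//   Wh      H x 4H  (effective) recurrent weights
//   b       4H      gate bias
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube Xe;                      // B x E x T embedded (masked) inputs
  cube Hs, Cs;                  // B x H x T states
  cube Gi, Gf, Gg, Go, Tc;      // gate activations and tanh(c)
};

// Forward pass over the whole padded block. Positions beyond a row's length
// are computed but never read by any head, and their gradients are masked
// out in the backward pass.
static void lstm_forward(const imat& X, const ivec& lengths, const mat& Wemb,
                         const mat& inmask, const mat& Wx, const mat& Wh,
                         const rowvec& b, LstmCache& cc) {
  const uword B = X.n_rows, T = X.n_cols;
  const uword E = Wemb.n_cols, H = Wh.n_rows;
  cc.Xe.set_size(B, E, T);
  cc.Hs.set_size(B, H, T);
  cc.Cs.set_size(B, H, T);
  cc.Gi.set_size(B, H, T); cc.Gf.set_size(B, H, T);
  cc.Gg.set_size(B, H, T); cc.Go.set_size(B, H, T);
  cc.Tc.set_size(B, H, T);

  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat xt(B, E);
    for (uword i = 0; i < B; ++i) {
      xt.row(i) = Wemb.row((uword)(X(i, t) - 1)) % inmask.row(i);
    }
    cc.Xe.slice(t) = xt;
    mat z = xt * Wx + h * Wh;
    z.each_row() += b;
    mat gi = sigm(z.cols(0, H - 1));
    mat gf = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = sigm(z.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    cc.Gi.slice(t) = gi; cc.Gf.slice(t) = gf;
    cc.Gg.slice(t) = gg; cc.Go.slice(t) = go;
    cc.Tc.slice(t) = tc;
    cc.Cs.slice(t) = c;
    cc.Hs.slice(t) = h;
  }
}

// Backward pass through time. dH holds the head gradients w.r.t. every
// hidden state (already zero at invalid positions). Returns gradients for
// the effective weights; the caller undoes the dropout scaling.
static void lstm_backward(const imat& X, const ivec& lengths, const mat& Wemb,
                          const mat& inmask, const mat& Wx, const mat& Wh,
                          const LstmCache& cc, const cube& dH,
                          mat& dWemb, mat& dWx, mat& dWh, rowvec& db) {
  const uword B = X.n_rows, T = X.n_cols;
  const uword E = Wemb.n_cols, H = Wh.n_rows;
  dWemb.zeros(Wemb.n_rows, E);
  dWx.zeros(E, 4 * H);
  dWh.zeros(H, 4 * H);
  db.zeros(4 * H);

  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat dh = dH.slice(tt) + dh_next;
    mat dc = dc_next;
    // mask rows whose sequence ended before this position
    for (uword i = 0; i < B; ++i) {
      if ((sword)tt >= lengths(i)) { dh.row(i).zeros(); dc.row(i).zeros(); }
    }
    const mat& gi = cc.Gi.slice(tt); const mat& gf = cc.Gf.slice(tt);
    const mat& gg = cc.Gg.slice(tt); const mat& go = cc.Go.slice(tt);
    const mat& tc = cc.Tc.slice(tt);
    dc += dh % go % (1.0 - tc % tc);
    mat c_prev = (tt == 0) ? mat(B, H, fill::zeros) : cc.Cs.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(B, H, fill::zeros) : cc.Hs.slice(tt - 1);
    mat dzi = (dc % gg) % gi % (1.0 - gi);
    mat dzf = (dc % c_prev) % gf % (1.0 - gf);
    mat dzg = (dc % gi) % (1.0 - gg % gg);
    mat dzo = (dh % tc) % go % (1.0 - go);
    mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));

    dWx += cc.Xe.slice(tt).t() * dz;
    dWh += h_prev.t() * dz;
    db += sum(dz, 0);
    mat dxe = dz * Wx.t();
    for (uword i = 0; i < B; ++i) {
      if ((sword)tt < lengths(i)) {
        dWemb.row((uword)(X(i, tt) - 1)) += dxe.row(i) % inmask.row(i);
      }
    }
    dh_next = dz * Wh.t();
    dc_next = dc % gf;
  }
}

// Hidden states only (deterministic eval path used for prediction and for
// the exported concat-pooling / language-model probability helpers).
// [[Rcpp::export]]
arma::cube cpp_lstm_hidden(const arma::imat& X, const arma::ivec& lengths,
                           const arma::mat& Wemb, const arma::mat& inmask,
                           const arma::mat& Wx, const arma::mat& Wh,
                           const arma::rowvec& b) {
  LstmCache cc;
  lstm_forward(X, lengths, Wemb, inmask, Wx, Wh, b, cc);
  return cc.Hs;
}

// One language-model step: mean next-token cross-entropy over all valid
// prediction positions (position t predicts token t+1; t runs to len-1),
// argmax accuracy counts, and (optionally) exact gradients.
// outmask is the B x H output-dropout mask applied to h before projection.
// [[Rcpp::export]]
Rcpp::List cpp_lm_step(const arma::imat& X, const arma::ivec& lengths,
                       const arma::mat& Wemb, const arma::mat& inmask,
                       const arma::mat& Wx, const arma::mat& Wh,
                       const arma::rowvec& b, const arma::mat& Wlm,
                       const arma::rowvec& blm, const arma::mat& outmask,
                       bool want_grad) {
  const uword B = X.n_rows, T = X.n_cols;
  const uword H = Wh.n_rows, V = Wlm.n_cols;
  LstmCache cc;
  lstm_forward(X, lengths, Wemb, inmask, Wx, Wh, b, cc);

  // count valid prediction positions
  double n_pos = 0.0;
  for (uword i = 0; i < B; ++i) n_pos += std::max((sword)0, lengths(i) - 1);
  if (n_pos == 0.0) Rcpp::stop("no valid next-token positions in batch");

  double ce_sum = 0.0;
  double n_correct = 0.0;
  cube dH(B, H, T, fill::zeros);
  mat dWlm(H, V, fill::zeros);
  rowvec dblm(V, fill::zeros);

  for (uword t = 0; t + 1 < T; ++t) {
    // rows with a next token at position t+1
    std::vector<uword> rows;
    for (uword i = 0; i < B; ++i) {
      if ((sword)t + 1 < lengths(i)) rows.push_back(i);
    }
    if (rows.empty()) continue;
    uvec ridx(rows.size());
    for (size_t k = 0; k < rows.size(); ++k) ridx(k) = rows[k];
    mat hu = cc.Hs.slice(t).rows(ridx) % outmask.rows(ridx);
    mat logits = hu * Wlm;
    logits.each_row() += blm;
    // row-wise stable softmax
    vec mx = max(logits, 1);
    logits.each_col() -= mx;
    mat ex = exp(logits);
    vec zs = sum(ex, 1);
    mat prob = ex.each_col() / zs;
    mat dlog = prob;
    for (size_t k = 0; k < rows.size(); ++k) {
      uword tgt = (uword)(X(rows[k], t + 1) - 1);
      ce_sum += -(logits(k, tgt) - std::log(zs(k)));
      if (prob.row(k).index_max() == tgt) n_correct += 1.0;
      dlog(k, tgt) -= 1.0;
    }
    if (want_grad) {
      dlog /= n_pos;
      dWlm += hu.t() * dlog;
      dblm += sum(dlog, 0);
      mat dhu = dlog * Wlm.t();
      mat dh_full(B, H, fill::zeros);
      dh_full.rows(ridx) = dhu % outmask.rows(ridx);
      dH.slice(t) += dh_full;
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = ce_sum / n_pos,
    Rcpp::Named("n_positions") = n_pos,
    Rcpp::Named("n_correct") = n_correct
  );
  if (want_grad) {
    mat dWemb, dWx, dWh; rowvec db_;
    lstm_backward(X, lengths, Wemb, inmask, Wx, Wh, cc, dH,
                  dWemb, dWx, dWh, db_);
    out["grads"] = Rcpp::List::create(
      Rcpp::Named("emb") = dWemb, Rcpp::Named("Wx") = dWx,
      Rcpp::Named("Wh") = dWh, Rcpp::Named("b") = db_,
      Rcpp::Named("Wlm") = dWlm, Rcpp::Named("blm") = dblm
    );
  }
  return out;
}

// One regression step: concat pooling (last / max / mean over the valid
// positions), two fully connected layers (ReLU between), censored MSE, and
// (optionally) exact gradients. headmask is the dropout mask on the first
// FC activation. branch codes: 0 point, 1 at_least, 2 at_most.
// [[Rcpp::export]]
Rcpp::List cpp_reg_step(const arma::imat& X, const arma::ivec& lengths,
                        const arma::mat& Wemb, const arma::mat& inmask,
                        const arma::mat& Wx, const arma::mat& Wh,
                        const arma::rowvec& b, const arma::mat& W1,
                        const arma::rowvec& b1, const arma::vec& W2,
                        double b2, const arma::mat& headmask,
                        const arma::vec& y, const arma::ivec& branch,
                        bool want_grad) {
  const uword B = X.n_rows, T = X.n_cols;
  const uword H = Wh.n_rows, D = W1.n_cols;
  LstmCache cc;
  lstm_forward(X, lengths, Wemb, inmask, Wx, Wh, b, cc);

  // concat pooling with max-argmax bookkeeping for the backward pass
  mat P(B, 3 * H);
  umat amax(B, H);
  for (uword i = 0; i < B; ++i) {
    uword L = (uword)lengths(i);
    rowvec hmax = cc.Hs.slice(0).row(i);
    rowvec hsum = cc.Hs.slice(0).row(i);
    for (uword h = 0; h < H; ++h) amax(i, h) = 0;
    for (uword t = 1; t < L; ++t) {
      rowvec ht = cc.Hs.slice(t).row(i);
      for (uword h = 0; h < H; ++h) {
        if (ht(h) > hmax(h)) { hmax(h) = ht(h); amax(i, h) = t; }
      }
      hsum += ht;
    }
    P(i, span(0, H - 1)) = cc.Hs.slice(L - 1).row(i);
    P(i, span(H, 2 * H - 1)) = hmax;
    P(i, span(2 * H, 3 * H - 1)) = hsum / (double)L;
  }

  mat z1 = P * W1;
  z1.each_row() += b1;
  // leaky rectifier: a plain ReLU head can die wholesale on small batches,
  // freezing the model at a constant prediction
  mat a1 = clamp(z1, 0.0, datum::inf) + 0.01 * clamp(z1, -datum::inf, 0.0);
  mat a1d = a1 % headmask;
  vec pred = a1d * W2 + b2;

  // censored mean-squared error
  vec resid = pred - y;
  vec active(B);
  for (uword i = 0; i < B; ++i) {
    if (branch(i) == 0) active(i) = 1.0;
    else if (branch(i) == 1) active(i) = (resid(i) < 0) ? 1.0 : 0.0;
    else active(i) = (resid(i) > 0) ? 1.0 : 0.0;
  }
  vec lvec = active % resid % resid;
  double loss = mean(lvec);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("pred") = pred,
    Rcpp::Named("pooled") = P
  );
  if (want_grad) {
    vec dpred = 2.0 * (active % resid) / (double)B;
    mat da1d = dpred * W2.t();
    vec dW2 = a1d.t() * dpred;
    double db2 = accu(dpred);
    mat da1 = da1d % headmask;
    da1.elem(find(z1 <= 0)) *= 0.01;
    mat dW1 = P.t() * da1;
    rowvec db1 = sum(da1, 0);
    mat dP = da1 * W1.t();

    cube dH(B, H, T, fill::zeros);
    for (uword i = 0; i < B; ++i) {
      uword L = (uword)lengths(i);
      for (uword h = 0; h < H; ++h) {
        dH(i, h, L - 1) += dP(i, h);
        dH(i, h, amax(i, h)) += dP(i, H + h);
        for (uword t = 0; t < L; ++t) dH(i, h, t) += dP(i, 2 * H + h) / (double)L;
      }
    }
    mat dWemb, dWx, dWh; rowvec db_;
    lstm_backward(X, lengths, Wemb, inmask, Wx, Wh, cc, dH,
                  dWemb, dWx, dWh, db_);
    out["grads"] = Rcpp::List::create(
      Rcpp::Named("emb") = dWemb, Rcpp::Named("Wx") = dWx,
      Rcpp::Named("Wh") = dWh, Rcpp::Named("b") = db_,
      Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
      Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2
    );
  }
  return out;
}
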