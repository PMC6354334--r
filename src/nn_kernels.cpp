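// Batched forward/backward kernels for the relation classifier:
// a peephole LSTM (gates see the cell state through full weight matrices,
// as the architecture writes them) and a multi-width sigmoid convolution
// with max-pooling. Layouts: sequence tensors are cubes (dim, batch, step);
// masks are (batch, step) with 1 for real tokens. Masked steps carry hidden
// and cell state through unchanged, so padding never changes the output.
// Per-step / per-window GEMMs keep the working set inside cache, which on a
// single core beats batching everything into one large multiply.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::cube& X, const arma::mat& mask,
                      const arma::mat& Wx, const arma::mat& Wh,
                      const arma::mat& Pi, const arma::mat& Pf,
                      const arma::mat& Po, const arma::vec& b,
                      bool reverse) {
  const uword d = X.n_rows, B = X.n_cols, n = X.n_slices;
  const uword h = Wh.n_cols;
  if (Wx.n_cols != d) stop("lstm_forward: input width mismatch");

  cube H(h, B, n), C(h, B, n), I(h, B, n), F(h, B, n), G(h, B, n), O(h, B, n);
  mat h_prev(h, B, fill::zeros), c_prev(h, B, fill::zeros);
  const mat Pif = join_cols(Pi, Pf);

  for (uword s = 0; s < n; ++s) {
    uword t = reverse ? (n - 1 - s) : s;
    rowvec m = mask.col(t).t();
    rowvec m1 = 1.0 - m;
    mat a = Wx * X.slice(t) + Wh * h_prev;
    a.each_col() += b;
    mat pif_c = Pif * c_prev;
    mat ig = sigm(a.rows(0, h - 1) + pif_c.rows(0, h - 1));
    mat fg = sigm(a.rows(h, 2 * h - 1) + pif_c.rows(h, 2 * h - 1));
    mat gg = tanh(a.rows(2 * h, 3 * h - 1));
    mat c_new = fg % c_prev + ig % gg;
    mat og = sigm(a.rows(3 * h, 4 * h - 1) + Po * c_new);
    mat h_new = og % tanh(c_new);
    // masked columns carry state through unchanged
    c_new.each_row() %= m;
    h_new.each_row() %= m;
    mat keep_c = c_prev; keep_c.each_row() %= m1;
    mat keep_h = h_prev; keep_h.each_row() %= m1;
    c_new += keep_c;
    h_new += keep_h;
    I.slice(t) = ig; F.slice(t) = fg; G.slice(t) = gg; O.slice(t) = og;
    C.slice(t) = c_new; H.slice(t) = h_new;
    h_prev = H.slice(t);
    c_prev = C.slice(t);
  }
  return List::create(_["H"] = H, _["C"] = C, _["I"] = I, _["F"] = F,
                      _["G"] = G, _["O"] = O);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::cube& dH, const arma::cube& X,
                       const arma::mat& mask,
                       const arma::cube& H, const arma::cube& C,
                       const arma::cube& I, const arma::cube& F,
                       const arma::cube& G, const arma::cube& O,
                       const arma::mat& Wx, const arma::mat& Wh,
                       const arma::mat& Pi, const arma::mat& Pf,
                       const arma::mat& Po, const arma::vec& b,
                       bool reverse) {
  const uword d = X.n_rows, B = X.n_cols, n = X.n_slices;
  const uword h = Wh.n_cols;

  cube dX(d, B, n, fill::zeros);
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  mat dPi(size(Pi), fill::zeros), dPf(size(Pf), fill::zeros),
      dPo(size(Po), fill::zeros);
  vec db(4 * h, fill::zeros);
  mat dh_carry(h, B, fill::zeros), dc_carry(h, B, fill::zeros);
  const mat WhT = Wh.t();
  const mat PifT = join_rows(Pi.t(), Pf.t());  // (h x 2h)
  const mat PoT = Po.t();

  for (uword s = 0; s < n; ++s) {
    // walk processing order backwards
    uword t = reverse ? s : (n - 1 - s);
    bool first_step = reverse ? (t == n - 1) : (t == 0);
    mat c_prev(h, B, fill::zeros), h_prev(h, B, fill::zeros);
    if (!first_step) {
      uword t_prev = reverse ? (t + 1) : (t - 1);
      c_prev = C.slice(t_prev);
      h_prev = H.slice(t_prev);
    }

    rowvec m = mask.col(t).t();
    rowvec m1 = 1.0 - m;

    mat dh_tot = dH.slice(t) + dh_carry;
    mat tc = tanh(C.slice(t));
    const mat& ig = I.slice(t); const mat& fg = F.slice(t);
    const mat& gg = G.slice(t); const mat& og = O.slice(t);

    mat do_raw = dh_tot % tc % og % (1.0 - og);
    mat dc = dh_tot % og % (1.0 - tc % tc) + PoT * do_raw + dc_carry;
    mat di_raw = dc % gg % ig % (1.0 - ig);
    mat df_raw = dc % c_prev % fg % (1.0 - fg);
    mat dg_raw = dc % ig % (1.0 - gg % gg);
    mat dc_prev_un = dc % fg + PifT * join_cols(di_raw, df_raw);

    di_raw.each_row() %= m; df_raw.each_row() %= m;
    dg_raw.each_row() %= m; do_raw.each_row() %= m;
    mat da = join_cols(join_cols(di_raw, df_raw), join_cols(dg_raw, do_raw));

    dWx += da * X.slice(t).t();
    dWh += da * h_prev.t();
    db += sum(da, 1);
    dPi += di_raw * c_prev.t();
    dPf += df_raw * c_prev.t();
    dPo += do_raw * C.slice(t).t();
    dX.slice(t) = Wx.t() * da;

    dh_carry = WhT * da;
    mat keep = dh_tot; keep.each_row() %= m1;
    dh_carry += keep;
    // masked columns keep exactly the incoming cell-state gradient
    dc_prev_un.each_row() %= m;
    dc_carry.each_row() %= m1;
    dc_carry += dc_prev_un;
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["dPi"] = dPi, _["dPf"] = dPf, _["dPo"] = dPo,
                      _["db"] = db);
}

// [[Rcpp::export(name = ".conv_forward_cpp")]]
List conv_forward_cpp(const arma::cube& H, const arma::ivec& nvalid,
                      const List& W, const List& bias,
                      const arma::ivec& widths) {
  const uword D = H.n_rows, B = H.n_cols, n = H.n_slices;
  uword n_total = 0;
  for (int w = 0; w < W.size(); ++w) n_total += as<arma::mat>(W[w]).n_rows;

  mat Cmax(n_total, B); Cmax.fill(-1.0);
  umat amax(n_total, B, fill::zeros);

  uword off = 0;
  for (int w = 0; w < W.size(); ++w) {
    mat Wk = W[w];
    vec bk = bias[w];
    uword k = (uword) widths[w];
    if (Wk.n_cols != k * D) stop("conv_forward: filter width mismatch");
    if (n < k) stop("conv_forward: sequence shorter than filter width");
    uword nf = Wk.n_rows, nwin = n - k + 1;
    mat win(k * D, B);
    for (uword j = 0; j < nwin; ++j) {
      for (uword r = 0; r < k; ++r)
        win.rows(r * D, (r + 1) * D - 1) = H.slice(j + r);
      mat S = Wk * win;
      S.each_col() += bk;
      mat sg = sigm(S);
      for (uword col = 0; col < B; ++col) {
        if ((sword) j >= nvalid[col]) continue;  // window entirely in padding
        for (uword f = 0; f < nf; ++f) {
          if (sg(f, col) > Cmax(off + f, col)) {
            Cmax(off + f, col) = sg(f, col);
            amax(off + f, col) = j;
          }
        }
      }
    }
    off += nf;
  }
  return List::create(_["C"] = Cmax, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".conv_backward_cpp")]]
List conv_backward_cpp(const arma::mat& dC, const arma::cube& H,
                       const arma::mat& Cmax, const arma::umat& amax,
                       const List& W, const arma::ivec& widths) {
  const uword D = H.n_rows, B = H.n_cols, n = H.n_slices;
  cube dHc(D, B, n, fill::zeros);
  List dW(W.size()), db(W.size());

  mat dS_all = dC % Cmax % (1.0 - Cmax);  // sigmoid applied before pooling

  uword off = 0;
  for (int w = 0; w < W.size(); ++w) {
    mat Wk = W[w];
    uword k = (uword) widths[w], nf = Wk.n_rows, nwin = n - k + 1;
    mat dWk(size(Wk), fill::zeros);
    vec dbk(nf, fill::zeros);
    mat dS = dS_all.rows(off, off + nf - 1);
    umat am = amax.rows(off, off + nf - 1);
    mat win(k * D, B);
    for (uword j = 0; j < nwin; ++j) {
      mat Dj = dS % conv_to<mat>::from(am == j);
      if (!any(any(Dj != 0))) continue;   // no filter won this window
      for (uword r = 0; r < k; ++r)
        win.rows(r * D, (r + 1) * D - 1) = H.slice(j + r);
      dWk += Dj * win.t();
      dbk += sum(Dj, 1);
      mat dwin = Wk.t() * Dj;
      for (uword r = 0; r < k; ++r)
        dHc.slice(j + r) += dwin.rows(r * D, (r + 1) * D - 1);
    }
    dW[w] = dWk;
    db[w] = dbk;
    off += nf;
  }
  return List::create(_["dH"] = dHc, _["dW"] = dW, _["db"] = db);
}
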