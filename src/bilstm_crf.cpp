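// Batched BiLSTM encoder + linear-chain CRF in log space.
//
// Layout conventions shared with the R side:
//  * params is a named list of numeric matrices:
//      emb            V x D        word embedding table (row per vocab id)
//      W<l><f|b>      in x 4H      input weights, layer l, forward/backward
//      U<l><f|b>      H  x 4H      recurrent weights
//      b<l><f|b>      1  x 4H      bias
//      Wout           2H x L       emission projection
//      bout           1  x L       emission bias
//      trans          (L+2)x(L+2)  CRF transitions; row/col L = virtual
//                                  start state, L+1 = virtual stop state
//  * gate order within the 4H axis: input | forget | output | cell
//  * token ids arrive 1-based (R rows of emb); labels arrive 0-based.
//  * sentences are padded at the end; masked steps have zeroed states, which
//    is exact here because the forward direction only pads the tail and the
//    reverse direction only pads the head of its own iteration order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double lse(const vec& x) {
  double m = x.max();
  return m + std::log(accu(exp(x - m)));
}

// ---------------------------------------------------------------------------
// CRF primitives (single sentence)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double crf_logZ_cpp(const arma::mat& em, const arma::mat& trans) {
  const int n = em.n_rows, L = em.n_cols;
  const int start = L, stop = L + 1;
  vec alpha = em.row(0).t() + trans(start, span(0, L - 1)).t();
  for (int t = 1; t < n; ++t) {
    vec nxt(L);
    for (int j = 0; j < L; ++j) {
      nxt(j) = lse(alpha + trans(span(0, L - 1), j)) + em(t, j);
    }
    alpha = nxt;
  }
  return lse(alpha + trans(span(0, L - 1), stop));
}

// [[Rcpp::export]]
double crf_score_cpp(const arma::mat& em, const arma::mat& trans,
                     const arma::ivec& y) {
  const int n = em.n_rows, L = em.n_cols;
  const int start = L, stop = L + 1;
  double s = trans(start, y(0)) + em(0, y(0));
  for (int t = 1; t < n; ++t) s += trans(y(t - 1), y(t)) + em(t, y(t));
  s += trans(y(n - 1), stop);
  return s;
}

// Viterbi with deterministic tie-breaking: the lower label index wins both
// in the running maximum and in the backtrace (strict > comparison).
// [[Rcpp::export]]
Rcpp::List crf_viterbi_cpp(const arma::mat& em, const arma::mat& trans) {
  const int n = em.n_rows, L = em.n_cols;
  const int start = L, stop = L + 1;
  mat delta(n, L);
  imat psi(n, L, fill::zeros);
  for (int j = 0; j < L; ++j) delta(0, j) = trans(start, j) + em(0, j);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < L; ++j) {
      double best = delta(t - 1, 0) + trans(0, j);
      int arg = 0;
      for (int k = 1; k < L; ++k) {
        double v = delta(t - 1, k) + trans(k, j);
        if (v > best) { best = v; arg = k; }
      }
      delta(t, j) = best + em(t, j);
      psi(t, j) = arg;
    }
  }
  double best = delta(n - 1, 0) + trans(0, stop);
  int arg = 0;
  for (int k = 1; k < L; ++k) {
    double v = delta(n - 1, k) + trans(k, stop);
    if (v > best) { best = v; arg = k; }
  }
  ivec path(n);
  path(n - 1) = arg;
  for (int t = n - 1; t > 0; --t) path(t - 1) = psi(t, path(t));
  return Rcpp::List::create(Rcpp::Named("path") = path,
                            Rcpp::Named("score") = best);
}

// NLL and gradients for one sentence; accumulates into d_em / d_trans.
static double crf_nll_grad(const mat& em, const mat& trans, const ivec& y,
                           mat& d_em, mat& d_trans) {
  const int n = em.n_rows, L = em.n_cols;
  const int start = L, stop = L + 1;
  mat alpha(n, L), beta(n, L);
  alpha.row(0) = em.row(0) + trans(start, span(0, L - 1));
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < L; ++j) {
      alpha(t, j) = lse(alpha.row(t - 1).t() + trans(span(0, L - 1), j)) + em(t, j);
    }
  }
  double logZ = lse(alpha.row(n - 1).t() + trans(span(0, L - 1), stop));
  for (int j = 0; j < L; ++j) beta(n - 1, j) = trans(j, stop);
  for (int t = n - 2; t >= 0; --t) {
    for (int k = 0; k < L; ++k) {
      vec v = trans(k, span(0, L - 1)).t() + em.row(t + 1).t() + beta.row(t + 1).t();
      beta(t, k) = lse(v);
    }
  }
  // unary marginals -> emission gradient
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < L; ++j) {
      d_em(t, j) += std::exp(alpha(t, j) + beta(t, j) - logZ);
    }
    d_em(t, y(t)) -= 1.0;
  }
  // pairwise marginals -> transition gradient
  for (int j = 0; j < L; ++j) {
    d_trans(start, j) += std::exp(alpha(0, j) + beta(0, j) - logZ);
    d_trans(j, stop) += std::exp(alpha(n - 1, j) + beta(n - 1, j) - logZ);
  }
  d_trans(start, y(0)) -= 1.0;
  d_trans(y(n - 1), stop) -= 1.0;
  for (int t = 0; t + 1 < n; ++t) {
    for (int k = 0; k < L; ++k) {
      for (int j = 0; j < L; ++j) {
        d_trans(k, j) += std::exp(alpha(t, k) + trans(k, j) + em(t + 1, j) +
                                  beta(t + 1, j) - logZ);
      }
    }
    d_trans(y(t), y(t + 1)) -= 1.0;
  }
  double score = crf_score_cpp(em, trans, y);
  return logZ - score;
}

// ---------------------------------------------------------------------------
// BiLSTM encoder
// ---------------------------------------------------------------------------

struct DirCache {
  std::vector<fmat> i, f, g, o, c, tc, h;  // per time step, each B x H
};

static fmat as_f(const Rcpp::NumericMatrix& m) {
  const mat d(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false);
  return conv_to<fmat>::from(d);
}

// One direction of one layer over the padded batch. xs[t] is the B x in
// layer input; mask[t] is B x 1 with 1 for real tokens. Gate layout within
// the 4H axis is [input | forget | output | cell] so the three sigmoid
// gates are transformed in one fused pass.
static void lstm_dir_forward(const std::vector<fmat>& xs,
                             const std::vector<fvec>& mask,
                             const fmat& W, const fmat& U, const frowvec& b,
                             bool reverse, DirCache& cache,
                             std::vector<fmat>& hs) {
  const int T = xs.size();
  const int B = xs[0].n_rows;
  const int H = U.n_rows;
  cache.i.resize(T); cache.f.resize(T); cache.g.resize(T); cache.o.resize(T);
  cache.c.resize(T); cache.tc.resize(T); cache.h.resize(T);
  hs.assign(T, fmat());
  fmat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  fmat Z;
  for (int step = 0; step < T; ++step) {
    int t = reverse ? (T - 1 - step) : step;
    Z = xs[t] * W;
    Z += h_prev * U;
    Z.each_row() += b;
    // fused in-place transforms: sigmoid on [0, 3H), tanh on [3H, 4H)
    float* zp = Z.memptr();
    const size_t nsig = (size_t)B * 3 * H, nall = (size_t)B * 4 * H;
    for (size_t k = 0; k < nsig; ++k) zp[k] = 1.0f / (1.0f + std::exp(-zp[k]));
    for (size_t k = nsig; k < nall; ++k) zp[k] = std::tanh(zp[k]);
    cache.i[t] = Z.cols(0, H - 1);
    cache.f[t] = Z.cols(H, 2 * H - 1);
    cache.o[t] = Z.cols(2 * H, 3 * H - 1);
    cache.g[t] = Z.cols(3 * H, 4 * H - 1);
    fmat cn = cache.f[t] % c_prev + cache.i[t] % cache.g[t];
    fmat tc = tanh(cn);
    fmat hn = cache.o[t] % tc;
    // zero out padded rows; exact because padding is contiguous at the far
    // end of this direction's iteration order
    cn.each_col() %= mask[t];
    hn.each_col() %= mask[t];
    cache.c[t] = std::move(cn); cache.tc[t] = std::move(tc);
    cache.h[t] = hn;
    hs[t] = hn;
    h_prev = std::move(hn); c_prev = cache.c[t];
  }
}

// Backward pass of one direction. dhs[t] holds dL/dh_t from layers above;
// dxs[t] accumulates dL/dx_t; dW/dU/db accumulate parameter gradients.
static void lstm_dir_backward(const std::vector<fmat>& xs,
                              const std::vector<fvec>& mask,
                              const fmat& W, const fmat& U,
                              bool reverse, const DirCache& cache,
                              const std::vector<fmat>& dhs,
                              std::vector<fmat>& dxs,
                              fmat& dW, fmat& dU, frowvec& db) {
  const int T = xs.size();
  const int B = xs[0].n_rows;
  const int H = U.n_rows;
  fmat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    int t = reverse ? (T - 1 - step) : step;
    int t_prev = reverse ? t + 1 : t - 1;  // previous step in iteration order
    fmat h_prev = (step == 0) ? fmat(B, H, fill::zeros) : cache.h[t_prev];
    fmat c_prev = (step == 0) ? fmat(B, H, fill::zeros) : cache.c[t_prev];
    fmat dh = dhs[t] + dh_carry;
    dh.each_col() %= mask[t];
    fmat d_o = dh % cache.tc[t];
    fmat dc = dc_carry;
    dc.each_col() %= mask[t];
    dc += dh % cache.o[t] % (1.0f - square(cache.tc[t]));
    fmat dZ(B, 4 * H);
    dZ.cols(0, H - 1)         = (dc % cache.g[t]) % cache.i[t] % (1.0f - cache.i[t]);
    dZ.cols(H, 2 * H - 1)     = (dc % c_prev)     % cache.f[t] % (1.0f - cache.f[t]);
    dZ.cols(2 * H, 3 * H - 1) = d_o               % cache.o[t] % (1.0f - cache.o[t]);
    dZ.cols(3 * H, 4 * H - 1) = (dc % cache.i[t]) % (1.0f - square(cache.g[t]));
    dW += xs[t].t() * dZ;
    dU += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dxs[t] += dZ * W.t();
    dh_carry = dZ * U.t();
    dc_carry = dc % cache.f[t];
  }
}

struct Batch {
  int B, T;
  std::vector<ivec> toks;          // 0-based embedding rows, per sentence
  std::vector<int> len;
  std::vector<fvec> mask;          // per t, B x 1
};

static Batch make_batch(const Rcpp::List& tokens) {
  Batch b;
  b.B = tokens.size();
  b.T = 0;
  b.toks.resize(b.B);
  b.len.resize(b.B);
  for (int s = 0; s < b.B; ++s) {
    Rcpp::IntegerVector tv = tokens[s];
    ivec iv(tv.size());
    for (int k = 0; k < tv.size(); ++k) iv(k) = tv[k] - 1;
    b.toks[s] = iv;
    b.len[s] = tv.size();
    b.T = std::max(b.T, (int)tv.size());
  }
  b.mask.assign(b.T, fvec(b.B, fill::zeros));
  for (int t = 0; t < b.T; ++t)
    for (int s = 0; s < b.B; ++s)
      if (t < b.len[s]) b.mask[t](s) = 1.0;
  return b;
}

struct EncCache {
  std::vector<std::vector<fmat>> layer_in;          // per layer, per t: B x in
  std::vector<DirCache> cf, cb;                     // per layer
  std::vector<std::vector<fmat>> hf, hb;            // per layer, per t
  std::vector<fmat> em;                             // per t: B x L
};

// Full encoder forward over a padded batch; fills cache, returns emissions.
static void encoder_forward(const Rcpp::List& params, const Batch& batch,
                            int n_layers, EncCache& cc) {
  const fmat Emb = as_f(params["emb"]);
  const fmat Wout = as_f(params["Wout"]);
  const frowvec bout = as_f(params["bout"]);

  const int B = batch.B, T = batch.T, D = Emb.n_cols;
  cc.layer_in.assign(n_layers, std::vector<fmat>());
  cc.cf.assign(n_layers, DirCache());
  cc.cb.assign(n_layers, DirCache());
  cc.hf.assign(n_layers, std::vector<fmat>());
  cc.hb.assign(n_layers, std::vector<fmat>());

  std::vector<fmat> x(T, fmat(B, D, fill::zeros));
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < B; ++s)
      if (t < batch.len[s]) x[t].row(s) = Emb.row(batch.toks[s](t));

  for (int l = 0; l < n_layers; ++l) {
    cc.layer_in[l] = x;
    char lf[8], lb[8];
    snprintf(lf, 8, "%df", l + 1);
    snprintf(lb, 8, "%db", l + 1);
    fmat Wf = as_f(params[std::string("W") + lf]);
    fmat Uf = as_f(params[std::string("U") + lf]);
    frowvec bf = as_f(params[std::string("b") + lf]);
    fmat Wb = as_f(params[std::string("W") + lb]);
    fmat Ub = as_f(params[std::string("U") + lb]);
    frowvec bb = as_f(params[std::string("b") + lb]);
    lstm_dir_forward(x, batch.mask, Wf, Uf, bf, false, cc.cf[l], cc.hf[l]);
    lstm_dir_forward(x, batch.mask, Wb, Ub, bb, true, cc.cb[l], cc.hb[l]);
    std::vector<fmat> nx(T);
    for (int t = 0; t < T; ++t) nx[t] = join_rows(cc.hf[l][t], cc.hb[l][t]);
    x = std::move(nx);
  }
  cc.em.assign(T, fmat());
  for (int t = 0; t < T; ++t) {
    fmat e = x[t] * Wout;
    e.each_row() += bout;
    e.each_col() %= batch.mask[t];
    cc.em[t] = e;
  }
}

// [[Rcpp::export]]
Rcpp::List tagger_forward_cpp(const Rcpp::List& params,
                              const Rcpp::List& tokens, int n_layers) {
  Batch batch = make_batch(tokens);
  if (batch.B == 0) return Rcpp::List::create();
  EncCache cc;
  encoder_forward(params, batch, n_layers, cc);
  const int L = cc.em[0].n_cols;
  Rcpp::List out(batch.B);
  for (int s = 0; s < batch.B; ++s) {
    fmat e(batch.len[s], L);
    for (int t = 0; t < batch.len[s]; ++t) e.row(t) = cc.em[t].row(s);
    out[s] = conv_to<mat>::from(e);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List tagger_loss_grad_cpp(const Rcpp::List& params,
                                const Rcpp::List& tokens,
                                const Rcpp::List& labels,
                                int n_layers, bool freeze_emb) {
  Batch batch = make_batch(tokens);
  const int B = batch.B;
  EncCache cc;
  encoder_forward(params, batch, n_layers, cc);
  const int T = batch.T;
  const int L = cc.em[0].n_cols;

  const Rcpp::NumericMatrix transR = params["trans"];
  const mat trans(transR.begin(), transR.nrow(), transR.ncol());

  mat d_trans(L + 2, L + 2, fill::zeros);
  std::vector<fmat> d_em(T, fmat(B, L, fill::zeros));
  double loss = 0.0;
  for (int s = 0; s < B; ++s) {
    const int n = batch.len[s];
    mat e(n, L);
    for (int t = 0; t < n; ++t) {
      for (int j = 0; j < L; ++j) e(t, j) = cc.em[t](s, j);
    }
    Rcpp::IntegerVector lv = labels[s];
    ivec y(n);
    for (int t = 0; t < n; ++t) y(t) = lv[t];
    mat de(n, L, fill::zeros);
    loss += crf_nll_grad(e, trans, y, de, d_trans);
    for (int t = 0; t < n; ++t) {
      for (int j = 0; j < L; ++j) d_em[t](s, j) = (float)de(t, j);
    }
  }

  // backprop through the emission projection
  const fmat Wout = as_f(params["Wout"]);
  const int H2 = Wout.n_rows;
  fmat dWout(H2, L, fill::zeros);
  frowvec dbout(L, fill::zeros);
  std::vector<fmat> dtop(T, fmat(B, H2, fill::zeros));
  for (int t = 0; t < T; ++t) {
    // top layer output at t is [hf | hb] of the last layer
    fmat top = join_rows(cc.hf[n_layers - 1][t], cc.hb[n_layers - 1][t]);
    dWout += top.t() * d_em[t];
    dbout += sum(d_em[t], 0);
    dtop[t] = d_em[t] * Wout.t();
  }

  std::vector<std::string> gnames;
  std::vector<mat> gmats;
  auto push_grad = [&](const std::string& nm, const fmat& g) {
    gnames.push_back(nm);
    gmats.push_back(conv_to<mat>::from(g));
  };
  // backprop through layers, top to bottom
  std::vector<fmat> dlayer_out = dtop;  // gradient on concat(hf, hb) of layer l
  const Rcpp::NumericMatrix embR = params["emb"];
  fmat dEmb;
  if (!freeze_emb) dEmb.zeros(embR.nrow(), embR.ncol());
  for (int l = n_layers - 1; l >= 0; --l) {
    char lf[8], lb[8];
    snprintf(lf, 8, "%df", l + 1);
    snprintf(lb, 8, "%db", l + 1);
    fmat Wf = as_f(params[std::string("W") + lf]);
    fmat Uf = as_f(params[std::string("U") + lf]);
    fmat Wb = as_f(params[std::string("W") + lb]);
    fmat Ub = as_f(params[std::string("U") + lb]);
    const int H = Uf.n_rows;
    const int in_dim = Wf.n_rows;
    std::vector<fmat> dhf(T), dhb(T);
    for (int t = 0; t < T; ++t) {
      dhf[t] = dlayer_out[t].cols(0, H - 1);
      dhb[t] = dlayer_out[t].cols(H, 2 * H - 1);
    }
    std::vector<fmat> dx(T, fmat(B, in_dim, fill::zeros));
    fmat dWf(size(Wf), fill::zeros), dUf(size(Uf), fill::zeros);
    fmat dWb(size(Wb), fill::zeros), dUb(size(Ub), fill::zeros);
    frowvec dbf(4 * H, fill::zeros), dbb(4 * H, fill::zeros);
    lstm_dir_backward(cc.layer_in[l], batch.mask, Wf, Uf, false, cc.cf[l],
                      dhf, dx, dWf, dUf, dbf);
    lstm_dir_backward(cc.layer_in[l], batch.mask, Wb, Ub, true, cc.cb[l],
                      dhb, dx, dWb, dUb, dbb);
    push_grad(std::string("W") + lf, dWf / B);
    push_grad(std::string("U") + lf, dUf / B);
    push_grad(std::string("b") + lf, fmat(dbf) / B);
    push_grad(std::string("W") + lb, dWb / B);
    push_grad(std::string("U") + lb, dUb / B);
    push_grad(std::string("b") + lb, fmat(dbb) / B);
    if (l > 0) {
      dlayer_out = dx;
    } else if (!freeze_emb) {
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < B; ++s)
          if (t < batch.len[s]) dEmb.row(batch.toks[s](t)) += dx[t].row(s);
    }
  }
  push_grad("Wout", dWout / B);
  push_grad("bout", fmat(dbout) / B);
  gnames.push_back("trans");
  gmats.push_back(d_trans / B);
  if (!freeze_emb) push_grad("emb", dEmb / B);
  Rcpp::List grads(gmats.size());
  Rcpp::CharacterVector nm(gmats.size());
  for (size_t k = 0; k < gmats.size(); ++k) {
    grads[k] = gmats[k];
    nm[k] = gnames[k];
  }
  grads.attr("names") = nm;
  return Rcpp::List::create(Rcpp::Named("loss") = loss / B,
                            Rcpp::Named("grads") = grads);
}
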