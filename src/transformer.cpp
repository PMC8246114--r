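// Fused transformer forward/backward, mirroring the reference R
// implementation in R/nn.R (pre-norm encoder-decoder, multi-head scaled
// dot-product attention, ReLU feed-forward, shared embeddings, untied
// output projection, masked mean cross-entropy). The R implementation is
// the correctness oracle: with dropout disabled both paths must agree to
// numerical precision (asserted in the test suite).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Single-precision core: neural-net training is numerically robust in
// float32 and single-precision BLAS roughly doubles throughput on CPU.
typedef arma::fmat M;
typedef arma::fvec CV;
typedef arma::frowvec RV;

namespace {

struct LnCache {
  M xhat;
  CV inv;
};

M ln_f(const M& x, const RV& g,
               const RV& b, LnCache& cc) {
  CV mu = arma::mean(x, 1);
  M xc = x.each_col() - mu;
  CV v = arma::mean(xc % xc, 1);
  cc.inv = 1.0f / arma::sqrt(v + 1e-6f);
  cc.xhat = xc.each_col() % cc.inv;
  M y = cc.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

M ln_b(const M& dy, const LnCache& cc, const RV& g,
               RV& dg, RV& db) {
  dg = arma::sum(dy % cc.xhat, 0);
  db = arma::sum(dy, 0);
  M dxhat = dy.each_row() % g;
  CV m1 = arma::mean(dxhat, 1);
  CV m2 = arma::mean(dxhat % cc.xhat, 1);
  M dx = dxhat;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.inv;
  return dx;
}

struct MhaCache {
  M Q, K, V, Ctx;
  std::vector<M> P;  // B*h softmax matrices
};

// Multi-head attention over sequence-major stacked rows.
M mha_f(const M& Xq, const M& Xkv,
                const M& Wq, const M& Wk,
                const M& Wv, const M& Wo,
                int h, int B, int Lq, int Lkv,
                const arma::ivec& kv_len, bool causal, MhaCache& cc) {
  const int d = Wq.n_cols, dh = d / h;
  const float scale = 1.0f / std::sqrt((float)dh);
  cc.Q = Xq * Wq;
  cc.K = Xkv * Wk;
  cc.V = Xkv * Wv;
  cc.Ctx.zeros(Xq.n_rows, d);
  cc.P.assign(B * h, M());
  for (int b = 0; b < B; ++b) {
    const int rq0 = b * Lq, rk0 = b * Lkv;
    const int kl = kv_len[b];
    for (int hh = 0; hh < h; ++hh) {
      const int c0 = hh * dh;
      M S = cc.Q.submat(rq0, c0, rq0 + Lq - 1, c0 + dh - 1) *
        cc.K.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1).t() * scale;
      if (kl < Lkv) {
        S.cols(kl, Lkv - 1).fill(-std::numeric_limits<float>::infinity());
      }
      if (causal) {
        for (int i = 0; i < Lq; ++i) {
          for (int j = i + 1; j < Lkv; ++j) S(i, j) = -std::numeric_limits<float>::infinity();
        }
      }
      CV mx = arma::max(S, 1);
      S.each_col() -= mx;
      M P = arma::exp(S);
      P.each_col() /= arma::sum(P, 1);
      cc.P[b * h + hh] = P;
      cc.Ctx.submat(rq0, c0, rq0 + Lq - 1, c0 + dh - 1) =
        P * cc.V.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1);
    }
  }
  return cc.Ctx * Wo;
}

void mha_b(const M& dOut, const MhaCache& cc,
           const M& Xq, const M& Xkv,
           const M& Wq, const M& Wk,
           const M& Wv, const M& Wo,
           int h, int B, int Lq, int Lkv,
           M& dXq, M& dXkv,
           M& dWq, M& dWk, M& dWv, M& dWo) {
  const int d = Wq.n_cols, dh = d / h;
  const float scale = 1.0f / std::sqrt((float)dh);
  M dCtx = dOut * Wo.t();
  dWo = cc.Ctx.t() * dOut;
  M dQ(cc.Q.n_rows, d, arma::fill::zeros);
  M dK(cc.K.n_rows, d, arma::fill::zeros);
  M dV(cc.K.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int rq0 = b * Lq, rk0 = b * Lkv;
    for (int hh = 0; hh < h; ++hh) {
      const int c0 = hh * dh;
      const M& P = cc.P[b * h + hh];
      M dC = dCtx.submat(rq0, c0, rq0 + Lq - 1, c0 + dh - 1);
      M Vh = cc.V.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1);
      M dP = dC * Vh.t();
      CV rs = arma::sum(P % dP, 1);
      M dS = P % (dP.each_col() - rs) * scale;
      dQ.submat(rq0, c0, rq0 + Lq - 1, c0 + dh - 1) =
        dS * cc.K.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1);
      dK.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1) =
        dS.t() * cc.Q.submat(rq0, c0, rq0 + Lq - 1, c0 + dh - 1);
      dV.submat(rk0, c0, rk0 + Lkv - 1, c0 + dh - 1) = P.t() * dC;
    }
  }
  dXq = dQ * Wq.t();
  dXkv = dK * Wk.t() + dV * Wv.t();
  dWq = Xq.t() * dQ;
  dWk = Xkv.t() * dK;
  dWv = Xkv.t() * dV;
}

struct FfnCache {
  M H;
};

M ffn_f(const M& X, const M& W1,
                const RV& b1, const M& W2,
                const RV& b2, FfnCache& cc) {
  cc.H = X * W1;
  cc.H.each_row() += b1;
  cc.H.transform([](float v) { return v > 0 ? v : 0.0f; });
  M y = cc.H * W2;
  y.each_row() += b2;
  return y;
}

M ffn_b(const M& dOut, const FfnCache& cc, const M& X,
                const M& W1, const M& W2,
                M& dW1, RV& db1,
                M& dW2, RV& db2) {
  M dH = dOut * W2.t();
  dH.elem(arma::find(cc.H <= 0)).zeros();
  dW1 = X.t() * dH;
  db1 = arma::sum(dH, 0);
  dW2 = cc.H.t() * dOut;
  db2 = arma::sum(dOut, 0);
  return dH * W1.t();
}

M drop_mask(int nr, int nc, double p) {
  M m(nr, nc);
  const double keep = 1.0 - p;
  for (arma::uword i = 0; i < m.n_elem; ++i) {
    m(i) = (unif_rand() > p) ? 1.0f / (float)keep : 0.0f;
  }
  return m;
}

NumericMatrix dwrap(const M& x) {
  arma::mat d = arma::conv_to<arma::mat>::from(x);
  return wrap(d);
}

NumericVector vwrap(const RV& x) {
  arma::rowvec d = arma::conv_to<arma::rowvec>::from(x);
  return NumericVector(d.begin(), d.end());
}

M get_mat(const List& params, const std::string& nm) {
  NumericMatrix p = params[nm];
  arma::mat d(p.begin(), p.nrow(), p.ncol(), false);
  return arma::conv_to<M>::from(d);
}

RV get_vec(const List& params, const std::string& nm) {
  NumericVector v = params[nm];
  arma::rowvec d(v.begin(), v.size(), false);
  return arma::conv_to<RV>::from(d);
}

}  // namespace

// [[Rcpp::export]]
List transformer_fb_cpp(List params, List config, IntegerVector src,
                        IntegerVector tgt_in, IntegerVector tgt_out,
                        LogicalVector tgt_mask, IntegerVector src_len,
                        IntegerVector tgt_len, int B, int Ls, int Lt,
                        NumericMatrix pos_enc, bool want_grads, bool train) {
  RNGScope rngScope;
  const int nl = as<int>(config["layers"]);
  const int d = as<int>(config["model_dim"]);
  const int h = as<int>(config["heads"]);
  const double ls_smooth = as<double>(config["label_smoothing"]);
  const double dp = train ? as<double>(config["dropout"]) : 0.0;
  const M E = get_mat(params, "E");
  const int V = E.n_rows;
  arma::mat posd(pos_enc.begin(), pos_enc.nrow(), pos_enc.ncol(), false);
  const M pos = arma::conv_to<M>::from(posd);
  const float esc = std::sqrt((float)d);

  arma::ivec slen(B), tlen(B);
  for (int b = 0; b < B; ++b) { slen[b] = src_len[b]; tlen[b] = tgt_len[b]; }

  auto embed = [&](const IntegerVector& ids, int L) {
    arma::uvec ridx(B * L), pidx(B * L);
    for (int r = 0; r < B * L; ++r) {
      ridx[r] = ids[r] - 1;
      pidx[r] = r % L;
    }
    M X = E.rows(ridx) * esc + pos.rows(pidx);
    return X;
  };

  std::map<std::string, M> masks;
  auto dmul = [&](M X, const std::string& key) {
    if (dp <= 0) return X;
    masks[key] = drop_mask(X.n_rows, X.n_cols, dp);
    return M(X % masks[key]);
  };
  auto dback = [&](const M& dX, const std::string& key) {
    if (dp <= 0) return dX;
    return M(dX % masks.at(key));
  };

  // caches
  std::vector<LnCache> e_ln1(nl), e_ln3(nl), d_ln1(nl), d_ln2(nl), d_ln3(nl);
  LnCache lnE, lnD;
  std::vector<MhaCache> e_at(nl), d_at(nl), d_ca(nl);
  std::vector<FfnCache> e_ff(nl), d_ff(nl);
  std::vector<M> e_at_in(nl), e_ff_in(nl), d_at_in(nl), d_ca_in(nl),
      d_ff_in(nl);

  auto pn = [](const char* side, int l, const char* what) {
    return std::string(side) + std::to_string(l + 1) + "_" + what;
  };

  // ---- encoder ----
  M X = dmul(embed(src, Ls), "Eenc");
  for (int l = 0; l < nl; ++l) {
    e_at_in[l] = ln_f(X, get_vec(params, pn("enc", l, "ln1g")),
                      get_vec(params, pn("enc", l, "ln1b")), e_ln1[l]);
    M at = mha_f(e_at_in[l], e_at_in[l],
                         get_mat(params, pn("enc", l, "Wq")),
                         get_mat(params, pn("enc", l, "Wk")),
                         get_mat(params, pn("enc", l, "Wv")),
                         get_mat(params, pn("enc", l, "Wo")),
                         h, B, Ls, Ls, slen, false, e_at[l]);
    X += dmul(at, pn("enc", l, "d1"));
    e_ff_in[l] = ln_f(X, get_vec(params, pn("enc", l, "ln3g")),
                      get_vec(params, pn("enc", l, "ln3b")), e_ln3[l]);
    M ff = ffn_f(e_ff_in[l], get_mat(params, pn("enc", l, "W1")),
                         get_vec(params, pn("enc", l, "b1")),
                         get_mat(params, pn("enc", l, "W2")),
                         get_vec(params, pn("enc", l, "b2")), e_ff[l]);
    X += dmul(ff, pn("enc", l, "d2"));
  }
  M mem = ln_f(X, get_vec(params, "lnEg"), get_vec(params, "lnEb"),
                       lnE);

  // ---- decoder ----
  M Y = dmul(embed(tgt_in, Lt), "Edec");
  for (int l = 0; l < nl; ++l) {
    d_at_in[l] = ln_f(Y, get_vec(params, pn("dec", l, "ln1g")),
                      get_vec(params, pn("dec", l, "ln1b")), d_ln1[l]);
    M at = mha_f(d_at_in[l], d_at_in[l],
                         get_mat(params, pn("dec", l, "Wq")),
                         get_mat(params, pn("dec", l, "Wk")),
                         get_mat(params, pn("dec", l, "Wv")),
                         get_mat(params, pn("dec", l, "Wo")),
                         h, B, Lt, Lt, tlen, true, d_at[l]);
    Y += dmul(at, pn("dec", l, "d1"));
    d_ca_in[l] = ln_f(Y, get_vec(params, pn("dec", l, "ln2g")),
                      get_vec(params, pn("dec", l, "ln2b")), d_ln2[l]);
    M ca = mha_f(d_ca_in[l], mem,
                         get_mat(params, pn("dec", l, "cWq")),
                         get_mat(params, pn("dec", l, "cWk")),
                         get_mat(params, pn("dec", l, "cWv")),
                         get_mat(params, pn("dec", l, "cWo")),
                         h, B, Lt, Ls, slen, false, d_ca[l]);
    Y += dmul(ca, pn("dec", l, "d2"));
    d_ff_in[l] = ln_f(Y, get_vec(params, pn("dec", l, "ln3g")),
                      get_vec(params, pn("dec", l, "ln3b")), d_ln3[l]);
    M ff = ffn_f(d_ff_in[l], get_mat(params, pn("dec", l, "W1")),
                         get_vec(params, pn("dec", l, "b1")),
                         get_mat(params, pn("dec", l, "W2")),
                         get_vec(params, pn("dec", l, "b2")), d_ff[l]);
    Y += dmul(ff, pn("dec", l, "d3"));
  }
  M Hd = ln_f(Y, get_vec(params, "lnDg"), get_vec(params, "lnDb"),
                      lnD);
  const M Wout = get_mat(params, "Wout");
  M logits = Hd * Wout;
  logits.each_row() += get_vec(params, "bout");

  // ---- loss ----
  const int nrow = logits.n_rows;
  CV mx = arma::max(logits, 1);
  M sm = arma::exp(logits.each_col() - mx);
  sm.each_col() /= arma::sum(sm, 1);
  double nmask = 0, loss = 0, acc = 0;
  for (int r = 0; r < nrow; ++r) {
    if (!tgt_mask[r]) continue;
    nmask += 1;
    const int t = tgt_out[r] - 1;
    double pt = std::max((double)sm(r, t), 1e-12);
    double nll = -std::log(pt);
    if (ls_smooth > 0) {
      double uni = 0;
      for (int v = 0; v < V; ++v) uni -= std::log(std::max((double)sm(r, v), 1e-12));
      uni /= V;
      loss += (1 - ls_smooth) * nll + ls_smooth * uni;
    } else {
      loss += nll;
    }
    acc += (sm.row(r).index_max() == (arma::uword)t) ? 1 : 0;
  }
  loss /= nmask;
  acc /= nmask;
  if (!want_grads) {
    return List::create(_["loss"] = loss, _["acc"] = acc,
                        _["n_tokens"] = nmask);
  }

  // ---- backward ----
  List g;
  M dlogits = sm;
  for (int r = 0; r < nrow; ++r) {
    if (!tgt_mask[r]) { dlogits.row(r).zeros(); continue; }
    dlogits(r, tgt_out[r] - 1) -= (float)(1 - ls_smooth);
    if (ls_smooth > 0) dlogits.row(r) -= (float)(ls_smooth / V);
  }
  dlogits /= (float)nmask;
  M gWout = Hd.t() * dlogits;
  RV gbout = arma::sum(dlogits, 0);
  M dY = dlogits * Wout.t();
  RV dg, db;
  dY = ln_b(dY, lnD, get_vec(params, "lnDg"), dg, db);
  g["lnDg"] = vwrap(dg);
  g["lnDb"] = vwrap(db);
  g["Wout"] = dwrap(gWout);
  g["bout"] = vwrap(gbout);
  M dmem(mem.n_rows, d, arma::fill::zeros);

  for (int l = nl - 1; l >= 0; --l) {
    M dW1, dW2, dWq, dWk, dWv, dWo, dXq, dXkv;
    RV db1, db2;
    M dff = ffn_b(dback(dY, pn("dec", l, "d3")), d_ff[l], d_ff_in[l],
                          get_mat(params, pn("dec", l, "W1")),
                          get_mat(params, pn("dec", l, "W2")),
                          dW1, db1, dW2, db2);
    g[pn("dec", l, "W1")] = dwrap(dW1);
    g[pn("dec", l, "b1")] = vwrap(db1);
    g[pn("dec", l, "W2")] = dwrap(dW2);
    g[pn("dec", l, "b2")] = vwrap(db2);
    M dx = ln_b(dff, d_ln3[l], get_vec(params, pn("dec", l, "ln3g")),
                        dg, db);
    g[pn("dec", l, "ln3g")] = vwrap(dg);
    g[pn("dec", l, "ln3b")] = vwrap(db);
    dY += dx;
    mha_b(dback(dY, pn("dec", l, "d2")), d_ca[l], d_ca_in[l], mem,
          get_mat(params, pn("dec", l, "cWq")),
          get_mat(params, pn("dec", l, "cWk")),
          get_mat(params, pn("dec", l, "cWv")),
          get_mat(params, pn("dec", l, "cWo")),
          h, B, Lt, Ls, dXq, dXkv, dWq, dWk, dWv, dWo);
    g[pn("dec", l, "cWq")] = dwrap(dWq);
    g[pn("dec", l, "cWk")] = dwrap(dWk);
    g[pn("dec", l, "cWv")] = dwrap(dWv);
    g[pn("dec", l, "cWo")] = dwrap(dWo);
    dmem += dXkv;
    dx = ln_b(dXq, d_ln2[l], get_vec(params, pn("dec", l, "ln2g")), dg, db);
    g[pn("dec", l, "ln2g")] = vwrap(dg);
    g[pn("dec", l, "ln2b")] = vwrap(db);
    dY += dx;
    mha_b(dback(dY, pn("dec", l, "d1")), d_at[l], d_at_in[l], d_at_in[l],
          get_mat(params, pn("dec", l, "Wq")),
          get_mat(params, pn("dec", l, "Wk")),
          get_mat(params, pn("dec", l, "Wv")),
          get_mat(params, pn("dec", l, "Wo")),
          h, B, Lt, Lt, dXq, dXkv, dWq, dWk, dWv, dWo);
    g[pn("dec", l, "Wq")] = dwrap(dWq);
    g[pn("dec", l, "Wk")] = dwrap(dWk);
    g[pn("dec", l, "Wv")] = dwrap(dWv);
    g[pn("dec", l, "Wo")] = dwrap(dWo);
    dx = ln_b(dXq + dXkv, d_ln1[l], get_vec(params, pn("dec", l, "ln1g")),
              dg, db);
    g[pn("dec", l, "ln1g")] = vwrap(dg);
    g[pn("dec", l, "ln1b")] = vwrap(db);
    dY += dx;
  }
  M dEdec = dback(dY, "Edec") * esc;

  M dX = ln_b(dmem, lnE, get_vec(params, "lnEg"), dg, db);
  g["lnEg"] = vwrap(dg);
  g["lnEb"] = vwrap(db);
  for (int l = nl - 1; l >= 0; --l) {
    M dW1, dW2, dWq, dWk, dWv, dWo, dXq, dXkv;
    RV db1, db2;
    M dff = ffn_b(dback(dX, pn("enc", l, "d2")), e_ff[l], e_ff_in[l],
                          get_mat(params, pn("enc", l, "W1")),
                          get_mat(params, pn("enc", l, "W2")),
                          dW1, db1, dW2, db2);
    g[pn("enc", l, "W1")] = dwrap(dW1);
    g[pn("enc", l, "b1")] = vwrap(db1);
    g[pn("enc", l, "W2")] = dwrap(dW2);
    g[pn("enc", l, "b2")] = vwrap(db2);
    M dx = ln_b(dff, e_ln3[l], get_vec(params, pn("enc", l, "ln3g")),
                        dg, db);
    g[pn("enc", l, "ln3g")] = vwrap(dg);
    g[pn("enc", l, "ln3b")] = vwrap(db);
    dX += dx;
    mha_b(dback(dX, pn("enc", l, "d1")), e_at[l], e_at_in[l], e_at_in[l],
          get_mat(params, pn("enc", l, "Wq")),
          get_mat(params, pn("enc", l, "Wk")),
          get_mat(params, pn("enc", l, "Wv")),
          get_mat(params, pn("enc", l, "Wo")),
          h, B, Ls, Ls, dXq, dXkv, dWq, dWk, dWv, dWo);
    g[pn("enc", l, "Wq")] = dwrap(dWq);
    g[pn("enc", l, "Wk")] = dwrap(dWk);
    g[pn("enc", l, "Wv")] = dwrap(dWv);
    g[pn("enc", l, "Wo")] = dwrap(dWo);
    dx = ln_b(dXq + dXkv, e_ln1[l], get_vec(params, pn("enc", l, "ln1g")),
              dg, db);
    g[pn("enc", l, "ln1g")] = vwrap(dg);
    g[pn("enc", l, "ln1b")] = vwrap(db);
    dX += dx;
  }
  M dEenc = dback(dX, "Eenc") * esc;

  M dE(V, d, arma::fill::zeros);
  for (int r = 0; r < B * Ls; ++r) dE.row(src[r] - 1) += dEenc.row(r);
  for (int r = 0; r < B * Lt; ++r) dE.row(tgt_in[r] - 1) += dEdec.row(r);
  dE.row(0).zeros();  // padding embedding never trains
  g["E"] = dwrap(dE);

  return List::create(_["loss"] = loss, _["acc"] = acc,
                      _["n_tokens"] = nmask, _["grads"] = g);
}

// In-place Adam update over the parameter list. The caller guarantees the
// params/m/v objects are privately owned (deep-copied at training start and
// when snapshotting the best parameters), so aliasing-free in-place updates
// are safe and avoid re-allocating ~1M doubles per step.
// [[Rcpp::export]]
void adam_step_cpp(List params, List grads, List m, List v, int t,
                   double lr, double b1, double b2, double eps) {
  const double bc1 = 1.0 - std::pow(b1, t);
  const double bc2 = 1.0 - std::pow(b2, t);
  const double step_size = lr / bc1;
  const double inv_sqrt_bc2 = 1.0 / std::sqrt(bc2);
  CharacterVector nms = params.names();
  for (int i = 0; i < nms.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    if (!grads.containsElementNamed(nm.c_str())) continue;
    NumericVector p = params[nm];
    NumericVector g = grads[nm];
    NumericVector mm = m[nm];
    NumericVector vv = v[nm];
    const int n = p.size();
    for (int k = 0; k < n; ++k) {
      double gg = g[k];
      mm[k] = b1 * mm[k] + (1 - b1) * gg;
      vv[k] = b2 * vv[k] + (1 - b2) * gg * gg;
      p[k] -= step_size * mm[k] / (std::sqrt(vv[k]) * inv_sqrt_bc2 + eps);
    }
  }
}
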