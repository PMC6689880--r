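// Training/inference engine for the two-stage voter network:
// char Bi-LSTM + additive attention, word embeddings, component-wise
// attention over stage-one one-hot features, word Bi-LSTM, linear
// projection, linear-chain CRF. Forward pass and analytic backpropagation
// are hand-derived; gradients are verified against finite differences in
// the test suite. All randomness (dropout) draws from R's RNG so training
// is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cell {
  mat Wxi, Wxf, Wxc, Wxo, Whi, Whf, Whc, Who;
  vec wci, wcf, wco, bi, bf, bc, bo;
};

struct CellGrad {
  mat Wxi, Wxf, Wxc, Wxo, Whi, Whf, Whc, Who;
  vec wci, wcf, wco, bi, bf, bc, bo;
  void init(const Cell& c) {
    Wxi.zeros(size(c.Wxi)); Wxf.zeros(size(c.Wxf));
    Wxc.zeros(size(c.Wxc)); Wxo.zeros(size(c.Wxo));
    Whi.zeros(size(c.Whi)); Whf.zeros(size(c.Whf));
    Whc.zeros(size(c.Whc)); Who.zeros(size(c.Who));
    wci.zeros(c.wci.n_elem); wcf.zeros(c.wcf.n_elem); wco.zeros(c.wco.n_elem);
    bi.zeros(c.bi.n_elem); bf.zeros(c.bf.n_elem);
    bc.zeros(c.bc.n_elem); bo.zeros(c.bo.n_elem);
  }
};

static Cell load_cell(const List& p, const std::string& pre, bool peephole) {
  Cell c;
  c.Wxi = as<mat>(p[pre + "Wxi"]); c.Wxf = as<mat>(p[pre + "Wxf"]);
  c.Wxc = as<mat>(p[pre + "Wxc"]); c.Wxo = as<mat>(p[pre + "Wxo"]);
  c.Whi = as<mat>(p[pre + "Whi"]); c.Whf = as<mat>(p[pre + "Whf"]);
  c.Whc = as<mat>(p[pre + "Whc"]); c.Who = as<mat>(p[pre + "Who"]);
  c.wci = as<vec>(p[pre + "wci"]); c.wcf = as<vec>(p[pre + "wcf"]);
  c.wco = as<vec>(p[pre + "wco"]);
  if (!peephole) { c.wci.zeros(); c.wcf.zeros(); c.wco.zeros(); }
  c.bi = as<vec>(p[pre + "bi"]); c.bf = as<vec>(p[pre + "bf"]);
  c.bc = as<vec>(p[pre + "bc"]); c.bo = as<vec>(p[pre + "bo"]);
  return c;
}

static void store_cell_grad(List& g, const std::string& pre, const CellGrad& cg) {
  g[pre + "Wxi"] = cg.Wxi; g[pre + "Wxf"] = cg.Wxf;
  g[pre + "Wxc"] = cg.Wxc; g[pre + "Wxo"] = cg.Wxo;
  g[pre + "Whi"] = cg.Whi; g[pre + "Whf"] = cg.Whf;
  g[pre + "Whc"] = cg.Whc; g[pre + "Who"] = cg.Who;
  g[pre + "wci"] = cg.wci; g[pre + "wcf"] = cg.wcf; g[pre + "wco"] = cg.wco;
  g[pre + "bi"] = cg.bi; g[pre + "bf"] = cg.bf;
  g[pre + "bc"] = cg.bc; g[pre + "bo"] = cg.bo;
}

struct LCache { mat X, I, F, G, O, C, Tc, H; };

static void lstm_fwd(const Cell& p, const mat& X, LCache& c) {
  const uword T = X.n_cols, dh = p.bi.n_elem;
  c.X = X;
  c.I.set_size(dh, T); c.F.set_size(dh, T); c.G.set_size(dh, T);
  c.O.set_size(dh, T); c.C.set_size(dh, T); c.Tc.set_size(dh, T);
  c.H.set_size(dh, T);
  vec h(dh, fill::zeros), cc(dh, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const vec x = X.col(t);
    const vec i = sigm(p.Wxi * x + p.Whi * h + p.wci % cc + p.bi);
    const vec f = sigm(p.Wxf * x + p.Whf * h + p.wcf % cc + p.bf);
    const vec g = tanh(p.Wxc * x + p.Whc * h + p.bc);
    const vec cn = f % cc + i % g;
    const vec o = sigm(p.Wxo * x + p.Who * h + p.wco % cn + p.bo);
    const vec tc = tanh(cn);
    h = o % tc;
    c.I.col(t) = i; c.F.col(t) = f; c.G.col(t) = g; c.O.col(t) = o;
    c.C.col(t) = cn; c.Tc.col(t) = tc; c.H.col(t) = h;
    cc = cn;
  }
}

// dH: gradient w.r.t. every hidden state (dh x T); returns dX, accumulates
// parameter gradients into g.
static mat lstm_bwd(const Cell& p, const LCache& c, const mat& dH,
                    CellGrad& g) {
  const uword T = c.X.n_cols, dh = p.bi.n_elem, din = c.X.n_rows;
  mat dX(din, T, fill::zeros);
  vec dh_next(dh, fill::zeros), dc_next(dh, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const vec dh_t = dH.col(tt) + dh_next;
    const vec i = c.I.col(tt), f = c.F.col(tt), gg = c.G.col(tt),
              o = c.O.col(tt), ct = c.C.col(tt), tc = c.Tc.col(tt);
    const vec cprev = (tt == 0) ? vec(dh, fill::zeros) : vec(c.C.col(tt - 1));
    const vec hprev = (tt == 0) ? vec(dh, fill::zeros) : vec(c.H.col(tt - 1));
    const vec do_ = dh_t % tc;
    const vec dao = do_ % o % (1.0 - o);
    const vec dc = dh_t % o % (1.0 - tc % tc) + dc_next + p.wco % dao;
    const vec di = dc % gg, df = dc % cprev, dg = dc % i;
    const vec dai = di % i % (1.0 - i);
    const vec daf = df % f % (1.0 - f);
    const vec dag = dg % (1.0 - gg % gg);
    dc_next = dc % f + p.wci % dai + p.wcf % daf;
    const vec x = c.X.col(tt);
    g.Wxi += dai * x.t(); g.Whi += dai * hprev.t();
    g.wci += dai % cprev; g.bi += dai;
    g.Wxf += daf * x.t(); g.Whf += daf * hprev.t();
    g.wcf += daf % cprev; g.bf += daf;
    g.Wxc += dag * x.t(); g.Whc += dag * hprev.t(); g.bc += dag;
    g.Wxo += dao * x.t(); g.Who += dao * hprev.t();
    g.wco += dao % ct; g.bo += dao;
    dX.col(tt) = p.Wxi.t() * dai + p.Wxf.t() * daf + p.Wxc.t() * dag +
                 p.Wxo.t() * dao;
    dh_next = p.Whi.t() * dai + p.Whf.t() * daf + p.Whc.t() * dag +
              p.Who.t() * dao;
  }
  return dX;
}

struct BiCache { LCache f, b; mat H; };

static void bilstm_fwd(const Cell& fc, const Cell& bc, const mat& X,
                       BiCache& c) {
  lstm_fwd(fc, X, c.f);
  lstm_fwd(bc, fliplr(X), c.b);
  c.H = join_cols(c.f.H, fliplr(c.b.H));
}

static mat bilstm_bwd(const Cell& fc, const Cell& bc, const BiCache& c,
                      const mat& dH, CellGrad& gf, CellGrad& gb) {
  const uword dh = fc.bi.n_elem;
  const mat dHf = dH.rows(0, dh - 1);
  const mat dHb = fliplr(dH.rows(dh, 2 * dh - 1));
  const mat dXf = lstm_bwd(fc, c.f, dHf, gf);
  const mat dXb = lstm_bwd(bc, c.b, dHb, gb);
  return dXf + fliplr(dXb);
}

static inline double logsumexp_v(const vec& v) {
  const double m = v.max();
  return m + std::log(accu(exp(v - m)));
}

static vec softmax_v(const vec& e) {
  vec w = exp(e - e.max());
  return w / accu(w);
}

// Negative log-likelihood of the gold path plus gradients w.r.t. emissions
// (L x n) and the transition matrix ((L+2) x (L+2); START = L, STOP = L+1
// in 0-based indexing).
static double crf_nll_grad(const mat& E, const mat& trans, const uvec& y,
                           mat& dE, mat& dtrans, bool want_grad) {
  const uword L = E.n_rows, n = E.n_cols, S = L, P = L + 1;
  mat A(L, n), B(L, n);
  A.col(0) = trans(S, span(0, L - 1)).t() + E.col(0);
  for (uword t = 1; t < n; ++t)
    for (uword j = 0; j < L; ++j)
      A(j, t) = logsumexp_v(A.col(t - 1) + trans(span(0, L - 1), j)) + E(j, t);
  B.col(n - 1) = trans(span(0, L - 1), P);
  for (uword t = n - 1; t-- > 0;)
    for (uword i = 0; i < L; ++i)
      B(i, t) = logsumexp_v(trans(i, span(0, L - 1)).t() + E.col(t + 1) +
                            B.col(t + 1));
  const double logZ = logsumexp_v(A.col(n - 1) + B.col(n - 1));

  double score = trans(S, y(0)) + E(y(0), 0) + trans(y(n - 1), P);
  for (uword t = 1; t < n; ++t) score += trans(y(t - 1), y(t)) + E(y(t), t);

  if (want_grad) {
    dE.zeros(L, n); dtrans.zeros(L + 2, L + 2);
    const mat M = exp(A + B - logZ);  // unary marginals
    dE = M;
    for (uword t = 0; t < n; ++t) dE(y(t), t) -= 1.0;
    for (uword j = 0; j < L; ++j) dtrans(S, j) += M(j, 0);
    dtrans(S, y(0)) -= 1.0;
    for (uword i = 0; i < L; ++i) dtrans(i, P) += M(i, n - 1);
    dtrans(y(n - 1), P) -= 1.0;
    for (uword t = 0; t + 1 < n; ++t) {
      for (uword i = 0; i < L; ++i)
        for (uword j = 0; j < L; ++j)
          dtrans(i, j) += std::exp(A(i, t) + trans(i, j) + E(j, t + 1) +
                                   B(j, t + 1) - logZ);
      dtrans(y(t), y(t + 1)) -= 1.0;
    }
  }
  return logZ - score;
}

struct Net {
  mat char_embed, word_embed;
  Cell cf, cb, wf, wb;
  mat ac_W; vec ac_b, ac_v;
  bool has_s1 = false;
  mat as_W1; vec as_b1; mat as_W2; vec as_b2;
  mat proj_W; vec proj_b;
  mat crf_trans;
};

static Net load_net(const List& p, bool peephole) {
  Net n;
  n.char_embed = as<mat>(p["char_embed"]);
  n.word_embed = as<mat>(p["word_embed"]);
  n.cf = load_cell(p, "cf_", peephole); n.cb = load_cell(p, "cb_", peephole);
  n.wf = load_cell(p, "wf_", peephole); n.wb = load_cell(p, "wb_", peephole);
  n.ac_W = as<mat>(p["ac_W"]); n.ac_b = as<vec>(p["ac_b"]);
  n.ac_v = as<vec>(p["ac_v"]);
  if (p.containsElementNamed("as_W1")) {
    n.has_s1 = true;
    n.as_W1 = as<mat>(p["as_W1"]); n.as_b1 = as<vec>(p["as_b1"]);
    n.as_W2 = as<mat>(p["as_W2"]); n.as_b2 = as<vec>(p["as_b2"]);
  }
  n.proj_W = as<mat>(p["proj_W"]); n.proj_b = as<vec>(p["proj_b"]);
  n.crf_trans = as<mat>(p["crf_trans"]);
  return n;
}

// per-token caches of one sentence's forward pass
struct SentCache {
  std::vector<BiCache> cbi;     // char Bi-LSTM per token
  std::vector<mat> U;           // char attention tanh layer (da x m)
  std::vector<vec> alpha;       // char attention weights
  std::vector<vec> u, q, beta;  // stage-one vector, tanh layer, weights
  mat reps;                     // D x n (pre-dropout)
  mat mask;                     // dropout mask
  BiCache wbi;                  // word Bi-LSTM
  mat E;                        // L x n emissions
};

static void forward_sentence(const Net& net, const IntegerVector& wid,
                             const List& chars, SEXP s1sexp, double dropout,
                             bool train, SentCache& sc) {
  const uword n = wid.size();
  const uword dwe = net.word_embed.n_rows;
  const uword dch2 = 2 * net.cf.bi.n_elem;
  const uword D1 = net.has_s1 ? net.as_b2.n_elem : 0;
  mat s1;
  if (net.has_s1) s1 = trans(as<mat>(s1sexp));  // D1 x n
  const uword D = dwe + dch2 + D1;
  sc.cbi.resize(n); sc.U.resize(n); sc.alpha.resize(n);
  sc.u.resize(n); sc.q.resize(n); sc.beta.resize(n);
  sc.reps.set_size(D, n);
  for (uword t = 0; t < n; ++t) {
    const IntegerVector ch = chars[t];
    uvec cid(ch.size());
    for (int j = 0; j < ch.size(); ++j) cid(j) = ch[j] - 1;
    const mat Xc = net.char_embed.cols(cid);
    bilstm_fwd(net.cf, net.cb, Xc, sc.cbi[t]);
    mat U = net.ac_W * sc.cbi[t].H;
    U.each_col() += net.ac_b;
    U = tanh(U);
    const vec e = U.t() * net.ac_v;
    const vec alpha = softmax_v(e);
    const vec ctx = sc.cbi[t].H * alpha;
    sc.U[t] = U; sc.alpha[t] = alpha;
    vec rep(D);
    rep.subvec(0, dwe - 1) = net.word_embed.col(wid[t] - 1);
    rep.subvec(dwe, dwe + dch2 - 1) = ctx;
    if (net.has_s1) {
      const vec u = s1.col(t);
      const vec q = tanh(net.as_W1 * u + net.as_b1);
      const vec beta = softmax_v(net.as_W2 * q + net.as_b2);
      rep.subvec(dwe + dch2, D - 1) = beta % u;
      sc.u[t] = u; sc.q[t] = q; sc.beta[t] = beta;
    }
    sc.reps.col(t) = rep;
  }
  mat dropped = sc.reps;
  if (train && dropout > 0) {
    sc.mask.set_size(D, n);
    const double keep = 1.0 - dropout;
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i < D; ++i)
        sc.mask(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    dropped %= sc.mask;
  } else {
    sc.mask.ones(D, n);
  }
  bilstm_fwd(net.wf, net.wb, dropped, sc.wbi);
  sc.E = net.proj_W * sc.wbi.H;
  sc.E.each_col() += net.proj_b;
}

struct NetGrad {
  mat char_embed, word_embed;
  CellGrad cf, cb, wf, wb;
  mat ac_W; vec ac_b, ac_v;
  mat as_W1; vec as_b1; mat as_W2; vec as_b2;
  mat proj_W; vec proj_b;
  mat crf_trans;
  void init(const Net& n) {
    char_embed.zeros(size(n.char_embed));
    word_embed.zeros(size(n.word_embed));
    cf.init(n.cf); cb.init(n.cb); wf.init(n.wf); wb.init(n.wb);
    ac_W.zeros(size(n.ac_W)); ac_b.zeros(n.ac_b.n_elem);
    ac_v.zeros(n.ac_v.n_elem);
    if (n.has_s1) {
      as_W1.zeros(size(n.as_W1)); as_b1.zeros(n.as_b1.n_elem);
      as_W2.zeros(size(n.as_W2)); as_b2.zeros(n.as_b2.n_elem);
    }
    proj_W.zeros(size(n.proj_W)); proj_b.zeros(n.proj_b.n_elem);
    crf_trans.zeros(size(n.crf_trans));
  }
};

static void backward_sentence(const Net& net, const IntegerVector& wid,
                              const List& chars, const SentCache& sc,
                              const mat& dE, const mat& dtrans, NetGrad& g) {
  const uword n = wid.size();
  const uword dwe = net.word_embed.n_rows;
  const uword dch2 = 2 * net.cf.bi.n_elem;
  const uword D = sc.reps.n_rows;
  g.crf_trans += dtrans;
  g.proj_W += dE * sc.wbi.H.t();
  g.proj_b += sum(dE, 1);
  const mat dHw = net.proj_W.t() * dE;
  mat dDropped = bilstm_bwd(net.wf, net.wb, sc.wbi, dHw, g.wf, g.wb);
  mat dReps = dDropped % sc.mask;
  for (uword t = 0; t < n; ++t) {
    const vec dr = dReps.col(t);
    g.word_embed.col(wid[t] - 1) += dr.subvec(0, dwe - 1);
    const vec dctx = dr.subvec(dwe, dwe + dch2 - 1);
    // char attention backward
    const vec& alpha = sc.alpha[t];
    const mat& S = sc.cbi[t].H;
    mat dS = dctx * alpha.t();
    const vec dalpha = S.t() * dctx;
    const vec de = alpha % (dalpha - dot(alpha, dalpha));
    g.ac_v += sc.U[t] * de;
    const mat dA = (net.ac_v * de.t()) % (1.0 - sc.U[t] % sc.U[t]);
    g.ac_W += dA * S.t();
    g.ac_b += sum(dA, 1);
    dS += net.ac_W.t() * dA;
    const mat dXc = bilstm_bwd(net.cf, net.cb, sc.cbi[t], dS, g.cf, g.cb);
    const IntegerVector ch = chars[t];
    for (int j = 0; j < ch.size(); ++j)
      g.char_embed.col(ch[j] - 1) += dXc.col(j);
    if (net.has_s1) {
      const vec ds1 = dr.subvec(dwe + dch2, D - 1);
      const vec& beta = sc.beta[t];
      const vec& u = sc.u[t];
      const vec dbeta = ds1 % u;
      const vec de2 = beta % (dbeta - dot(beta, dbeta));
      g.as_W2 += de2 * sc.q[t].t();
      g.as_b2 += de2;
      const vec dq = net.as_W2.t() * de2;
      const vec da = dq % (1.0 - sc.q[t] % sc.q[t]);
      g.as_W1 += da * u.t();
      g.as_b1 += da;
    }
  }
}

// [[Rcpp::export]]
List cpp_loss_grad(List sents, List params, double dropout, bool peephole) {
  const Net net = load_net(params, peephole);
  NetGrad g; g.init(net);
  double total = 0.0;
  const int B = sents.size();
  for (int s = 0; s < B; ++s) {
    List sent = sents[s];
    IntegerVector wid = sent["word"];
    List chars = sent["chars"];
    IntegerVector yv = sent["y"];
    SEXP s1 = sent.containsElementNamed("s1") ? (SEXP)sent["s1"] : R_NilValue;
    SentCache sc;
    forward_sentence(net, wid, chars, s1, dropout, true, sc);
    uvec y(yv.size());
    for (int t = 0; t < yv.size(); ++t) y(t) = yv[t] - 1;
    mat dE, dtrans;
    const double nll = crf_nll_grad(sc.E, net.crf_trans, y, dE, dtrans, true);
    if (!std::isfinite(nll))
      stop("non-finite loss in sentence %d of batch", s + 1);
    total += nll;
    backward_sentence(net, wid, chars, sc, dE, dtrans, g);
  }
  const double inv = 1.0 / std::max(1, B);
  List out = List::create(Named("loss") = total * inv);
  List gr;
  gr["char_embed"] = mat(g.char_embed * inv);
  gr["word_embed"] = mat(g.word_embed * inv);
  auto scale_cell = [&](CellGrad& cg) {
    cg.Wxi *= inv; cg.Wxf *= inv; cg.Wxc *= inv; cg.Wxo *= inv;
    cg.Whi *= inv; cg.Whf *= inv; cg.Whc *= inv; cg.Who *= inv;
    cg.wci *= inv; cg.wcf *= inv; cg.wco *= inv;
    if (!peephole) { cg.wci.zeros(); cg.wcf.zeros(); cg.wco.zeros(); }
    cg.bi *= inv; cg.bf *= inv; cg.bc *= inv; cg.bo *= inv;
  };
  scale_cell(g.cf); scale_cell(g.cb); scale_cell(g.wf); scale_cell(g.wb);
  store_cell_grad(gr, "cf_", g.cf); store_cell_grad(gr, "cb_", g.cb);
  store_cell_grad(gr, "wf_", g.wf); store_cell_grad(gr, "wb_", g.wb);
  gr["ac_W"] = mat(g.ac_W * inv); gr["ac_b"] = vec(g.ac_b * inv);
  gr["ac_v"] = vec(g.ac_v * inv);
  if (net.has_s1) {
    gr["as_W1"] = mat(g.as_W1 * inv); gr["as_b1"] = vec(g.as_b1 * inv);
    gr["as_W2"] = mat(g.as_W2 * inv); gr["as_b2"] = vec(g.as_b2 * inv);
  }
  gr["proj_W"] = mat(g.proj_W * inv); gr["proj_b"] = vec(g.proj_b * inv);
  gr["crf_trans"] = mat(g.crf_trans * inv);
  out["grads"] = gr;
  return out;
}

// [[Rcpp::export]]
List cpp_forward(List sents, List params, bool peephole,
                 bool return_attention) {
  const Net net = load_net(params, peephole);
  const int B = sents.size();
  List out(B);
  for (int s = 0; s < B; ++s) {
    List sent = sents[s];
    IntegerVector wid = sent["word"];
    List chars = sent["chars"];
    SEXP s1 = sent.containsElementNamed("s1") ? (SEXP)sent["s1"] : R_NilValue;
    SentCache sc;
    forward_sentence(net, wid, chars, s1, 0.0, false, sc);
    List res = List::create(Named("emissions") = mat(sc.E.t()));
    if (return_attention) {
      const uword n = wid.size();
      List ca(n);
      for (uword t = 0; t < n; ++t) ca[t] = vec(sc.alpha[t]);
      res["char_attention"] = ca;
      if (net.has_s1) {
        mat sa(n, net.as_b2.n_elem);
        for (uword t = 0; t < n; ++t) sa.row(t) = sc.beta[t].t();
        res["stage_one_attention"] = sa;
      }
    }
    out[s] = res;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sentence_nll(List sents, List params, bool peephole) {
  const Net net = load_net(params, peephole);
  const int B = sents.size();
  NumericVector out(B);
  for (int s = 0; s < B; ++s) {
    List sent = sents[s];
    IntegerVector wid = sent["word"];
    List chars = sent["chars"];
    IntegerVector yv = sent["y"];
    SEXP s1 = sent.containsElementNamed("s1") ? (SEXP)sent["s1"] : R_NilValue;
    SentCache sc;
    forward_sentence(net, wid, chars, s1, 0.0, false, sc);
    uvec y(yv.size());
    for (int t = 0; t < yv.size(); ++t) y(t) = yv[t] - 1;
    mat dE, dtrans;
    out[s] = crf_nll_grad(sc.E, net.crf_trans, y, dE, dtrans, false);
  }
  return out;
}
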