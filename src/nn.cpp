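// Minimal neural sequence models for cleavage-score regression and
// autoregressive peptide generation. The models are small (tens to a few
// hundred thousand parameters), so forward and backward passes are written
// directly against Armadillo; parameters travel as one flat numeric vector
// whose layout is fixed by the config (see ParamPack). All position-wise
// linear algebra is batched across the minibatch (sequences stacked
// row-wise); only the attention score blocks run per sequence. Gradients are
// checked against finite differences in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct TfCfg {
  int V;     // vocabulary size (tokens)
  int D;     // model dimension
  int H;     // attention heads
  int dh;    // head width
  int L;     // layers
  int F;     // feed-forward width
  int M;     // head outputs (encoder: proteases; decoder: V)
  int Mtag;  // conditioning-tag length (decoder only, else 0)
  bool causal;
  double dropout;  // rate on the two sublayer outputs during training
};

static TfCfg tf_cfg(const List& cfg) {
  TfCfg c;
  c.V = as<int>(cfg["V"]);
  c.D = as<int>(cfg["D"]);
  c.H = as<int>(cfg["H"]);
  c.dh = as<int>(cfg["dh"]);
  c.L = as<int>(cfg["L"]);
  c.F = as<int>(cfg["F"]);
  c.M = as<int>(cfg["M"]);
  c.Mtag = cfg.containsElementNamed("Mtag") ? as<int>(cfg["Mtag"]) : 0;
  c.causal = as<bool>(cfg["causal"]);
  c.dropout = cfg.containsElementNamed("dropout") ? as<double>(cfg["dropout"]) : 0.0;
  return c;
}

// Fixed order of parameter matrices; shared by counting, init and views.
static void tf_shapes(const TfCfg& c, std::vector<std::pair<int,int> >& sh) {
  int Hi = c.H * c.dh;
  sh.clear();
  sh.push_back(std::make_pair(c.V, c.D));            // 0: embedding
  for (int l = 0; l < c.L; ++l) {
    sh.push_back(std::make_pair(c.D, Hi));           // Wq
    sh.push_back(std::make_pair(1, Hi));             // bq
    sh.push_back(std::make_pair(c.D, Hi));           // Wk
    sh.push_back(std::make_pair(1, Hi));             // bk
    sh.push_back(std::make_pair(c.D, Hi));           // Wv
    sh.push_back(std::make_pair(1, Hi));             // bv
    sh.push_back(std::make_pair(Hi, c.D));           // Wo
    sh.push_back(std::make_pair(1, c.D));            // bo
    sh.push_back(std::make_pair(1, c.D));            // ln1 gain
    sh.push_back(std::make_pair(1, c.D));            // ln1 bias
    sh.push_back(std::make_pair(c.D, c.F));          // W1
    sh.push_back(std::make_pair(1, c.F));            // b1
    sh.push_back(std::make_pair(c.F, c.D));          // W2
    sh.push_back(std::make_pair(1, c.D));            // b2
    sh.push_back(std::make_pair(1, c.D));            // ln2 gain
    sh.push_back(std::make_pair(1, c.D));            // ln2 bias
  }
  sh.push_back(std::make_pair(c.D, c.M));            // head weight
  sh.push_back(std::make_pair(1, c.M));              // head bias
  if (c.Mtag > 0) {
    sh.push_back(std::make_pair(c.Mtag, c.D));       // tag projection
    sh.push_back(std::make_pair(1, c.D));            // tag bias
  }
}

struct ParamPack {
  // heap-allocated aliasing views into the flat vector (vector reallocation
  // must never copy them, or they would silently stop aliasing)
  std::vector<arma::mat*> m;
  int per_layer;
  ParamPack(double* ptr, const TfCfg& c) : per_layer(16) {
    std::vector<std::pair<int,int> > sh;
    tf_shapes(c, sh);
    size_t off = 0;
    for (size_t i = 0; i < sh.size(); ++i) {
      m.push_back(new arma::mat(ptr + off, sh[i].first, sh[i].second, false, true));
      off += (size_t)sh[i].first * sh[i].second;
    }
  }
  ~ParamPack() { for (size_t i = 0; i < m.size(); ++i) delete m[i]; }
  arma::mat& emb() { return *m[0]; }
  arma::mat& lay(int l, int k) { return *m[1 + l * per_layer + k]; }
  arma::mat& head_w(const TfCfg& c) { return *m[1 + c.L * per_layer]; }
  arma::mat& head_b(const TfCfg& c) { return *m[2 + c.L * per_layer]; }
  arma::mat& tag_w(const TfCfg& c) { return *m[3 + c.L * per_layer]; }
  arma::mat& tag_b(const TfCfg& c) { return *m[4 + c.L * per_layer]; }
};

static size_t tf_count(const TfCfg& c) {
  std::vector<std::pair<int,int> > sh;
  tf_shapes(c, sh);
  size_t n = 0;
  for (size_t i = 0; i < sh.size(); ++i)
    n += (size_t)sh[i].first * sh[i].second;
  return n;
}

// [[Rcpp::export]]
int cpp_tf_nparams(List cfg) { return (int)tf_count(tf_cfg(cfg)); }

// Xavier-uniform weights, zero biases/LN-biases, unit LN gains; uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_tf_init(List cfg) {
  TfCfg c = tf_cfg(cfg);
  std::vector<std::pair<int,int> > sh;
  tf_shapes(c, sh);
  size_t n = tf_count(c);
  NumericVector out(n);
  RNGScope scope;
  size_t off = 0;
  for (size_t i = 0; i < sh.size(); ++i) {
    int r = sh[i].first, cc = sh[i].second;
    size_t len = (size_t)r * cc;
    bool is_bias = (r == 1);
    int k = (i >= 1 && i < (size_t)(1 + c.L * 16)) ? (int)((i - 1) % 16) : -1;
    bool ln_gain = (k == 8 || k == 14);
    bool ln_bias = (k == 9 || k == 15);
    if (ln_gain) {
      for (size_t j = 0; j < len; ++j) out[off + j] = 1.0;
    } else if (is_bias || ln_bias) {
      for (size_t j = 0; j < len; ++j) out[off + j] = 0.0;
    } else {
      double lim = std::sqrt(6.0 / (double)(r + cc));
      for (size_t j = 0; j < len; ++j) out[off + j] = R::runif(-lim, lim);
    }
    off += len;
  }
  return out;
}

static arma::mat sinusoidal_pe(int T, int D) {
  arma::mat pe(T, D, arma::fill::zeros);
  for (int pos = 0; pos < T; ++pos)
    for (int i = 0; i < D; ++i) {
      double angle = pos / std::pow(10000.0, (double)(2 * (i / 2)) / D);
      pe(pos, i) = (i % 2 == 0) ? std::sin(angle) : std::cos(angle);
    }
  return pe;
}

// Row-wise layer norm over a stacked batch matrix.
static void layernorm_fwd(const arma::mat& x, const arma::mat& g,
                          const arma::mat& b, arma::mat& y,
                          arma::vec& istd, arma::mat& xhat) {
  int D = x.n_cols;
  arma::vec mu = arma::mean(x, 1);
  arma::mat cent = x.each_col() - mu;
  arma::vec var = arma::sum(arma::square(cent), 1) / D;
  istd = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = cent.each_col() % istd;
  y = xhat.each_row() % g.row(0);
  y.each_row() += b.row(0);
}

static void layernorm_bwd(const arma::mat& dy, const arma::mat& g,
                          const arma::mat& xhat, const arma::vec& istd,
                          arma::mat& dx, arma::mat& dg, arma::mat& db) {
  int D = dy.n_cols;
  arma::mat dxh = dy.each_row() % g.row(0);
  arma::vec s1 = arma::sum(dxh, 1) / D;
  arma::vec s2 = arma::sum(dxh % xhat, 1) / D;
  dx = dxh;
  dx.each_col() -= s1;
  dx -= xhat.each_col() % s2;
  dx.each_col() %= istd;
  dg.row(0) += arma::sum(dy % xhat, 0);
  db.row(0) += arma::sum(dy, 0);
}

// Per-layer cache for one stacked batch.
struct LayerCache {
  arma::mat X;                              // layer input (rows x D)
  arma::mat Q, K, Vv;                       // projections (rows x Hi)
  std::vector<std::vector<arma::mat> > A;   // [seq][head] attention weights
  arma::mat O;                              // head outputs (rows x Hi)
  arma::mat y1, xhat1;                      // LN1
  arma::vec istd1;
  arma::mat pre, Hff;                       // FFN
  arma::mat y2, xhat2;                      // LN2
  arma::vec istd2;
  arma::mat drop1, drop2;                   // inverted-dropout masks
};

static arma::mat dropout_mask(int n, int m, double rate) {
  arma::mat mask(n, m);
  double keep = 1.0 - rate;
  for (arma::uword i = 0; i < mask.n_elem; ++i)
    mask(i) = (R::unif_rand() < rate) ? 0.0 : 1.0 / keep;
  return mask;
}

// Forward pass over a stacked batch. `off` holds B+1 row offsets delimiting
// the sequences inside the stacked matrix. With train=true and dropout > 0,
// inverted dropout is applied to both sublayer outputs.
static arma::mat tf_forward_batch(ParamPack& P, const TfCfg& c,
                                  const arma::mat& X0, const arma::ivec& off,
                                  std::vector<LayerCache>* cache,
                                  bool train = false) {
  int B = off.n_elem - 1;
  arma::mat X = X0;
  double scale = 1.0 / std::sqrt((double)c.dh);
  for (int l = 0; l < c.L; ++l) {
    LayerCache lc;
    lc.X = X;
    lc.Q = X * P.lay(l, 0); lc.Q.each_row() += P.lay(l, 1).row(0);
    lc.K = X * P.lay(l, 2); lc.K.each_row() += P.lay(l, 3).row(0);
    lc.Vv = X * P.lay(l, 4); lc.Vv.each_row() += P.lay(l, 5).row(0);
    lc.O.set_size(X.n_rows, c.H * c.dh);
    lc.A.resize(B);
    for (int b = 0; b < B; ++b) {
      int a = off(b), z = off(b + 1) - 1;
      int n = z - a + 1;
      lc.A[b].resize(c.H);
      arma::span rs(a, z);
      for (int h = 0; h < c.H; ++h) {
        arma::span cs(h * c.dh, (h + 1) * c.dh - 1);
        arma::mat S = lc.Q(rs, cs) * lc.K(rs, cs).t() * scale;
        if (c.causal)
          for (int i = 0; i < n; ++i)
            for (int j = i + 1; j < n; ++j) S(i, j) = -arma::datum::inf;
        arma::mat A(n, n);
        for (int i = 0; i < n; ++i) {
          arma::rowvec r = S.row(i);
          double mx = r.max();
          arma::rowvec e = arma::exp(r - mx);
          A.row(i) = e / arma::accu(e);
        }
        lc.A[b][h] = A;
        lc.O(rs, cs) = A * lc.Vv(rs, cs);
      }
    }
    arma::mat Pp = lc.O * P.lay(l, 6); Pp.each_row() += P.lay(l, 7).row(0);
    if (train && c.dropout > 0) {
      lc.drop1 = dropout_mask(Pp.n_rows, Pp.n_cols, c.dropout);
      Pp %= lc.drop1;
    }
    arma::mat r1 = X + Pp;
    layernorm_fwd(r1, P.lay(l, 8), P.lay(l, 9), lc.y1, lc.istd1, lc.xhat1);
    lc.pre = lc.y1 * P.lay(l, 10); lc.pre.each_row() += P.lay(l, 11).row(0);
    lc.Hff = arma::clamp(lc.pre, 0.0, arma::datum::inf);
    arma::mat Fo = lc.Hff * P.lay(l, 12); Fo.each_row() += P.lay(l, 13).row(0);
    if (train && c.dropout > 0) {
      lc.drop2 = dropout_mask(Fo.n_rows, Fo.n_cols, c.dropout);
      Fo %= lc.drop2;
    }
    arma::mat r2 = lc.y1 + Fo;
    layernorm_fwd(r2, P.lay(l, 14), P.lay(l, 15), lc.y2, lc.istd2, lc.xhat2);
    X = lc.y2;
    if (cache) cache->push_back(lc);
  }
  return X;
}

// Backward pass over the stacked batch; returns gradient w.r.t. X0.
static arma::mat tf_backward_batch(ParamPack& P, ParamPack& G, const TfCfg& c,
                                   std::vector<LayerCache>& cache,
                                   const arma::ivec& off, arma::mat dX) {
  int B = off.n_elem - 1;
  double scale = 1.0 / std::sqrt((double)c.dh);
  for (int l = c.L - 1; l >= 0; --l) {
    LayerCache& lc = cache[l];
    arma::mat dr2;
    layernorm_bwd(dX, P.lay(l, 14), lc.xhat2, lc.istd2, dr2,
                  G.lay(l, 14), G.lay(l, 15));
    arma::mat dy1 = dr2;                       // residual branch
    arma::mat dFo = dr2;
    if (lc.drop2.n_elem > 0) dFo %= lc.drop2;
    G.lay(l, 12) += lc.Hff.t() * dFo;
    G.lay(l, 13) += arma::sum(dFo, 0);
    arma::mat dH = dFo * P.lay(l, 12).t();
    arma::mat dpre = dH % arma::conv_to<arma::mat>::from(lc.pre > 0);
    G.lay(l, 10) += lc.y1.t() * dpre;
    G.lay(l, 11) += arma::sum(dpre, 0);
    dy1 += dpre * P.lay(l, 10).t();
    arma::mat dr1;
    layernorm_bwd(dy1, P.lay(l, 8), lc.xhat1, lc.istd1, dr1,
                  G.lay(l, 8), G.lay(l, 9));
    arma::mat dXin = dr1;                      // residual branch
    arma::mat dP = dr1;
    if (lc.drop1.n_elem > 0) dP %= lc.drop1;
    G.lay(l, 6) += lc.O.t() * dP;
    G.lay(l, 7) += arma::sum(dP, 0);
    arma::mat dO = dP * P.lay(l, 6).t();
    arma::mat dQ(arma::size(lc.Q), arma::fill::zeros);
    arma::mat dK(arma::size(lc.K), arma::fill::zeros);
    arma::mat dV(arma::size(lc.Vv), arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int a = off(b), z = off(b + 1) - 1;
      arma::span rs(a, z);
      for (int h = 0; h < c.H; ++h) {
        arma::span cs(h * c.dh, (h + 1) * c.dh - 1);
        arma::mat dOh = dO(rs, cs);
        arma::mat& A = lc.A[b][h];
        arma::mat dA = dOh * lc.Vv(rs, cs).t();
        dV(rs, cs) = A.t() * dOh;
        arma::vec rsum = arma::sum(dA % A, 1);
        arma::mat dS = A % (dA.each_col() - rsum);
        dS *= scale;
        dQ(rs, cs) = dS * lc.K(rs, cs);
        dK(rs, cs) = dS.t() * lc.Q(rs, cs);
      }
    }
    G.lay(l, 0) += lc.X.t() * dQ; G.lay(l, 1) += arma::sum(dQ, 0);
    G.lay(l, 2) += lc.X.t() * dK; G.lay(l, 3) += arma::sum(dK, 0);
    G.lay(l, 4) += lc.X.t() * dV; G.lay(l, 5) += arma::sum(dV, 0);
    dXin += dQ * P.lay(l, 0).t() + dK * P.lay(l, 2).t() + dV * P.lay(l, 4).t();
    dX = dXin;
  }
  return dX;
}

// Stack the batch: embedding rows + sinusoidal positions; decoder tags (when
// present) replace the first token's embedding of their sequence.
static arma::mat stack_embed(ParamPack& P, const TfCfg& c,
                             const IntegerMatrix& tokens,
                             const IntegerVector& lengths,
                             const NumericMatrix* tags,
                             const LogicalVector* use_tag,
                             arma::ivec& off) {
  int B = tokens.nrow();
  off.set_size(B + 1);
  off(0) = 0;
  for (int b = 0; b < B; ++b) off(b + 1) = off(b) + lengths[b];
  int Tmax = 0;
  for (int b = 0; b < B; ++b) if (lengths[b] > Tmax) Tmax = lengths[b];
  arma::mat pe = sinusoidal_pe(Tmax, c.D);
  arma::mat X(off(B), c.D);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < lengths[b]; ++i) {
      if (i == 0 && tags != NULL && (*use_tag)[b]) {
        arma::rowvec tg(c.Mtag);
        for (int m = 0; m < c.Mtag; ++m) tg(m) = (*tags)(b, m);
        X.row(off(b)) = tg * P.tag_w(c) + P.tag_b(c).row(0);
      } else {
        X.row(off(b) + i) = P.emb().row(tokens(b, i));
      }
      X.row(off(b) + i) += pe.row(i);
    }
  }
  return X;
}

// Multi-output regression loss (mean squared error over outputs and batch)
// for the encoder; CLS is token 0 of each sequence.
// [[Rcpp::export]]
List cpp_enc_loss_grad(NumericVector par, IntegerMatrix tokens,
                       IntegerVector lengths, NumericMatrix targets,
                       List cfg, bool want_grad, bool train = false) {
  TfCfg c = tf_cfg(cfg);
  ParamPack P(par.begin(), c);
  RNGScope scope;
  int B = tokens.nrow();
  arma::ivec off;
  arma::mat X0 = stack_embed(P, c, tokens, lengths, NULL, NULL, off);
  std::vector<LayerCache> cache;
  arma::mat X = tf_forward_batch(P, c, X0, off, want_grad ? &cache : NULL, train);
  NumericVector grad(want_grad ? par.size() : 1);
  ParamPack* Gp = want_grad ? new ParamPack(grad.begin(), c) : NULL;
  double loss = 0.0;
  arma::mat dX;
  if (want_grad) dX.zeros(X.n_rows, c.D);
  for (int b = 0; b < B; ++b) {
    arma::rowvec y = X.row(off(b)) * P.head_w(c) + P.head_b(c).row(0);
    arma::rowvec z(c.M);
    for (int m = 0; m < c.M; ++m) z(m) = targets(b, m);
    arma::rowvec diff = y - z;
    loss += arma::accu(arma::square(diff)) / c.M;
    if (want_grad) {
      arma::rowvec dy = 2.0 * diff / (double)(c.M * B);
      Gp->head_w(c) += X.row(off(b)).t() * dy;
      Gp->head_b(c) += dy;
      dX.row(off(b)) = dy * P.head_w(c).t();
    }
  }
  loss /= B;
  if (want_grad) {
    arma::mat dX0 = tf_backward_batch(P, *Gp, c, cache, off, dX);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < lengths[b]; ++i)
        Gp->emb().row(tokens(b, i)) += dX0.row(off(b) + i);
  }
  List out = List::create(_["loss"] = loss);
  if (want_grad) { out["grad"] = grad; delete Gp; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_enc_predict(NumericVector par, IntegerMatrix tokens,
                              IntegerVector lengths, List cfg) {
  TfCfg c = tf_cfg(cfg);
  ParamPack P(par.begin(), c);
  int B = tokens.nrow();
  arma::ivec off;
  arma::mat X0 = stack_embed(P, c, tokens, lengths, NULL, NULL, off);
  arma::mat X = tf_forward_batch(P, c, X0, off, NULL, false);
  NumericMatrix out(B, c.M);
  for (int b = 0; b < B; ++b) {
    arma::rowvec y = X.row(off(b)) * P.head_w(c) + P.head_b(c).row(0);
    for (int m = 0; m < c.M; ++m) out(b, m) = y(m);
  }
  return out;
}

// Next-token cross-entropy for the decoder, averaged per predicted token.
// Sequences are START token ... STOP; a per-sequence flag selects whether the
// first position is the tag projection (conditional) or the START embedding.
// [[Rcpp::export]]
List cpp_dec_loss_grad(NumericVector par, IntegerMatrix tokens,
                       IntegerVector lengths, NumericMatrix tags,
                       LogicalVector use_tag, List cfg, bool want_grad,
                       bool train = false) {
  TfCfg c = tf_cfg(cfg);
  ParamPack P(par.begin(), c);
  RNGScope scope;
  int B = tokens.nrow();
  // inputs are positions 0 .. n-2 of each sequence
  IntegerVector in_len(B);
  long ntok = 0;
  for (int b = 0; b < B; ++b) { in_len[b] = lengths[b] - 1; ntok += in_len[b]; }
  arma::ivec off;
  arma::mat X0 = stack_embed(P, c, tokens, in_len, &tags, &use_tag, off);
  std::vector<LayerCache> cache;
  arma::mat X = tf_forward_batch(P, c, X0, off, want_grad ? &cache : NULL, train);
  NumericVector grad(want_grad ? par.size() : 1);
  ParamPack* Gp = want_grad ? new ParamPack(grad.begin(), c) : NULL;
  arma::mat logits = X * P.head_w(c);
  logits.each_row() += P.head_b(c).row(0);
  double loss = 0.0;
  arma::mat dlogits;
  if (want_grad) dlogits.zeros(X.n_rows, c.M);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < in_len[b]; ++i) {
      int row = off(b) + i;
      int target = tokens(b, i + 1);
      arma::rowvec r = logits.row(row);
      double mx = r.max();
      arma::rowvec e = arma::exp(r - mx);
      double Zs = arma::accu(e);
      loss -= (r(target) - mx - std::log(Zs));
      if (want_grad) {
        arma::rowvec p = e / Zs;
        p(target) -= 1.0;
        dlogits.row(row) = p / (double)ntok;
      }
    }
  }
  loss /= (double)ntok;
  if (want_grad) {
    Gp->head_w(c) += X.t() * dlogits;
    Gp->head_b(c) += arma::sum(dlogits, 0);
    arma::mat dX = dlogits * P.head_w(c).t();
    arma::mat dX0 = tf_backward_batch(P, *Gp, c, cache, off, dX);
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < in_len[b]; ++i) {
        if (i == 0 && use_tag[b]) {
          arma::rowvec tg(c.Mtag);
          for (int m = 0; m < c.Mtag; ++m) tg(m) = tags(b, m);
          Gp->tag_w(c) += tg.t() * dX0.row(off(b));
          Gp->tag_b(c) += dX0.row(off(b));
        } else {
          Gp->emb().row(tokens(b, i)) += dX0.row(off(b) + i);
        }
      }
    }
  }
  List out = List::create(_["loss"] = loss, _["ntok"] = (double)ntok);
  if (want_grad) { out["grad"] = grad; delete Gp; }
  return out;
}

// Position-wise next-token logits for one prefix (log-probability scoring).
// [[Rcpp::export]]
NumericMatrix cpp_dec_logits(NumericVector par, IntegerVector prefix,
                             Nullable<NumericVector> tag_, List cfg) {
  TfCfg c = tf_cfg(cfg);
  ParamPack P(par.begin(), c);
  int n = prefix.size();
  IntegerMatrix tok(1, n);
  for (int i = 0; i < n; ++i) tok(0, i) = prefix[i];
  IntegerVector len = IntegerVector::create(n);
  NumericMatrix tags(1, std::max(1, c.Mtag));
  LogicalVector use(1);
  use[0] = tag_.isNotNull();
  if (use[0]) {
    NumericVector t(tag_);
    for (int i = 0; i < t.size(); ++i) tags(0, i) = t[i];
  }
  arma::ivec off;
  arma::mat X0 = stack_embed(P, c, tok, len, &tags, &use, off);
  arma::mat X = tf_forward_batch(P, c, X0, off, NULL, false);
  arma::mat logits = X * P.head_w(c);
  logits.each_row() += P.head_b(c).row(0);
  return wrap(logits);
}

// Last-position logits for a batch of equal-length prefixes (one sampling
// step over many sequences at once).
// [[Rcpp::export]]
NumericMatrix cpp_dec_logits_batch(NumericVector par, IntegerMatrix prefixes,
                                   Nullable<NumericMatrix> tags_,
                                   Nullable<LogicalVector> use_tag_,
                                   List cfg) {
  TfCfg c = tf_cfg(cfg);
  ParamPack P(par.begin(), c);
  int B = prefixes.nrow();
  int n = prefixes.ncol();
  IntegerVector len(B, n);
  NumericMatrix tags(B, std::max(1, c.Mtag));
  LogicalVector use(B);
  if (tags_.isNotNull() && use_tag_.isNotNull()) {
    NumericMatrix t(tags_);
    LogicalVector u(use_tag_);
    for (int b = 0; b < B; ++b) {
      use[b] = u[b];
      for (int m = 0; m < t.ncol(); ++m) tags(b, m) = t(b, m);
    }
  }
  arma::ivec off;
  arma::mat X0 = stack_embed(P, c, prefixes, len, &tags, &use, off);
  arma::mat X = tf_forward_batch(P, c, X0, off, NULL, false);
  NumericMatrix out(B, c.M);
  for (int b = 0; b < B; ++b) {
    arma::rowvec y = X.row(off(b + 1) - 1) * P.head_w(c) + P.head_b(c).row(0);
    for (int m = 0; m < c.M; ++m) out(b, m) = y(m);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bidirectional LSTM regressor
// ---------------------------------------------------------------------------

struct LstmCfg {
  int V, De, hid, L, M;
  double dropout;
};

static LstmCfg lstm_cfg(const List& cfg) {
  LstmCfg c;
  c.V = as<int>(cfg["V"]);
  c.De = as<int>(cfg["De"]);
  c.hid = as<int>(cfg["hid"]);
  c.L = as<int>(cfg["L"]);
  c.M = as<int>(cfg["M"]);
  c.dropout = cfg.containsElementNamed("dropout") ? as<double>(cfg["dropout"]) : 0.0;
  return c;
}

// Layout: embedding; per layer x direction {W(in x 4h), U(h x 4h), b(1 x 4h)};
// head (2h x M), head bias.
static void lstm_shapes(const LstmCfg& c, std::vector<std::pair<int,int> >& sh) {
  sh.clear();
  sh.push_back(std::make_pair(c.V, c.De));
  for (int l = 0; l < c.L; ++l) {
    int in = (l == 0) ? c.De : 2 * c.hid;
    for (int d = 0; d < 2; ++d) {
      sh.push_back(std::make_pair(in, 4 * c.hid));
      sh.push_back(std::make_pair(c.hid, 4 * c.hid));
      sh.push_back(std::make_pair(1, 4 * c.hid));
    }
  }
  sh.push_back(std::make_pair(2 * c.hid, c.M));
  sh.push_back(std::make_pair(1, c.M));
}

struct LstmPack {
  std::vector<arma::mat*> m;
  LstmPack(double* ptr, const LstmCfg& c) {
    std::vector<std::pair<int,int> > sh;
    lstm_shapes(c, sh);
    size_t off = 0;
    for (size_t i = 0; i < sh.size(); ++i) {
      m.push_back(new arma::mat(ptr + off, sh[i].first, sh[i].second, false, true));
      off += (size_t)sh[i].first * sh[i].second;
    }
  }
  ~LstmPack() { for (size_t i = 0; i < m.size(); ++i) delete m[i]; }
  arma::mat& emb() { return *m[0]; }
  arma::mat& W(int l, int d) { return *m[1 + (l * 2 + d) * 3 + 0]; }
  arma::mat& U(int l, int d) { return *m[1 + (l * 2 + d) * 3 + 1]; }
  arma::mat& b(int l, int d) { return *m[1 + (l * 2 + d) * 3 + 2]; }
  arma::mat& head_w(const LstmCfg& c) { return *m[1 + c.L * 6]; }
  arma::mat& head_b(const LstmCfg& c) { return *m[2 + c.L * 6]; }
};

static size_t lstm_count(const LstmCfg& c) {
  std::vector<std::pair<int,int> > sh;
  lstm_shapes(c, sh);
  size_t n = 0;
  for (size_t i = 0; i < sh.size(); ++i)
    n += (size_t)sh[i].first * sh[i].second;
  return n;
}

// [[Rcpp::export]]
int cpp_lstm_nparams(List cfg) { return (int)lstm_count(lstm_cfg(cfg)); }

// [[Rcpp::export]]
NumericVector cpp_lstm_init(List cfg) {
  LstmCfg c = lstm_cfg(cfg);
  std::vector<std::pair<int,int> > sh;
  lstm_shapes(c, sh);
  NumericVector out(lstm_count(c));
  RNGScope scope;
  size_t off = 0;
  for (size_t i = 0; i < sh.size(); ++i) {
    int r = sh[i].first, cc = sh[i].second;
    size_t len = (size_t)r * cc;
    if (r == 1) {
      // biases zero except forget gate (+1) for LSTM gate biases
      bool is_gate_bias = (i >= 1 && i < (size_t)(1 + c.L * 6) && ((i - 1) % 3) == 2);
      for (size_t j = 0; j < len; ++j) out[off + j] = 0.0;
      if (is_gate_bias)
        for (int j = c.hid; j < 2 * c.hid; ++j) out[off + j] = 1.0;
    } else {
      double lim = std::sqrt(6.0 / (double)(r + cc));
      for (size_t j = 0; j < len; ++j) out[off + j] = R::runif(-lim, lim);
    }
    off += len;
  }
  return out;
}

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct LstmDirCache {
  arma::mat i, f, g, o, cst, h, tanhc; // n x hid each
  arma::mat in;                        // layer input (n x in_dim)
};

// One direction of one layer; reverse=true runs right-to-left.
static void lstm_dir_fwd(LstmPack& P, const LstmCfg& c, int l, int d,
                         const arma::mat& input, bool reverse, LstmDirCache& lc) {
  int n = input.n_rows, h = c.hid;
  lc.in = input;
  lc.i.set_size(n, h); lc.f.set_size(n, h); lc.g.set_size(n, h);
  lc.o.set_size(n, h); lc.cst.set_size(n, h); lc.h.set_size(n, h);
  lc.tanhc.set_size(n, h);
  arma::rowvec hp(h, arma::fill::zeros), cp(h, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    int t = reverse ? (n - 1 - s) : s;
    arma::rowvec z = input.row(t) * P.W(l, d) + hp * P.U(l, d) + P.b(l, d).row(0);
    for (int j = 0; j < h; ++j) {
      double iv = sigm(z(j));
      double fv = sigm(z(h + j));
      double gv = std::tanh(z(2 * h + j));
      double ov = sigm(z(3 * h + j));
      double cv = fv * cp(j) + iv * gv;
      double tc = std::tanh(cv);
      lc.i(t, j) = iv; lc.f(t, j) = fv; lc.g(t, j) = gv; lc.o(t, j) = ov;
      lc.cst(t, j) = cv; lc.tanhc(t, j) = tc;
      lc.h(t, j) = ov * tc;
    }
    hp = lc.h.row(t);
    cp = lc.cst.row(t);
  }
}

static void lstm_dir_bwd(LstmPack& P, LstmPack& G, const LstmCfg& c, int l, int d,
                         const LstmDirCache& lc, const arma::mat& dh_out,
                         bool reverse, arma::mat& din) {
  int n = lc.h.n_rows, h = c.hid;
  din.zeros(n, lc.in.n_cols);
  arma::rowvec dh_next(h, arma::fill::zeros), dc_next(h, arma::fill::zeros);
  for (int s = n - 1; s >= 0; --s) {
    int t = reverse ? (n - 1 - s) : s;
    int tprev = reverse ? (t + 1) : (t - 1);
    bool has_prev = reverse ? (t + 1 < n) : (t - 1 >= 0);
    arma::rowvec dh = dh_out.row(t) + dh_next;
    arma::rowvec dz(4 * h);
    arma::rowvec dc(h);
    for (int j = 0; j < h; ++j) {
      double tc = lc.tanhc(t, j);
      double doo = dh(j) * tc;
      double dcj = dh(j) * lc.o(t, j) * (1.0 - tc * tc) + dc_next(j);
      double cprev = has_prev ? lc.cst(tprev, j) : 0.0;
      double di = dcj * lc.g(t, j);
      double df = dcj * cprev;
      double dg = dcj * lc.i(t, j);
      dz(j) = di * lc.i(t, j) * (1.0 - lc.i(t, j));
      dz(h + j) = df * lc.f(t, j) * (1.0 - lc.f(t, j));
      dz(2 * h + j) = dg * (1.0 - lc.g(t, j) * lc.g(t, j));
      dz(3 * h + j) = doo * lc.o(t, j) * (1.0 - lc.o(t, j));
      dc(j) = dcj * lc.f(t, j);
    }
    G.W(l, d) += lc.in.row(t).t() * dz;
    if (has_prev) G.U(l, d) += lc.h.row(tprev).t() * dz;
    G.b(l, d) += dz;
    din.row(t) += dz * P.W(l, d).t();
    dh_next = has_prev ? arma::rowvec(dz * P.U(l, d).t())
                       : arma::rowvec(h, arma::fill::zeros);
    dc_next = dc;
  }
}

// Full biLSTM regression loss/gradient. Dropout masks (inverted dropout) are
// drawn from R's RNG when train=true and dropout>0.
// [[Rcpp::export]]
List cpp_lstm_loss_grad(NumericVector par, IntegerMatrix tokens,
                        IntegerVector lengths, NumericMatrix targets,
                        List cfg, bool train, bool want_grad) {
  LstmCfg c = lstm_cfg(cfg);
  LstmPack P(par.begin(), c);
  int B = tokens.nrow();
  NumericVector grad(want_grad ? par.size() : 1);
  LstmPack* Gp = want_grad ? new LstmPack(grad.begin(), c) : NULL;
  RNGScope scope;
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    int n = lengths[b];
    arma::mat X(n, c.De);
    arma::ivec tok(n);
    for (int i = 0; i < n; ++i) { tok(i) = tokens(b, i); X.row(i) = P.emb().row(tok(i)); }
    std::vector<LstmDirCache> fw(c.L), bw(c.L);
    std::vector<arma::mat> masks(c.L);
    arma::mat layer_in = X;
    for (int l = 0; l < c.L; ++l) {
      lstm_dir_fwd(P, c, l, 0, layer_in, false, fw[l]);
      lstm_dir_fwd(P, c, l, 1, layer_in, true, bw[l]);
      arma::mat out = arma::join_rows(fw[l].h, bw[l].h);
      if (train && c.dropout > 0) {
        masks[l] = dropout_mask(out.n_rows, out.n_cols, c.dropout);
        out %= masks[l];
      }
      layer_in = out;
    }
    // pool: final forward state and first-position backward state of top layer
    arma::rowvec feat(2 * c.hid);
    feat.cols(0, c.hid - 1) = layer_in(n - 1, arma::span(0, c.hid - 1));
    feat.cols(c.hid, 2 * c.hid - 1) = layer_in(0, arma::span(c.hid, 2 * c.hid - 1));
    arma::rowvec y = feat * P.head_w(c) + P.head_b(c).row(0);
    arma::rowvec z(c.M);
    for (int m = 0; m < c.M; ++m) z(m) = targets(b, m);
    arma::rowvec diff = y - z;
    loss += arma::accu(arma::square(diff)) / c.M;
    if (want_grad) {
      arma::rowvec dy = 2.0 * diff / (double)(c.M * B);
      Gp->head_w(c) += feat.t() * dy;
      Gp->head_b(c) += dy;
      arma::rowvec dfeat = dy * P.head_w(c).t();
      arma::mat dtop(n, 2 * c.hid, arma::fill::zeros);
      dtop(n - 1, arma::span(0, c.hid - 1)) = dfeat.cols(0, c.hid - 1);
      dtop(0, arma::span(c.hid, 2 * c.hid - 1)) = dfeat.cols(c.hid, 2 * c.hid - 1);
      arma::mat dout = dtop;
      for (int l = c.L - 1; l >= 0; --l) {
        if (train && c.dropout > 0) dout %= masks[l];
        arma::mat din_f, din_b;
        lstm_dir_bwd(P, *Gp, c, l, 0, fw[l], dout.cols(0, c.hid - 1), false, din_f);
        lstm_dir_bwd(P, *Gp, c, l, 1, bw[l], dout.cols(c.hid, 2 * c.hid - 1), true, din_b);
        dout = din_f + din_b;
      }
      for (int i = 0; i < n; ++i) Gp->emb().row(tok(i)) += dout.row(i);
    }
  }
  loss /= B;
  List out = List::create(_["loss"] = loss);
  if (want_grad) { out["grad"] = grad; delete Gp; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_lstm_predict(NumericVector par, IntegerMatrix tokens,
                               IntegerVector lengths, List cfg) {
  LstmCfg c = lstm_cfg(cfg);
  LstmPack P(par.begin(), c);
  int B = tokens.nrow();
  NumericMatrix out(B, c.M);
  for (int b = 0; b < B; ++b) {
    int n = lengths[b];
    arma::mat X(n, c.De);
    for (int i = 0; i < n; ++i) X.row(i) = P.emb().row(tokens(b, i));
    arma::mat layer_in = X;
    for (int l = 0; l < c.L; ++l) {
      LstmDirCache f, r;
      lstm_dir_fwd(P, c, l, 0, layer_in, false, f);
      lstm_dir_fwd(P, c, l, 1, layer_in, true, r);
      layer_in = arma::join_rows(f.h, r.h);
    }
    arma::rowvec feat(2 * c.hid);
    feat.cols(0, c.hid - 1) = layer_in(n - 1, arma::span(0, c.hid - 1));
    feat.cols(c.hid, 2 * c.hid - 1) = layer_in(0, arma::span(c.hid, 2 * c.hid - 1));
    arma::rowvec y = feat * P.head_w(c) + P.head_b(c).row(0);
    for (int m = 0; m < c.M; ++m) out(b, m) = y(m);
  }
  return out;
}
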