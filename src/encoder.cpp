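// Compact bidirectional transformer encoder with ALiBi distance penalties.
// Forward and analytic backward passes; no autograd dependency. Pre-layer
// normalization, GELU feed-forward, tied input/output embeddings, no
// positional embeddings other than the attention bias.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;
static const double LOG2E = 1.4426950408889634; // 1/ln(2)

struct LayerParams {
  arma::vec ln1_g, ln1_b, ln2_g, ln2_b, b1, b2;
  arma::mat Wq, Wk, Wv, Wo, W1, W2;
};

struct EncoderParams {
  arma::mat emb;          // V x d
  arma::vec out_b;        // V
  arma::vec lnf_g, lnf_b; // d
  std::vector<LayerParams> layers;
};

static EncoderParams parse_params(const List& p, int n_layers) {
  EncoderParams ep;
  ep.emb = as<arma::mat>(p["emb"]);
  ep.out_b = as<arma::vec>(p["out_b"]);
  ep.lnf_g = as<arma::vec>(p["lnf_g"]);
  ep.lnf_b = as<arma::vec>(p["lnf_b"]);
  ep.layers.resize(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    std::string pre = "l" + std::to_string(l + 1) + ".";
    LayerParams& L = ep.layers[l];
    L.ln1_g = as<arma::vec>(p[pre + "ln1_g"]);
    L.ln1_b = as<arma::vec>(p[pre + "ln1_b"]);
    L.Wq = as<arma::mat>(p[pre + "Wq"]);
    L.Wk = as<arma::mat>(p[pre + "Wk"]);
    L.Wv = as<arma::mat>(p[pre + "Wv"]);
    L.Wo = as<arma::mat>(p[pre + "Wo"]);
    L.ln2_g = as<arma::vec>(p[pre + "ln2_g"]);
    L.ln2_b = as<arma::vec>(p[pre + "ln2_b"]);
    L.W1 = as<arma::mat>(p[pre + "W1"]);
    L.b1 = as<arma::vec>(p[pre + "b1"]);
    L.W2 = as<arma::mat>(p[pre + "W2"]);
    L.b2 = as<arma::vec>(p[pre + "b2"]);
  }
  return ep;
}

// layer norm over rows; caches xhat and 1/sigma for backward
static arma::mat layernorm_fwd(const arma::mat& X, const arma::vec& g,
                               const arma::vec& b, arma::mat& xhat,
                               arma::vec& inv_sigma) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat Xc = X.each_col() - mu;
  arma::vec var = arma::mean(arma::square(Xc), 1);
  inv_sigma = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = Xc.each_col() % inv_sigma;
  arma::mat Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static arma::mat layernorm_bwd(const arma::mat& dY, const arma::mat& xhat,
                               const arma::vec& inv_sigma, const arma::vec& g,
                               arma::vec& dg, arma::vec& db) {
  dg += arma::sum(dY % xhat, 0).t();
  db += arma::sum(dY, 0).t();
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv_sigma;
  return dX;
}

static arma::mat gelu(const arma::mat& X) {
  // exact GELU: x * Phi(x)
  return X % (0.5 * (1.0 + arma::erf(X / std::sqrt(2.0))));
}

static arma::mat gelu_grad(const arma::mat& X) {
  arma::mat Phi = 0.5 * (1.0 + arma::erf(X / std::sqrt(2.0)));
  arma::mat phi = arma::exp(-0.5 * arma::square(X)) / std::sqrt(2.0 * M_PI);
  return Phi + X % phi;
}

static arma::mat softmax_rows(const arma::mat& S) {
  arma::vec mx = arma::max(S, 1);
  arma::mat E = arma::exp(S.each_col() - mx);
  arma::vec Z = arma::sum(E, 1);
  return E.each_col() / Z;
}

struct LayerCache {
  arma::mat Xin, xhat1, Xn, Q, K, V, O, Xmid, xhat2, Xn2, pre, H1;
  arma::vec is1, is2;
  std::vector<arma::mat> P; // attention weights per head
};

struct ForwardCache {
  arma::mat X0, Xlast, xhatf;
  arma::vec isf;
  std::vector<LayerCache> layers;
};

// Full forward pass; returns final layer-normalized states (L x d).
static arma::mat encoder_forward(const EncoderParams& ep, int n_heads,
                                 const arma::ivec& tok0, const arma::vec& slopes,
                                 ForwardCache* cache) {
  const int L = tok0.n_elem;
  const int d = ep.emb.n_cols;
  const int H = n_heads;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);

  arma::mat X(L, d);
  for (int i = 0; i < L; ++i) X.row(i) = ep.emb.row(tok0[i]);
  if (cache) { cache->X0 = X; cache->layers.resize(ep.layers.size()); }

  // |i-j| matrix
  arma::mat D(L, L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) D(i, j) = std::abs(i - j);

  for (size_t l = 0; l < ep.layers.size(); ++l) {
    const LayerParams& P = ep.layers[l];
    LayerCache lc;
    lc.Xin = X;
    arma::mat Xn = layernorm_fwd(X, P.ln1_g, P.ln1_b, lc.xhat1, lc.is1);
    lc.Xn = Xn;
    arma::mat Q = Xn * P.Wq, K = Xn * P.Wk, V = Xn * P.Wv;
    lc.Q = Q; lc.K = K; lc.V = V;
    arma::mat O(L, d);
    lc.P.resize(H);
    for (int h = 0; h < H; ++h) {
      arma::span cs(h * dh, (h + 1) * dh - 1);
      arma::mat S = (Q.cols(cs) * K.cols(cs).t()) * scale - slopes[h] * D;
      arma::mat A = softmax_rows(S);
      lc.P[h] = A;
      O.cols(cs) = A * V.cols(cs);
    }
    lc.O = O;
    X = X + O * P.Wo;
    lc.Xmid = X;
    arma::mat Xn2 = layernorm_fwd(X, P.ln2_g, P.ln2_b, lc.xhat2, lc.is2);
    lc.Xn2 = Xn2;
    arma::mat pre = Xn2 * P.W1;
    pre.each_row() += P.b1.t();
    lc.pre = pre;
    arma::mat H1 = gelu(pre);
    lc.H1 = H1;
    arma::mat ff = H1 * P.W2;
    ff.each_row() += P.b2.t();
    X = X + ff;
    if (cache) cache->layers[l] = std::move(lc);
  }

  arma::mat xhatf;
  arma::vec isf;
  arma::mat Xf = layernorm_fwd(X, ep.lnf_g, ep.lnf_b, xhatf, isf);
  if (cache) { cache->Xlast = X; cache->xhatf = xhatf; cache->isf = isf; }
  return Xf;
}

struct EncoderGrads {
  arma::mat emb;
  arma::vec out_b, lnf_g, lnf_b;
  std::vector<LayerParams> layers; // reused as gradient holders
  void init(const EncoderParams& ep) {
    emb.zeros(ep.emb.n_rows, ep.emb.n_cols);
    out_b.zeros(ep.out_b.n_elem);
    lnf_g.zeros(ep.lnf_g.n_elem);
    lnf_b.zeros(ep.lnf_b.n_elem);
    layers.resize(ep.layers.size());
    for (size_t l = 0; l < layers.size(); ++l) {
      const LayerParams& P = ep.layers[l];
      LayerParams& G = layers[l];
      G.ln1_g.zeros(P.ln1_g.n_elem); G.ln1_b.zeros(P.ln1_b.n_elem);
      G.ln2_g.zeros(P.ln2_g.n_elem); G.ln2_b.zeros(P.ln2_b.n_elem);
      G.b1.zeros(P.b1.n_elem); G.b2.zeros(P.b2.n_elem);
      G.Wq.zeros(arma::size(P.Wq)); G.Wk.zeros(arma::size(P.Wk));
      G.Wv.zeros(arma::size(P.Wv)); G.Wo.zeros(arma::size(P.Wo));
      G.W1.zeros(arma::size(P.W1)); G.W2.zeros(arma::size(P.W2));
    }
  }
};

// Backward from dXf (gradient wrt final normalized states), accumulating into G.
static void encoder_backward(const EncoderParams& ep, int n_heads,
                             const arma::ivec& tok0, const ForwardCache& fc,
                             arma::mat dXf, EncoderGrads& G) {
  const int H = n_heads;
  const int d = ep.emb.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);

  arma::mat dX = layernorm_bwd(dXf, fc.xhatf, fc.isf, ep.lnf_g, G.lnf_g, G.lnf_b);

  for (int l = (int)ep.layers.size() - 1; l >= 0; --l) {
    const LayerParams& P = ep.layers[l];
    const LayerCache& lc = fc.layers[l];
    LayerParams& g = G.layers[l];

    // FF block: X = Xmid + gelu(LN(Xmid) W1 + b1) W2 + b2
    arma::mat dH1 = dX * P.W2.t();
    g.W2 += lc.H1.t() * dX;
    g.b2 += arma::sum(dX, 0).t();
    arma::mat dpre = dH1 % gelu_grad(lc.pre);
    g.W1 += lc.Xn2.t() * dpre;
    g.b1 += arma::sum(dpre, 0).t();
    arma::mat dXn2 = dpre * P.W1.t();
    arma::mat dXmid = layernorm_bwd(dXn2, lc.xhat2, lc.is2, P.ln2_g, g.ln2_g, g.ln2_b);
    dXmid += dX; // residual

    // Attention block: Xmid = Xin + O Wo
    arma::mat dO = dXmid * P.Wo.t();
    g.Wo += lc.O.t() * dXmid;
    arma::mat dQ(arma::size(lc.Q), arma::fill::zeros);
    arma::mat dK(arma::size(lc.K), arma::fill::zeros);
    arma::mat dV(arma::size(lc.V), arma::fill::zeros);
    for (int h = 0; h < H; ++h) {
      arma::span cs(h * dh, (h + 1) * dh - 1);
      const arma::mat& A = lc.P[h];
      arma::mat dA = dO.cols(cs) * lc.V.cols(cs).t();
      dV.cols(cs) = A.t() * dO.cols(cs);
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rs);
      dQ.cols(cs) = (dS * lc.K.cols(cs)) * scale;
      dK.cols(cs) = (dS.t() * lc.Q.cols(cs)) * scale;
    }
    arma::mat dXn = dQ * P.Wq.t() + dK * P.Wk.t() + dV * P.Wv.t();
    g.Wq += lc.Xn.t() * dQ;
    g.Wk += lc.Xn.t() * dK;
    g.Wv += lc.Xn.t() * dV;
    arma::mat dXin = layernorm_bwd(dXn, lc.xhat1, lc.is1, P.ln1_g, g.ln1_g, g.ln1_b);
    dX = dXin + dXmid; // residual
  }

  for (arma::uword i = 0; i < tok0.n_elem; ++i)
    G.emb.row(tok0[i]) += dX.row(i);
}

// [[Rcpp::export]]
arma::mat cpp_forward_states(List params, int n_layers, int n_heads,
                             IntegerVector tokens, arma::vec slopes) {
  EncoderParams ep = parse_params(params, n_layers);
  arma::ivec tok0(tokens.size());
  for (int i = 0; i < tokens.size(); ++i) tok0[i] = tokens[i] - 1;
  return encoder_forward(ep, n_heads, tok0, slopes, nullptr);
}

// [[Rcpp::export]]
arma::mat cpp_forward_probs(List params, int n_layers, int n_heads,
                            IntegerVector tokens, arma::vec slopes) {
  EncoderParams ep = parse_params(params, n_layers);
  arma::ivec tok0(tokens.size());
  for (int i = 0; i < tokens.size(); ++i) tok0[i] = tokens[i] - 1;
  arma::mat Xf = encoder_forward(ep, n_heads, tok0, slopes, nullptr);
  arma::mat logits = Xf * ep.emb.t();
  logits.each_row() += ep.out_b.t();
  return softmax_rows(logits);
}

// Masked-LM loss (bits) and, optionally, parameter gradients, accumulated over
// a batch of sequences. mask positions and target ids are 1-based.
// [[Rcpp::export]]
List cpp_mlm_batch(List params, int n_layers, int n_heads, arma::vec slopes,
                   List seqs, List mask_pos, List targets, bool want_grad) {
  EncoderParams ep = parse_params(params, n_layers);
  EncoderGrads G;
  if (want_grad) G.init(ep);
  double loss_bits = 0.0;
  long n_masked = 0;

  const int B = seqs.size();
  for (int b = 0; b < B; ++b) {
    IntegerVector tv = seqs[b];
    IntegerVector mp = mask_pos[b];
    IntegerVector tg = targets[b];
    if (mp.size() == 0) continue;
    arma::ivec tok0(tv.size());
    for (int i = 0; i < tv.size(); ++i) tok0[i] = tv[i] - 1;
    ForwardCache fc;
    arma::mat Xf = encoder_forward(ep, n_heads, tok0, slopes, want_grad ? &fc : nullptr);
    if (!want_grad) {
      // loss only: compute logits just at masked rows
      for (int k = 0; k < mp.size(); ++k) {
        arma::rowvec lg = Xf.row(mp[k] - 1) * ep.emb.t() + ep.out_b.t();
        double mx = lg.max();
        double z = arma::accu(arma::exp(lg - mx));
        double lp = (lg[tg[k] - 1] - mx) - std::log(z);
        loss_bits += -lp * LOG2E;
      }
      n_masked += mp.size();
      continue;
    }
    const int L = tok0.n_elem;
    arma::mat dXf(L, ep.emb.n_cols, arma::fill::zeros);
    for (int k = 0; k < mp.size(); ++k) {
      int i = mp[k] - 1, y = tg[k] - 1;
      arma::rowvec lg = Xf.row(i) * ep.emb.t() + ep.out_b.t();
      double mx = lg.max();
      arma::rowvec e = arma::exp(lg - mx);
      arma::rowvec p = e / arma::accu(e);
      loss_bits += -std::log(p[y]) * LOG2E;
      arma::rowvec dlg = p * LOG2E;
      dlg[y] -= LOG2E;
      dXf.row(i) += dlg * ep.emb;
      G.emb += dlg.t() * Xf.row(i); // logits = Xf emb^T => d emb = dlg^T Xf
      G.out_b += dlg.t();
    }
    encoder_backward(ep, n_heads, tok0, fc, dXf, G);
    n_masked += mp.size();
  }

  List out = List::create(_["loss_bits"] = loss_bits, _["n_masked"] = (double)n_masked);
  if (want_grad) {
    List gl;
    gl["emb"] = G.emb;
    gl["out_b"] = G.out_b;
    gl["lnf_g"] = G.lnf_g;
    gl["lnf_b"] = G.lnf_b;
    for (int l = 0; l < n_layers; ++l) {
      std::string pre = "l" + std::to_string(l + 1) + ".";
      LayerParams& g = G.layers[l];
      gl[pre + "ln1_g"] = g.ln1_g; gl[pre + "ln1_b"] = g.ln1_b;
      gl[pre + "Wq"] = g.Wq; gl[pre + "Wk"] = g.Wk; gl[pre + "Wv"] = g.Wv;
      gl[pre + "Wo"] = g.Wo;
      gl[pre + "ln2_g"] = g.ln2_g; gl[pre + "ln2_b"] = g.ln2_b;
      gl[pre + "W1"] = g.W1; gl[pre + "b1"] = g.b1;
      gl[pre + "W2"] = g.W2; gl[pre + "b2"] = g.b2;
    }
    out["grads"] = gl;
  }
  return out;
}
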