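// Fast path for the transformer encoder: forward pass, masked-LM loss and
// full backward pass in one call.  This mirrors, operation for operation,
// the reference implementation in R/transformer.R; the test suite checks
// the two paths against each other and against finite differences, so any
// change here must be made in both places.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::vec;

static const double LN_EPS = 1e-5;
static const double GELU_C = 0.7978845608028654;  // sqrt(2/pi)
static const double GELU_A = 0.044715;

struct LNCache {
  mat Xhat;
  vec inv;
};

static mat ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                      LNCache& c) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = arma::mean(Xc % Xc, 1);
  c.inv = 1.0 / arma::sqrt(v + LN_EPS);
  c.Xhat = Xc.each_col() % c.inv;
  mat Y = c.Xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_backward(const mat& dY, const LNCache& c, const rowvec& g,
                       rowvec& dg, rowvec& db) {
  dg = arma::sum(dY % c.Xhat, 0);
  db = arma::sum(dY, 0);
  mat dXhat = dY.each_row() % g;
  vec m1 = arma::mean(dXhat, 1);
  vec m2 = arma::mean(dXhat % c.Xhat, 1);
  mat dX = dXhat;
  dX.each_col() -= m1;
  dX -= c.Xhat.each_col() % m2;
  dX.each_col() %= c.inv;
  return dX;
}

static void softmax_rows_inplace(mat& S) {
  vec rmax = arma::max(S, 1);
  S.each_col() -= rmax;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

struct LayerCache {
  mat Q, K, V, O;
  std::vector<mat> A;  // B * n_heads attention matrices
  LNCache ln1, ln2;
  mat H_in, H1, Z, Tn, G;
};

struct Cfg {
  int num_layers, hidden_dim, num_heads, ff_dim, max_len, vocab_size;
  double dropout;
  bool relu;
};

// rowvec -> plain R numeric vector (wrap() would give a 1 x d matrix)
static NumericVector rv(const rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.num_layers = as<int>(cfg["num_layers"]);
  c.hidden_dim = as<int>(cfg["hidden_dim"]);
  c.num_heads = as<int>(cfg["num_heads"]);
  c.ff_dim = as<int>(cfg["ff_dim"]);
  c.max_len = as<int>(cfg["max_len"]);
  c.vocab_size = as<int>(cfg["vocab_size"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.relu = as<bool>(cfg["relu"]);
  return c;
}

struct Forward {
  mat H;
  uvec ids_flat;           // 0-based embedding rows, row-major (b, t)
  LNCache ln0;
  mat drop_mask;           // empty when dropout is off
  std::vector<LayerCache> layers;
  std::vector<uvec> masked_keys;  // per sequence, indices of PAD keys
  int B, L;
};

static void run_forward(const List& params, const Cfg& cfg,
                        const IntegerMatrix& ids, const NumericMatrix& mask,
                        double dropout_rate, Forward& fw) {
  const int B = ids.nrow(), L = ids.ncol(), d = cfg.hidden_dim;
  const int nh = cfg.num_heads, dk = d / nh;
  const double scal = 1.0 / std::sqrt((double)dk);
  fw.B = B;
  fw.L = L;

  mat tok_emb = as<mat>(params["tok_emb"]);
  mat pos_emb = as<mat>(params["pos_emb"]);
  rowvec eg = as<rowvec>(params["emb_ln_g"]);
  rowvec eb = as<rowvec>(params["emb_ln_b"]);

  fw.ids_flat.set_size(B * L);
  mat X(B * L, d);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t) {
      int r = b * L + t;
      fw.ids_flat[r] = ids(b, t);
      X.row(r) = tok_emb.row(ids(b, t)) + pos_emb.row(t);
    }
  mat H = ln_forward(X, eg, eb, fw.ln0);

  if (dropout_rate > 0) {
    // draws from R's RNG in column-major order: identical to the R path
    fw.drop_mask.set_size(B * L, d);
    const double keep = 1.0 - dropout_rate;
    for (arma::uword i = 0; i < fw.drop_mask.n_elem; ++i)
      fw.drop_mask[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    H %= fw.drop_mask;
  }

  fw.masked_keys.resize(B);
  for (int b = 0; b < B; ++b) {
    std::vector<arma::uword> bad;
    for (int t = 0; t < L; ++t)
      if (mask(b, t) == 0) bad.push_back(t);
    fw.masked_keys[b] = uvec(bad);
  }

  List layer_params = params["layers"];
  fw.layers.resize(cfg.num_layers);
  for (int l = 0; l < cfg.num_layers; ++l) {
    List lp = layer_params[l];
    LayerCache& cc = fw.layers[l];
    cc.H_in = H;
    cc.Q = H * as<mat>(lp["Wq"]);
    cc.Q.each_row() += as<rowvec>(lp["bq"]);
    cc.K = H * as<mat>(lp["Wk"]);
    cc.K.each_row() += as<rowvec>(lp["bk"]);
    cc.V = H * as<mat>(lp["Wv"]);
    cc.V.each_row() += as<rowvec>(lp["bv"]);
    cc.O.zeros(B * L, d);
    cc.A.resize(B * nh);
    for (int b = 0; b < B; ++b) {
      arma::span rows(b * L, b * L + L - 1);
      const uvec& bad = fw.masked_keys[b];
      for (int h = 0; h < nh; ++h) {
        arma::span cols(h * dk, h * dk + dk - 1);
        mat S = cc.Q(rows, cols) * cc.K(rows, cols).t() * scal;
        if (bad.n_elem > 0)
          S.cols(bad).fill(-1e30);
        softmax_rows_inplace(S);
        cc.O(rows, cols) = S * cc.V(rows, cols);
        cc.A[b * nh + h] = std::move(S);
      }
    }
    mat attn = cc.O * as<mat>(lp["Wo"]);
    attn.each_row() += as<rowvec>(lp["bo"]);
    cc.H1 = ln_forward(H + attn, as<rowvec>(lp["ln1_g"]),
                       as<rowvec>(lp["ln1_b"]), cc.ln1);
    cc.Z = cc.H1 * as<mat>(lp["W1"]);
    cc.Z.each_row() += as<rowvec>(lp["b1"]);
    if (cfg.relu) {
      cc.G = arma::clamp(cc.Z, 0.0, arma::datum::inf);
    } else {
      cc.Tn = arma::tanh(GELU_C * (cc.Z + GELU_A * (cc.Z % cc.Z % cc.Z)));
      cc.G = 0.5 * cc.Z % (1 + cc.Tn);
    }
    mat FF = cc.G * as<mat>(lp["W2"]);
    FF.each_row() += as<rowvec>(lp["b2"]);
    H = ln_forward(cc.H1 + FF, as<rowvec>(lp["ln2_g"]),
                   as<rowvec>(lp["ln2_b"]), cc.ln2);
  }
  fw.H = std::move(H);
}

// Hidden states only (inference).
// [[Rcpp::export(name = ".cpp_encoder_hidden")]]
NumericMatrix cpp_encoder_hidden(List params, List cfg, IntegerMatrix ids,
                                 NumericMatrix mask) {
  Cfg c = read_cfg(cfg);
  Forward fw;
  run_forward(params, c, ids, mask, 0.0, fw);
  return wrap(fw.H);
}

// One masked-LM training step: forward, loss over labeled positions,
// full backward.  labels: 0-based original token ids, -1 = unlabeled.
// [[Rcpp::export(name = ".cpp_mlm_step")]]
List cpp_mlm_step(List params, List cfg, IntegerMatrix ids,
                  NumericMatrix mask, IntegerVector labels) {
  Cfg c = read_cfg(cfg);
  RNGScope rng;  // dropout draws come from R's RNG stream
  Forward fw;
  run_forward(params, c, ids, mask, c.dropout, fw);
  const int B = fw.B, L = fw.L, d = c.hidden_dim;
  const int nh = c.num_heads, dk = d / nh;
  const double scal = 1.0 / std::sqrt((double)dk);

  // ---- masked-LM head -------------------------------------------------
  std::vector<arma::uword> lab_idx;
  for (int i = 0; i < labels.size(); ++i)
    if (labels[i] >= 0) lab_idx.push_back(i);
  if (lab_idx.empty()) stop("no labeled positions in batch");
  uvec rows_lab(lab_idx);
  const int n = rows_lab.n_elem;
  mat mlm_W = as<mat>(params["mlm_W"]);
  rowvec mlm_b = as<rowvec>(params["mlm_b"]);
  mat Hl = fw.H.rows(rows_lab);
  mat logits = Hl * mlm_W;
  logits.each_row() += mlm_b;
  mat P = logits;
  softmax_rows_inplace(P);
  double loss = 0.0;
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    int y = labels[rows_lab[i]];
    loss -= std::log(std::max(P(i, y), 1e-12));
    if ((int)logits.row(i).index_max() == y) ++correct;
  }
  loss /= n;
  mat dlogits = P;
  for (int i = 0; i < n; ++i) dlogits(i, labels[rows_lab[i]]) -= 1.0;
  dlogits /= n;
  mat dW_mlm = Hl.t() * dlogits;
  rowvec db_mlm = arma::sum(dlogits, 0);
  mat dH(B * L, d, arma::fill::zeros);
  dH.rows(rows_lab) = dlogits * mlm_W.t();

  // ---- backward through the layers ------------------------------------
  List layer_params = params["layers"];
  List layer_grads(c.num_layers);
  for (int l = c.num_layers - 1; l >= 0; --l) {
    List lp = layer_params[l];
    LayerCache& cc = fw.layers[l];
    rowvec dg2, db2g;
    mat dFF = ln_backward(dH, cc.ln2, as<rowvec>(lp["ln2_g"]), dg2, db2g);
    mat dG = dFF * as<mat>(lp["W2"]).t();
    mat dZ;
    if (c.relu) {
      dZ = std::move(dG);
      dZ.elem(arma::find(cc.Z <= 0)).zeros();
    } else {
      dZ = dG % (0.5 * (1 + cc.Tn) +
                 0.5 * cc.Z % (1 - cc.Tn % cc.Tn) %
                     (GELU_C * (1 + 3 * GELU_A * cc.Z % cc.Z)));
    }
    mat dH1 = dFF + dZ * as<mat>(lp["W1"]).t();
    rowvec dg1, db1g;
    mat dAttnIn = ln_backward(dH1, cc.ln1, as<rowvec>(lp["ln1_g"]), dg1, db1g);
    mat Wo = as<mat>(lp["Wo"]);
    mat dWo = cc.O.t() * dAttnIn;
    rowvec dbo = arma::sum(dAttnIn, 0);
    mat dO = dAttnIn * Wo.t();
    mat dQ(B * L, d, arma::fill::zeros);
    mat dK(B * L, d, arma::fill::zeros);
    mat dV(B * L, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::span rows(b * L, b * L + L - 1);
      for (int h = 0; h < nh; ++h) {
        arma::span cols(h * dk, h * dk + dk - 1);
        const mat& A = cc.A[b * nh + h];
        mat dOh = dO(rows, cols);
        mat dA = dOh * cc.V(rows, cols).t();
        dV(rows, cols) = A.t() * dOh;
        mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
        dQ(rows, cols) = dS * cc.K(rows, cols) * scal;
        dK(rows, cols) = dS.t() * cc.Q(rows, cols) * scal;
      }
    }
    mat dH_in = dAttnIn + dQ * as<mat>(lp["Wq"]).t() +
                dK * as<mat>(lp["Wk"]).t() + dV * as<mat>(lp["Wv"]).t();
    layer_grads[l] = List::create(
        _["Wq"] = cc.H_in.t() * dQ, _["bq"] = rv(arma::sum(dQ, 0)),
        _["Wk"] = cc.H_in.t() * dK, _["bk"] = rv(arma::sum(dK, 0)),
        _["Wv"] = cc.H_in.t() * dV, _["bv"] = rv(arma::sum(dV, 0)),
        _["Wo"] = dWo, _["bo"] = rv(dbo),
        _["ln1_g"] = rv(dg1), _["ln1_b"] = rv(db1g),
        _["W1"] = cc.H1.t() * dZ, _["b1"] = rv(arma::sum(dZ, 0)),
        _["W2"] = cc.G.t() * dFF, _["b2"] = rv(arma::sum(dFF, 0)),
        _["ln2_g"] = rv(dg2), _["ln2_b"] = rv(db2g));
    dH = std::move(dH_in);
  }
  if (c.dropout > 0) dH %= fw.drop_mask;
  rowvec dg0, db0;
  mat dX = ln_backward(dH, fw.ln0, as<rowvec>(params["emb_ln_g"]), dg0, db0);
  mat dTok(c.vocab_size, d, arma::fill::zeros);
  mat dPos(c.max_len, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t) {
      int r = b * L + t;
      dTok.row(fw.ids_flat[r]) += dX.row(r);
      dPos.row(t) += dX.row(r);
    }

  List grads = List::create(
      _["tok_emb"] = dTok, _["pos_emb"] = dPos,
      _["emb_ln_g"] = rv(dg0), _["emb_ln_b"] = rv(db0),
      _["layers"] = layer_grads,
      _["mlm_W"] = dW_mlm, _["mlm_b"] = rv(db_mlm));
  return List::create(_["loss"] = loss,
                      _["accuracy"] = (double)correct / n,
                      _["grads"] = grads);
}
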