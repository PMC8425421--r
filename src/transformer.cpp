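// Segment-recurrent, convolution-augmented multi-head attention network.
//
// One segment of length Lc (<= l) is processed at a time; the previous
// segment's per-layer hidden states ("memory") are visible to attention
// as read-only context, so the effective attention window of a query is
// always the l most recent positions. q/k/v are derived by a width-cw
// convolution over layer-normalised hidden states (centred receptive
// field, zero padding at sequence ends), and relative position enters the
// attention score as a learned per-head bias over the offset 0..l-1.
//
// Parameters live in one flat vector; the layout is fixed by the config
// (see param_layout). Analytic gradients for every parameter are produced
// by tx_segment_grad and are verified against finite differences in the
// test suite. Memory is detached: no gradient flows into cached hidden
// states (their layer-norm still contributes to the gain/bias gradients,
// since k/v of memory rows are recomputed with live weights).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;
static const int N_TOKENS = 5;  // A C G T N

struct Cfg {
  int l, k, H, dh, E, cw, hh;
  Cfg(const List& cfg) {
    l  = as<int>(cfg["segment_length"]);
    k  = as<int>(cfg["num_layers"]);
    H  = as<int>(cfg["heads_per_layer"]);
    dh = as<int>(cfg["head_dim"]);
    E  = as<int>(cfg["embed_dim"]);
    cw = as<int>(cfg["conv_width"]);
    hh = as<int>(cfg["head_hidden"]);
    if (H * dh != E) stop("heads_per_layer * head_dim must equal embed_dim");
    if (cw % 2 == 0) stop("conv_width must be odd");
  }
};

// Sequential walker over the flat parameter (or gradient) vector.
struct Walker {
  double* p;
  size_t left;
  Walker(double* ptr, size_t n) : p(ptr), left(n) {}
  mat matBlock(int r, int c) {
    size_t n = (size_t)r * c;
    if (n > left) stop("parameter vector too short");
    mat m(p, r, c, false, true);  // alias, column-major
    p += n; left -= n;
    return m;
  }
  rowvec rowBlock(int n) {
    if ((size_t)n > left) stop("parameter vector too short");
    rowvec v(p, n, false, true);
    p += n; left -= n;
    return v;
  }
};

struct LayerW {
  mat ln_g, ln_b;        // 1 x E each (as mat for convenience)
  mat Wq, Wk, Wv;        // (cw*E) x E
  rowvec bq, bk, bv;     // E
  mat relb;              // l x H, bias over relative offset per head
  mat Wo;                // E x E
  rowvec bo;
};

struct Weights {
  mat embed;             // N_TOKENS x E
  std::vector<LayerW> layers;
  rowvec lnf_g, lnf_b;
  mat W1; rowvec b1;     // E x hh
  mat W2; rowvec b2;     // hh x 2
};

// NOTE: matBlock aliases the input buffer but assignment into Weights
// copies, so bind_weights reads the layout; writing back goes through
// serialize_weights below.
static Weights bind_weights(double* ptr, size_t n, const Cfg& c) {
  Walker w(ptr, n);
  Weights W;
  W.embed = w.matBlock(N_TOKENS, c.E);
  for (int i = 0; i < c.k; ++i) {
    LayerW L;
    L.ln_g = w.matBlock(1, c.E);
    L.ln_b = w.matBlock(1, c.E);
    L.Wq = w.matBlock(c.cw * c.E, c.E); L.bq = w.rowBlock(c.E);
    L.Wk = w.matBlock(c.cw * c.E, c.E); L.bk = w.rowBlock(c.E);
    L.Wv = w.matBlock(c.cw * c.E, c.E); L.bv = w.rowBlock(c.E);
    L.relb = w.matBlock(c.l, c.H);
    L.Wo = w.matBlock(c.E, c.E); L.bo = w.rowBlock(c.E);
    W.layers.push_back(L);
  }
  W.lnf_g = w.rowBlock(c.E); W.lnf_b = w.rowBlock(c.E);
  W.W1 = w.matBlock(c.E, c.hh); W.b1 = w.rowBlock(c.hh);
  W.W2 = w.matBlock(c.hh, 2);  W.b2 = w.rowBlock(2);
  if (w.left != 0) stop("parameter vector too long");
  return W;
}

static void put_block(double*& p, const mat& m) {
  std::memcpy(p, m.memptr(), m.n_elem * sizeof(double));
  p += m.n_elem;
}
static void put_block(double*& p, const rowvec& v) {
  std::memcpy(p, v.memptr(), v.n_elem * sizeof(double));
  p += v.n_elem;
}

// write a Weights struct back into a flat vector, in layout order
static void serialize_weights(const Weights& W, const Cfg& c, double* p) {
  put_block(p, W.embed);
  for (int i = 0; i < c.k; ++i) {
    const LayerW& L = W.layers[i];
    put_block(p, L.ln_g); put_block(p, L.ln_b);
    put_block(p, L.Wq); put_block(p, L.bq);
    put_block(p, L.Wk); put_block(p, L.bk);
    put_block(p, L.Wv); put_block(p, L.bv);
    put_block(p, L.relb);
    put_block(p, L.Wo); put_block(p, L.bo);
  }
  put_block(p, W.lnf_g); put_block(p, W.lnf_b);
  put_block(p, W.W1); put_block(p, W.b1);
  put_block(p, W.W2); put_block(p, W.b2);
}

static size_t param_count(const Cfg& c) {
  size_t n = (size_t)N_TOKENS * c.E;
  n += (size_t)c.k * (2 * c.E + 3 * ((size_t)c.cw * c.E * c.E + c.E) +
                      (size_t)c.l * c.H + (size_t)c.E * c.E + c.E);
  n += 2 * c.E + (size_t)c.E * c.hh + c.hh + 2 * c.hh + 2;
  return n;
}

// [[Rcpp::export(name = ".tx_param_count")]]
double tx_param_count(List cfg) { return (double)param_count(Cfg(cfg)); }

// Named block sizes, in layout order, so R can initialise blockwise.
// [[Rcpp::export(name = ".tx_param_layout")]]
List tx_param_layout(List cfg) {
  Cfg c(cfg);
  std::vector<std::string> nm;
  std::vector<double> sz, fanin;
  nm.push_back("embed"); sz.push_back(N_TOKENS * c.E); fanin.push_back(1);
  for (int i = 0; i < c.k; ++i) {
    std::string p = "layer" + std::to_string(i + 1) + ".";
    nm.push_back(p + "ln_g"); sz.push_back(c.E); fanin.push_back(0);
    nm.push_back(p + "ln_b"); sz.push_back(c.E); fanin.push_back(0);
    const char* qkv[3] = {"Wq", "Wk", "Wv"};
    for (int j = 0; j < 3; ++j) {
      nm.push_back(p + qkv[j]); sz.push_back((double)c.cw * c.E * c.E);
      fanin.push_back(c.cw * c.E);
      nm.push_back(p + "b" + std::string(1, "qkv"[j]));
      sz.push_back(c.E); fanin.push_back(0);
    }
    nm.push_back(p + "relb"); sz.push_back((double)c.l * c.H); fanin.push_back(0);
    nm.push_back(p + "Wo"); sz.push_back((double)c.E * c.E); fanin.push_back(c.E);
    nm.push_back(p + "bo"); sz.push_back(c.E); fanin.push_back(0);
  }
  nm.push_back("lnf_g"); sz.push_back(c.E); fanin.push_back(0);
  nm.push_back("lnf_b"); sz.push_back(c.E); fanin.push_back(0);
  nm.push_back("W1"); sz.push_back((double)c.E * c.hh); fanin.push_back(c.E);
  nm.push_back("b1"); sz.push_back(c.hh); fanin.push_back(0);
  nm.push_back("W2"); sz.push_back((double)c.hh * 2); fanin.push_back(c.hh);
  nm.push_back("b2"); sz.push_back(2); fanin.push_back(0);
  return List::create(_["block"] = nm, _["size"] = sz, _["fan_in"] = fanin);
}

// row-wise layer norm; stores xhat and inv std for backward
static mat layer_norm(const mat& X, const mat& g, const mat& b,
                      mat& xhat, vec& istd) {
  int n = X.n_rows;
  xhat.set_size(n, X.n_cols);
  istd.set_size(n);
  mat out(n, X.n_cols);
  for (int i = 0; i < n; ++i) {
    double mu = arma::mean(X.row(i));
    double va = arma::mean(arma::square(X.row(i) - mu));
    double is = 1.0 / std::sqrt(va + LN_EPS);
    istd(i) = is;
    xhat.row(i) = (X.row(i) - mu) * is;
    out.row(i) = xhat.row(i) % g.row(0) + b.row(0);
  }
  return out;
}

// backward through layer norm for one row block; accumulates dg, db and
// returns dX (ignored by caller for detached memory rows)
static mat layer_norm_bwd(const mat& dY, const mat& xhat, const vec& istd,
                          const mat& g, mat& dg, mat& db) {
  int n = dY.n_rows, E = dY.n_cols;
  mat dX(n, E);
  for (int i = 0; i < n; ++i) {
    rowvec dy = dY.row(i);
    dg.row(0) += dy % xhat.row(i);
    db.row(0) += dy;
    rowvec dxh = dy % g.row(0);
    double m1 = arma::mean(dxh);
    double m2 = arma::mean(dxh % xhat.row(i));
    dX.row(i) = (dxh - m1 - xhat.row(i) * m2) * istd(i);
  }
  return dX;
}

// unfold for convolution: row t of the result is the concatenation of the
// cw rows X[t-c .. t+c] (zero outside range), blocks ordered by tap index
static mat unfold(const mat& X, int cw) {
  int n = X.n_rows, E = X.n_cols, c = cw / 2;
  mat U(n, cw * E, arma::fill::zeros);
  for (int w0 = 0; w0 < cw; ++w0) {
    int shift = w0 - c;            // source row = t + shift
    int t0 = std::max(0, -shift), t1 = std::min(n, n - shift);
    if (t0 < t1)
      U.submat(t0, w0 * E, t1 - 1, (w0 + 1) * E - 1) =
        X.rows(t0 + shift, t1 - 1 + shift);
  }
  return U;
}

static void fold_back(const mat& dU, int cw, mat& dX) {
  int n = dX.n_rows, E = dX.n_cols, c = cw / 2;
  for (int w0 = 0; w0 < cw; ++w0) {
    int shift = w0 - c;
    int t0 = std::max(0, -shift), t1 = std::min(n, n - shift);
    if (t0 < t1)
      dX.rows(t0 + shift, t1 - 1 + shift) +=
        dU.submat(t0, w0 * E, t1 - 1, (w0 + 1) * E - 1);
  }
}

struct LayerCache {
  mat h_in;                 // Lc x E (input hidden states, current rows)
  mat xhat; vec istd;       // LN cache over all (M+Lc) rows
  mat U;                    // unfolded LN output
  mat Q, K, V;              // Q: Lc x E; K,V: (M+Lc) x E
  std::vector<mat> S;       // per head: Lc x (M+Lc) softmax scores (masked=0)
  mat Z;                    // Lc x E concat head outputs
  int M;
};

struct FinalCache {
  mat h_k, xhat; vec istd;
  mat Y, O1, P;             // P: Lc x 2 class probabilities
};

// forward pass over one segment; attn (if non-null) gets per layer/head
// score rows remapped to offset index (l-1-offset) for each query
static void forward_segment(const Weights& W, const Cfg& c,
                            const arma::ivec& tokens,
                            const std::vector<mat>& mem,
                            std::vector<LayerCache>& LC, FinalCache& FC,
                            std::vector<mat>& new_mem,
                            arma::cube* attn) {
  int Lc = tokens.n_elem;
  if (Lc > c.l) stop("segment longer than segment_length");
  mat h(Lc, c.E);
  for (int t = 0; t < Lc; ++t) {
    int tok = tokens(t);
    if (tok < 0 || tok >= N_TOKENS) stop("invalid token");
    h.row(t) = W.embed.row(tok);
  }
  LC.resize(c.k);
  new_mem.resize(c.k);
  double scale = 1.0 / std::sqrt((double)c.dh);
  for (int i = 0; i < c.k; ++i) {
    LayerCache& L = LC[i];
    const LayerW& lw = W.layers[i];
    int M = (i < (int)mem.size() && mem[i].n_rows > 0) ? mem[i].n_rows : 0;
    L.M = M;
    L.h_in = h;
    new_mem[i] = h;  // cache BEFORE the block transforms it (h^(i))
    mat X;
    if (M > 0) X = arma::join_cols(mem[i], h); else X = h;
    mat Xn = layer_norm(X, lw.ln_g, lw.ln_b, L.xhat, L.istd);
    L.U = unfold(Xn, c.cw);
    // queries only need current rows
    L.Q = L.U.rows(M, M + Lc - 1) * lw.Wq;
    L.Q.each_row() += lw.bq;
    L.K = L.U * lw.Wk; L.K.each_row() += lw.bk;
    L.V = L.U * lw.Wv; L.V.each_row() += lw.bv;
    L.S.resize(c.H);
    L.Z.set_size(Lc, c.E);
    for (int hd = 0; hd < c.H; ++hd) {
      int c0 = hd * c.dh, c1 = (hd + 1) * c.dh - 1;
      mat Qh = L.Q.cols(c0, c1);
      mat Kh = L.K.cols(c0, c1);
      mat Vh = L.V.cols(c0, c1);
      mat S = Qh * Kh.t() * scale;       // Lc x (M+Lc)
      // mask + relative bias, then softmax per row
      for (int t = 0; t < Lc; ++t) {
        int gq = M + t;
        int j0 = std::max(0, gq - c.l + 1);
        double mx = -arma::datum::inf;
        for (int j = j0; j <= gq; ++j) {
          S(t, j) += lw.relb(gq - j, hd);
          if (S(t, j) > mx) mx = S(t, j);
        }
        double Zs = 0;
        for (int j = 0; j < (int)S.n_cols; ++j) {
          if (j < j0 || j > gq) { S(t, j) = 0; continue; }
          S(t, j) = std::exp(S(t, j) - mx);
          Zs += S(t, j);
        }
        for (int j = j0; j <= gq; ++j) S(t, j) /= Zs;
      }
      L.S[hd] = S;
      L.Z.cols(c0, c1) = S * Vh;
      if (attn) {
        for (int t = 0; t < Lc; ++t) {
          int gq = M + t;
          int j0 = std::max(0, gq - c.l + 1);
          for (int j = j0; j <= gq; ++j)
            (*attn)(t, c.l - 1 - (gq - j), i * c.H + hd) = S(t, j);
        }
      }
    }
    mat A = L.Z * lw.Wo;
    A.each_row() += lw.bo;
    h = L.h_in + A;
  }
  FC.h_k = h;
  mat g(1, c.E), b(1, c.E);
  g.row(0) = W.lnf_g; b.row(0) = W.lnf_b;
  FC.Y = layer_norm(h, g, b, FC.xhat, FC.istd);
  FC.O1 = FC.Y * W.W1;
  FC.O1.each_row() += W.b1;
  FC.O1 = arma::clamp(FC.O1, 0.0, arma::datum::inf);  // ReLU
  mat logits = FC.O1 * W.W2;
  logits.each_row() += W.b2;
  FC.P.set_size(Lc, 2);
  for (int t = 0; t < Lc; ++t) {
    double mx = std::max(logits(t, 0), logits(t, 1));
    double e0 = std::exp(logits(t, 0) - mx), e1 = std::exp(logits(t, 1) - mx);
    FC.P(t, 0) = e0 / (e0 + e1);
    FC.P(t, 1) = e1 / (e0 + e1);
  }
}

static std::vector<mat> mem_from_list(List mem_list) {
  std::vector<mat> mem;
  for (int i = 0; i < mem_list.size(); ++i)
    mem.push_back(as<mat>(mem_list[i]));
  return mem;
}

static List mem_to_list(const std::vector<mat>& mem) {
  List out(mem.size());
  for (size_t i = 0; i < mem.size(); ++i) out[i] = mem[i];
  return out;
}

// One attention-head application on explicit q/K/V: scores =
// softmax(q.K' / sqrt(d_head) + bias) over the supplied (unmasked) rows,
// z = scores . V. The same arithmetic the full forward uses, exposed for
// direct verification against naive implementations.
// [[Rcpp::export(name = ".tx_attention_head")]]
List tx_attention_head(arma::rowvec q, arma::mat K, arma::mat V,
                       double d_head, arma::vec bias) {
  if (K.n_rows != V.n_rows) stop("K and V must have the same number of rows");
  if (K.n_rows == 0) stop("empty attendable set");
  if (bias.n_elem != K.n_rows) stop("bias length must match rows of K");
  vec s = (K * q.t()) / std::sqrt(d_head) + bias;
  s -= s.max();
  s = arma::exp(s);
  s /= arma::accu(s);
  rowvec z = s.t() * V;
  return List::create(_["scores"] = NumericVector(s.begin(), s.end()),
                      _["z"] = NumericVector(z.begin(), z.end()));
}

// Inference over one segment. Returns the positive-class probability per
// position, the new memory, and (optionally) every attention record:
// a (Lc, l, k*H) array indexed [query, l-1-offset, layer*H + head].
// [[Rcpp::export(name = ".tx_segment_forward")]]
List tx_segment_forward(NumericVector params, List cfg, IntegerVector tokens,
                        List mem_list, bool record_attention = false) {
  Cfg c(cfg);
  if ((size_t)params.size() != param_count(c))
    stop("parameter vector has wrong length");
  Weights W = bind_weights(params.begin(), params.size(), c);
  arma::ivec tok(tokens.size());
  for (int i = 0; i < tokens.size(); ++i) tok(i) = tokens[i];
  std::vector<mat> mem = mem_from_list(mem_list);
  std::vector<LayerCache> LC; FinalCache FC;
  std::vector<mat> new_mem;
  arma::cube attn;
  if (record_attention)
    attn.zeros(tok.n_elem, c.l, c.k * c.H);
  forward_segment(W, c, tok, mem, LC, FC, new_mem,
                  record_attention ? &attn : nullptr);
  List out = List::create(
    _["prob"] = NumericVector(FC.P.colptr(1), FC.P.colptr(1) + FC.P.n_rows),
    _["new_mem"] = mem_to_list(new_mem));
  if (record_attention) out["attention"] = wrap(attn);
  return out;
}

// One training step's forward + backward over a segment. labels: 0/1 per
// position, -1 = excluded from the loss (outside the training split).
// Returns mean cross-entropy over included positions and the gradient.
// [[Rcpp::export(name = ".tx_segment_grad")]]
List tx_segment_grad(NumericVector params, List cfg, IntegerVector tokens,
                     IntegerVector labels, List mem_list) {
  Cfg c(cfg);
  if ((size_t)params.size() != param_count(c))
    stop("parameter vector has wrong length");
  if (labels.size() != tokens.size())
    stop("labels and tokens differ in length");
  Weights W = bind_weights(params.begin(), params.size(), c);
  arma::ivec tok(tokens.size());
  for (int i = 0; i < tokens.size(); ++i) tok(i) = tokens[i];
  std::vector<mat> mem = mem_from_list(mem_list);
  std::vector<LayerCache> LC; FinalCache FC;
  std::vector<mat> new_mem;
  forward_segment(W, c, tok, mem, LC, FC, new_mem, nullptr);

  int Lc = tok.n_elem;
  int n_loss = 0;
  double loss = 0;
  for (int t = 0; t < Lc; ++t)
    if (labels[t] >= 0) {
      ++n_loss;
      loss -= std::log(std::max(FC.P(t, labels[t]), 1e-300));
    }
  NumericVector gradv(params.size());
  List out = List::create(_["loss"] = n_loss ? loss / n_loss : NA_REAL,
                          _["n_loss"] = n_loss,
                          _["grad"] = gradv,
                          _["new_mem"] = mem_to_list(new_mem),
                          _["prob"] = NumericVector(FC.P.colptr(1),
                                                    FC.P.colptr(1) + Lc));
  if (n_loss == 0) return out;
  loss /= n_loss;
  std::vector<double> zbuf(params.size(), 0.0);
  Weights G = bind_weights(zbuf.data(), zbuf.size(), c);  // zero-shaped copy

  // output head backward
  mat dlogits(Lc, 2, arma::fill::zeros);
  for (int t = 0; t < Lc; ++t)
    if (labels[t] >= 0) {
      dlogits(t, 0) = (FC.P(t, 0) - (labels[t] == 0 ? 1.0 : 0.0)) / n_loss;
      dlogits(t, 1) = (FC.P(t, 1) - (labels[t] == 1 ? 1.0 : 0.0)) / n_loss;
    }
  G.W2 += FC.O1.t() * dlogits;
  G.b2 += arma::sum(dlogits, 0);
  mat dO1 = dlogits * W.W2.t();
  dO1 %= arma::conv_to<mat>::from(FC.O1 > 0);
  G.W1 += FC.Y.t() * dO1;
  G.b1 += arma::sum(dO1, 0);
  mat dY = dO1 * W.W1.t();
  mat gf(1, c.E), dgf(1, c.E, arma::fill::zeros), dbf(1, c.E, arma::fill::zeros);
  gf.row(0) = W.lnf_g;
  mat dh = layer_norm_bwd(dY, FC.xhat, FC.istd, gf, dgf, dbf);
  G.lnf_g += dgf.row(0); G.lnf_b += dbf.row(0);

  double scale = 1.0 / std::sqrt((double)c.dh);
  for (int i = c.k - 1; i >= 0; --i) {
    LayerCache& L = LC[i];
    const LayerW& lw = W.layers[i];
    LayerW& gl = G.layers[i];
    int M = L.M, nrows = M + Lc;
    // h_out = h_in + Z*Wo + bo
    mat dA = dh;                      // Lc x E
    gl.Wo += L.Z.t() * dA;
    gl.bo += arma::sum(dA, 0);
    mat dZ = dA * lw.Wo.t();
    mat dQ(Lc, c.E, arma::fill::zeros);
    mat dK(nrows, c.E, arma::fill::zeros);
    mat dV(nrows, c.E, arma::fill::zeros);
    for (int hd = 0; hd < c.H; ++hd) {
      int c0 = hd * c.dh, c1 = (hd + 1) * c.dh - 1;
      const mat& S = L.S[hd];
      mat dZh = dZ.cols(c0, c1);
      mat Vh = L.V.cols(c0, c1);
      mat dS = dZh * Vh.t();          // Lc x nrows
      dV.cols(c0, c1) += S.t() * dZh;
      // softmax backward (masked entries have S == 0)
      vec rs = arma::sum(dS % S, 1);
      mat dsr = S % (dS.each_col() - rs);
      // relative-position bias gradient
      for (int t = 0; t < Lc; ++t) {
        int gq = M + t;
        int j0 = std::max(0, gq - c.l + 1);
        for (int j = j0; j <= gq; ++j)
          gl.relb(gq - j, hd) += dsr(t, j);
      }
      mat Kh = L.K.cols(c0, c1);
      mat Qh = L.Q.cols(c0, c1);
      dQ.cols(c0, c1) += dsr * Kh * scale;
      dK.cols(c0, c1) += dsr.t() * Qh * scale;
    }
    // conv banks
    mat dU(nrows, c.cw * c.E, arma::fill::zeros);
    mat Ucur = L.U.rows(M, nrows - 1);
    gl.Wq += Ucur.t() * dQ;
    gl.bq += arma::sum(dQ, 0);
    dU.rows(M, nrows - 1) += dQ * lw.Wq.t();
    gl.Wk += L.U.t() * dK;
    gl.bk += arma::sum(dK, 0);
    dU += dK * lw.Wk.t();
    gl.Wv += L.U.t() * dV;
    gl.bv += arma::sum(dV, 0);
    dU += dV * lw.Wv.t();
    mat dXn(nrows, c.E, arma::fill::zeros);
    fold_back(dU, c.cw, dXn);
    mat dg(1, c.E, arma::fill::zeros), db(1, c.E, arma::fill::zeros);
    mat dX = layer_norm_bwd(dXn, L.xhat, L.istd, lw.ln_g, dg, db);
    gl.ln_g += dg; gl.ln_b += db;
    // memory rows are detached: their dX is dropped
    dh += dX.rows(M, nrows - 1);      // residual path + block path
  }
  // embedding gradient
  for (int t = 0; t < Lc; ++t) G.embed.row(tok(t)) += dh.row(t);
  serialize_weights(G, c, gradv.begin());
  out["loss"] = loss;
  return out;
}
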