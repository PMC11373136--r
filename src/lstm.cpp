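// Small stacked-LSTM binary classifier trained by backpropagation through
// time with Adam and binary cross-entropy. Input is a (samples x channels x
// timesteps) cube: the fixed-length feature vector folded into a short
// sequence. Dropout (inverted) is applied to each LSTM layer's output
// during training. All randomness comes from one std::mt19937 seed, so fits
// are bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LstmLayer {
  mat W;   // (in + units) x 4*units, gate order i|f|g|o
  rowvec b;
  int in, units;
};

struct Adam {
  mat mW, vW;
  rowvec mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const LstmLayer& L) {
    mW.zeros(size(L.W)); vW.zeros(size(L.W));
    mb.zeros(size(L.b)); vb.zeros(size(L.b));
  }
  void step(LstmLayer& L, const mat& gW, const rowvec& gb, double lr, long tt) {
    mW = b1 * mW + (1 - b1) * gW;  vW = b2 * vW + (1 - b2) * square(gW);
    mb = b1 * mb + (1 - b1) * gb;  vb = b2 * vb + (1 - b2) * square(gb);
    double c1 = 1 - std::pow(b1, (double)tt), c2 = 1 - std::pow(b2, (double)tt);
    L.W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
    L.b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
  }
};

// forward pass through one LSTM layer over all timesteps; caches gate
// activations for BPTT when train=true
struct LayerCache {
  cube i, f, g, o, c, tc, h;  // each B x units x T
  cube xin;                   // B x in x T
};

static void lstm_forward(const LstmLayer& L, const cube& X, LayerCache& C,
                         bool cache) {
  int B = X.n_rows, T = X.n_slices, H = L.units;
  if (cache) {
    C.i.set_size(B, H, T); C.f.set_size(B, H, T); C.g.set_size(B, H, T);
    C.o.set_size(B, H, T); C.c.set_size(B, H, T); C.tc.set_size(B, H, T);
    C.xin = X;
  }
  C.h.set_size(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat zin = join_rows(X.slice(t), h);
    mat z = zin * L.W;
    z.each_row() += L.b;
    mat gi = sigm(z.cols(0, H - 1));
    mat gf = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = sigm(z.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    if (cache) {
      C.i.slice(t) = gi; C.f.slice(t) = gf; C.g.slice(t) = gg;
      C.o.slice(t) = go; C.c.slice(t) = c; C.tc.slice(t) = tc;
    }
    C.h.slice(t) = h;
  }
}

// BPTT through one layer. dH: gradient w.r.t. the layer's output sequence
// (B x units x T). Returns gradient w.r.t. the input sequence; accumulates
// weight gradients into gW/gb.
static cube lstm_backward(const LstmLayer& L, const LayerCache& C,
                          const cube& dH, mat& gW, rowvec& gb) {
  int B = dH.n_rows, T = dH.n_slices, H = L.units, in = L.in;
  gW.zeros(in + H, 4 * H);
  gb.zeros(4 * H);
  cube dX(B, in, T, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  mat Wx = L.W.rows(0, in - 1);
  mat Wh = L.W.rows(in, in + H - 1);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dH.slice(t) + dh_next;
    mat go = C.o.slice(t), tc = C.tc.slice(t);
    mat dct = dc_next + dh % go % (1 - square(tc));
    mat gi = C.i.slice(t), gf = C.f.slice(t), gg = C.g.slice(t);
    mat c_prev = (t > 0) ? C.c.slice(t - 1) : mat(B, H, fill::zeros);
    mat dzi = (dct % gg) % gi % (1 - gi);
    mat dzf = (dct % c_prev) % gf % (1 - gf);
    mat dzg = (dct % gi) % (1 - square(gg));
    mat dzo = (dh % tc) % go % (1 - go);
    mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    mat h_prev = (t > 0) ? C.h.slice(t - 1) : mat(B, H, fill::zeros);
    mat zin = join_rows(C.xin.slice(t), h_prev);
    gW += zin.t() * dz;
    gb += sum(dz, 0);
    dX.slice(t) = dz * Wx.t();
    dh_next = dz * Wh.t();
    dc_next = dct % gf;
  }
  return dX;
}

static LstmLayer make_layer(int in, int units, std::mt19937& rng) {
  LstmLayer L;
  L.in = in; L.units = units;
  double r = std::sqrt(6.0 / (in + units + 4.0 * units));
  std::uniform_real_distribution<double> U(-r, r);
  L.W.set_size(in + units, 4 * units);
  for (uword k = 0; k < L.W.n_elem; ++k) L.W(k) = U(rng);
  L.b.zeros(4 * units);
  L.b.cols(units, 2 * units - 1).fill(1.0);  // forget-gate bias 1
  return L;
}

// [[Rcpp::export]]
Rcpp::List lstm_fit_cpp(const arma::cube& X, const arma::vec& y, int units,
                        int layers, double dropout, double lr, int epochs,
                        int batch_size, int seed) {
  int n = X.n_rows, C = X.n_cols, T = X.n_slices;
  std::mt19937 rng((unsigned)seed);
  std::vector<LstmLayer> L(layers);
  std::vector<Adam> opt(layers);
  for (int l = 0; l < layers; ++l) {
    L[l] = make_layer(l == 0 ? C : units, units, rng);
    opt[l].init(L[l]);
  }
  // dense output layer
  double r = std::sqrt(6.0 / (units + 1.0));
  std::uniform_real_distribution<double> U(-r, r);
  vec wout(units);
  for (int k = 0; k < units; ++k) wout(k) = U(rng);
  double bout = 0;
  vec m_wout(units, fill::zeros), v_wout(units, fill::zeros);
  double m_bout = 0, v_bout = 0;

  std::vector<int> order(n);
  for (int k = 0; k < n; ++k) order[k] = k;
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  vec loss_log(epochs, fill::zeros);
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      int B = stop - start;
      uvec idx(B);
      for (int k = 0; k < B; ++k) idx(k) = order[start + k];
      cube Xb(B, C, T);
      for (int t = 0; t < T; ++t) Xb.slice(t) = X.slice(t).rows(idx);
      vec yb = y.elem(idx);

      // forward
      std::vector<LayerCache> cache(layers);
      std::vector<cube> masks(layers);
      cube cur = Xb;
      for (int l = 0; l < layers; ++l) {
        lstm_forward(L[l], cur, cache[l], true);
        cur = cache[l].h;
        if (dropout > 0) {                    // inverted dropout on outputs
          masks[l].set_size(size(cur));
          for (uword k = 0; k < masks[l].n_elem; ++k)
            masks[l](k) = (U01(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
          cur %= masks[l];
        }
      }
      mat h_last = cur.slice(T - 1);
      vec p = 1.0 / (1.0 + exp(-(h_last * wout + bout)));
      p = clamp(p, 1e-12, 1 - 1e-12);
      ep_loss += -mean(yb % log(p) + (1 - yb) % log(1 - p));
      n_batches++;

      // backward
      vec d = (p - yb) / (double)B;
      vec g_wout = h_last.t() * d;
      double g_bout = accu(d);
      cube dH(B, units, T, fill::zeros);
      dH.slice(T - 1) = d * wout.t();
      step++;
      for (int l = layers - 1; l >= 0; --l) {
        if (dropout > 0) dH %= masks[l];
        mat gW; rowvec gb;
        cube dX = lstm_backward(L[l], cache[l], dH, gW, gb);
        // clip per-layer gradient norm at 5
        double nrm = std::sqrt(accu(square(gW)) + accu(square(gb)));
        if (nrm > 5.0) { gW *= 5.0 / nrm; gb *= 5.0 / nrm; }
        opt[l].step(L[l], gW, gb, lr, step);
        if (l > 0) dH = dX;
      }
      // dense Adam update
      m_wout = 0.9 * m_wout + 0.1 * g_wout;
      v_wout = 0.999 * v_wout + 0.001 * square(g_wout);
      m_bout = 0.9 * m_bout + 0.1 * g_bout;
      v_bout = 0.999 * v_bout + 0.001 * g_bout * g_bout;
      double c1 = 1 - std::pow(0.9, (double)step), c2 = 1 - std::pow(0.999, (double)step);
      wout -= lr * (m_wout / c1) / (sqrt(v_wout / c2) + 1e-8);
      bout -= lr * (m_bout / c1) / (std::sqrt(v_bout / c2) + 1e-8);
    }
    loss_log(ep) = ep_loss / n_batches;
  }

  Rcpp::List Ws(layers), bs(layers);
  for (int l = 0; l < layers; ++l) {
    Ws[l] = Rcpp::wrap(L[l].W);
    bs[l] = Rcpp::wrap(mat(L[l].b));
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs,
    Rcpp::Named("wout") = wout, Rcpp::Named("bout") = bout,
    Rcpp::Named("units") = units, Rcpp::Named("layers") = layers,
    Rcpp::Named("loss") = loss_log);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(const Rcpp::List& model, const arma::cube& X) {
  int layers = Rcpp::as<int>(model["layers"]);
  int units = Rcpp::as<int>(model["units"]);
  Rcpp::List Ws = model["W"], bs = model["b"];
  int T = X.n_slices;
  cube cur = X;
  for (int l = 0; l < layers; ++l) {
    LstmLayer L;
    L.W = Rcpp::as<mat>(Ws[l]);
    mat bm = Rcpp::as<mat>(bs[l]);
    L.b = bm.row(0);
    L.units = units;
    L.in = L.W.n_rows - units;
    LayerCache Ccache;
    lstm_forward(L, cur, Ccache, false);
    cur = Ccache.h;
  }
  vec wout = Rcpp::as<vec>(model["wout"]);
  double bout = Rcpp::as<double>(model["bout"]);
  return 1.0 / (1.0 + exp(-(cur.slice(T - 1) * wout + bout)));
}
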