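// Multitask 1D-CNN backend: promoter one-hot sequence + half-life covariates
// -> per-population standardized expression. Single precision throughout;
// all randomness (init, shuffling, dropout) is driven by explicit seeds so
// training is bit-reproducible on one machine for a fixed thread count.
// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;
using arma::uword;

namespace {

struct NetConfig {
  int L, T;
  int F1, K1, P1;
  int F2, K2, P2;
  int L1, M1, L2, M2, flat, nin;
  int hidden;
  float dropout;
};

NetConfig parse_config(const List& cfg) {
  NetConfig c;
  c.L = as<int>(cfg["L"]);
  c.T = as<int>(cfg["n_tasks"]);
  IntegerVector fl = cfg["conv_filters"], wd = cfg["conv_widths"], pl = cfg["pool_widths"];
  if (fl.size() != 2 || wd.size() != 2 || pl.size() != 2)
    stop("exactly two convolutional blocks are supported");
  c.F1 = fl[0]; c.K1 = wd[0]; c.P1 = pl[0];
  c.F2 = fl[1]; c.K2 = wd[1]; c.P2 = pl[1];
  IntegerVector hid = cfg["fc_hidden"];
  c.hidden = hid.size() > 0 ? hid[0] : 0;
  c.dropout = as<double>(cfg["dropout"]);
  c.L1 = c.L - c.K1 + 1;
  c.M1 = c.L1 / c.P1;
  c.L2 = c.M1 - c.K2 + 1;
  c.M2 = c.L2 / c.P2;
  c.flat = c.F2 * c.M2;
  c.nin = c.flat + 5;
  if (c.L1 < 1 || c.M1 < 1 || c.L2 < 1 || c.M2 < 1)
    stop("window length %d incompatible with conv/pool widths (flattened size 0)", c.L);
  return c;
}

struct Params {
  std::vector<fmat> w;  // W1 b1 W2 b2 [Wh bh] Wo bo (biases as 1-col fmat)
  int nlayers(bool hidden) const { return hidden ? 8 : 6; }
};

Params weights_from_list(const List& wl, const NetConfig& c) {
  Params p;
  CharacterVector nm = wl.names();
  for (int i = 0; i < wl.size(); i++) {
    NumericMatrix m = wl[i];
    fmat fm(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); j++)
      for (int k = 0; k < m.nrow(); k++) fm(k, j) = (float)m(k, j);
    p.w.push_back(fm);
  }
  if ((int)p.w.size() != (c.hidden > 0 ? 8 : 6)) stop("weight list does not match config");
  return p;
}

List weights_to_list(const Params& p, const NetConfig& c) {
  List out;
  CharacterVector nm;
  const char* names6[] = {"W1", "b1", "W2", "b2", "Wo", "bo"};
  const char* names8[] = {"W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo"};
  const char** names = c.hidden > 0 ? names8 : names6;
  for (size_t i = 0; i < p.w.size(); i++) {
    NumericMatrix m(p.w[i].n_rows, p.w[i].n_cols);
    for (uword j = 0; j < p.w[i].n_cols; j++)
      for (uword k = 0; k < p.w[i].n_rows; k++) m(k, j) = p.w[i](k, j);
    out.push_back(m, names[i]);
  }
  return out;
}

// One-hot a single integer-coded sequence (codes 1..ncode, column-major 4 x L)
inline void onehot_sample(const int* codes, int L, const fmat& table, float* out) {
  const int ncode = table.n_cols;
  for (int j = 0; j < L; j++) {
    int cd = codes[j];
    if (cd < 1 || cd > ncode) ::Rf_error("invalid sequence code %d at position %d", cd, j + 1);
    const float* col = table.colptr(cd - 1);
    float* o = out + 4 * j;
    o[0] = col[0]; o[1] = col[1]; o[2] = col[2]; o[3] = col[3];
  }
}

// Non-overlapping max-pool over per-sample column blocks, recording the
// argmax column for the backward scatter.
inline void maxpool(const fmat& Y, int F, int Lc, int P, int M, int B,
                    fmat& out, umat& amax) {
  out.set_size(F, (uword)M * B);
  amax.set_size(F, (uword)M * B);
  for (int s = 0; s < B; s++) {
    for (int m = 0; m < M; m++) {
      const uword oc = (uword)s * M + m;
      const uword base = (uword)s * Lc + (uword)m * P;
      const float* col0 = Y.colptr(base);
      float* o = out.colptr(oc);
      uword* a = amax.colptr(oc);
      for (int f = 0; f < F; f++) { o[f] = col0[f]; a[f] = base; }
      for (int q = 1; q < P; q++) {
        const float* cq = Y.colptr(base + q);
        for (int f = 0; f < F; f++) {
          if (cq[f] > o[f]) { o[f] = cq[f]; a[f] = base + q; }
        }
      }
      // ReLU fused into pooling: max(relu(x)) == relu(max(x)); when the
      // whole window is negative the pooled unit is 0 and its gradient is
      // gated on P*m > 0, so the argmax is irrelevant there.
      for (int f = 0; f < F; f++) {
        if (o[f] < 0.f) o[f] = 0.f;
      }
    }
  }
}

// zero entries of g where the (post-ReLU) activation is zero
inline void relu_mask(fmat& g, const fmat& act) {
  const float* a = act.memptr();
  float* p = g.memptr();
  const uword n = g.n_elem;
  for (uword i = 0; i < n; i++) {
    if (a[i] <= 0.f) p[i] = 0.f;
  }
}

// Scratch buffers for one forward/backward pass over a batch
struct Batch {
  fmat C1, Y1, P1m, C2, Y2, P2m, H, A, O, mask;
  umat amax1, amax2;
};

// Forward pass. codes: L x N ints (column = one gene); idx: batch members.
void forward(const Params& p, const NetConfig& c, const arma::imat& codes,
             const fmat& table, const fmat& hl, const arma::uvec& idx,
             Batch& b, bool training, std::mt19937* rng) {
  const int B = idx.n_elem;
  b.C1.set_size(4 * c.K1, (uword)c.L1 * B);
  fmat X(4, c.L);
  std::vector<int> buf(c.L);
  for (int s = 0; s < B; s++) {
    for (int j = 0; j < c.L; j++) buf[j] = (int)codes(j, idx[s]);
    onehot_sample(buf.data(), c.L, table, X.memptr());
    float* dst = b.C1.colptr((uword)s * c.L1);
    for (int j = 0; j < c.L1; j++)
      std::memcpy(dst + (size_t)4 * c.K1 * j, X.colptr(j), sizeof(float) * 4 * c.K1);
  }
  b.Y1 = p.w[0] * b.C1;
  b.Y1.each_col() += p.w[1].col(0);

  // max-pool 1 (non-overlapping, remainder dropped), ReLU fused
  maxpool(b.Y1, c.F1, c.L1, c.P1, c.M1, B, b.P1m, b.amax1);

  b.C2.set_size((uword)c.F1 * c.K2, (uword)c.L2 * B);
  for (int s = 0; s < B; s++)
    for (int j = 0; j < c.L2; j++)
      std::memcpy(b.C2.colptr((uword)s * c.L2 + j),
                  b.P1m.colptr((uword)s * c.M1 + j), sizeof(float) * c.F1 * c.K2);
  b.Y2 = p.w[2] * b.C2;
  b.Y2.each_col() += p.w[3].col(0);

  maxpool(b.Y2, c.F2, c.L2, c.P2, c.M2, B, b.P2m, b.amax2);

  b.H.set_size(c.nin, B);
  for (int s = 0; s < B; s++) {
    std::memcpy(b.H.colptr(s), b.P2m.colptr((uword)s * c.M2), sizeof(float) * c.flat);
    for (int q = 0; q < 5; q++) b.H(c.flat + q, s) = hl(idx[s], q);
  }

  if (training && c.dropout > 0.f) {
    b.mask.set_size(c.nin, B);
    std::uniform_real_distribution<float> U(0.f, 1.f);
    const float keep = 1.f - c.dropout, inv = 1.f / keep;
    for (uword i = 0; i < b.mask.n_elem; i++) b.mask(i) = U(*rng) < keep ? inv : 0.f;
    b.H %= b.mask;
  }

  int iw = 4;
  if (c.hidden > 0) {
    b.A = p.w[4] * b.H;
    b.A.each_col() += p.w[5].col(0);
    b.A.transform([](float v) { return v > 0.f ? v : 0.f; });
    iw = 6;
    b.O = p.w[iw] * b.A;
  } else {
    b.O = p.w[iw] * b.H;
  }
  b.O.each_col() += p.w[iw + 1].col(0);
}

// Backward pass for MSE; fills grads (same shapes as params).
void backward(const Params& p, const NetConfig& c, const fmat& Yt,
              Batch& b, std::vector<fmat>& g) {
  const int B = b.O.n_cols;
  fmat dO = (2.0f / (float)(c.T * B)) * (b.O - Yt);
  fmat dH;
  if (c.hidden > 0) {
    g[6] = dO * b.A.t();
    g[7] = fmat(arma::sum(dO, 1));
    fmat dA = p.w[6].t() * dO;
    relu_mask(dA, b.A);
    g[4] = dA * b.H.t();
    g[5] = fmat(arma::sum(dA, 1));
    dH = p.w[4].t() * dA;
  } else {
    g[4] = dO * b.H.t();
    g[5] = fmat(arma::sum(dO, 1));
    dH = p.w[4].t() * dO;
  }
  if (b.mask.n_elem > 0) dH %= b.mask;

  fmat dP2m(c.F2, (uword)c.M2 * B);
  for (int s = 0; s < B; s++)
    std::memcpy(dP2m.colptr((uword)s * c.M2), dH.colptr(s), sizeof(float) * c.flat);

  // Conv gradients exploit pooling sparsity: only the argmax column of each
  // pool window carries gradient (gated by the pooled activation being
  // positive, i.e. the ReLU), so dW accumulates rank-1 pieces instead of a
  // dense (filters x positions) GEMM.
  fmat dW2t(c.F1 * c.K2, c.F2, arma::fill::zeros);
  fvec db2(c.F2, arma::fill::zeros);
  fmat W2t = p.w[2].t();  // (F1*K2) x F2
  fmat dC2((uword)c.F1 * c.K2, (uword)c.L2 * B, arma::fill::zeros);
  const int n2 = c.F1 * c.K2;
  for (uword ocol = 0; ocol < dP2m.n_cols; ocol++) {
    const float* src = dP2m.colptr(ocol);
    const float* pooled = b.P2m.colptr(ocol);
    const uword* a = b.amax2.colptr(ocol);
    for (int f = 0; f < c.F2; f++) {
      const float v = src[f];
      if (v == 0.f || pooled[f] <= 0.f) continue;
      db2[f] += v;
      const float* xc = b.C2.colptr(a[f]);
      float* wc = dW2t.colptr(f);
      const float* wt = W2t.colptr(f);
      float* cc = dC2.colptr(a[f]);
      for (int q = 0; q < n2; q++) {
        wc[q] += v * xc[q];
        cc[q] += v * wt[q];
      }
    }
  }
  g[2] = dW2t.t();
  g[3] = fmat(db2);

  fmat dP1m(c.F1, (uword)c.M1 * B, arma::fill::zeros);
  for (int s = 0; s < B; s++)
    for (int j = 0; j < c.L2; j++) {
      const float* src = dC2.colptr((uword)s * c.L2 + j);
      float* dst = dP1m.colptr((uword)s * c.M1 + j);
      for (int q = 0; q < n2; q++) dst[q] += src[q];
    }

  fmat dW1t(4 * c.K1, c.F1, arma::fill::zeros);
  fvec db1(c.F1, arma::fill::zeros);
  const int n1 = 4 * c.K1;
  for (uword ocol = 0; ocol < dP1m.n_cols; ocol++) {
    const float* src = dP1m.colptr(ocol);
    const float* pooled = b.P1m.colptr(ocol);
    const uword* a = b.amax1.colptr(ocol);
    for (int f = 0; f < c.F1; f++) {
      const float v = src[f];
      if (v == 0.f || pooled[f] <= 0.f) continue;
      db1[f] += v;
      const float* xc = b.C1.colptr(a[f]);
      float* wc = dW1t.colptr(f);
      for (int q = 0; q < n1; q++) wc[q] += v * xc[q];
    }
  }
  g[0] = dW1t.t();
  g[1] = fmat(db1);
}

fmat targets_for(const NumericMatrix& Y, const arma::uvec& idx) {
  fmat t(Y.ncol(), idx.n_elem);
  for (uword s = 0; s < idx.n_elem; s++)
    for (int k = 0; k < Y.ncol(); k++) t(k, s) = (float)Y(idx[s], k);
  return t;
}

double eval_mse(const Params& p, const NetConfig& c, const arma::imat& codes,
                const fmat& table, const fmat& hl, const NumericMatrix& Y,
                const arma::uvec& idx, int batch) {
  Batch b;
  double sse = 0.0;
  for (uword s0 = 0; s0 < idx.n_elem; s0 += batch) {
    uword s1 = std::min<uword>(s0 + batch, idx.n_elem) - 1;
    arma::uvec sub = idx.subvec(s0, s1);
    forward(p, c, codes, table, hl, sub, b, false, nullptr);
    fmat Yt = targets_for(Y, sub);
    sse += arma::accu(arma::square(b.O - Yt));
  }
  return sse / ((double)idx.n_elem * c.T);
}

}  // namespace

// [[Rcpp::export]]
List cpp_init_weights(List cfg, int seed, double head_sd = 0.0) {
  NetConfig c = parse_config(cfg);
  std::mt19937 rng((uint32_t)seed);
  std::normal_distribution<float> N(0.f, 1.f);
  Params p;
  auto he = [&](int rows, int cols, int fan_in) {
    fmat m(rows, cols);
    float sd = std::sqrt(2.f / (float)fan_in);
    for (uword j = 0; j < m.n_cols; j++)
      for (uword i = 0; i < m.n_rows; i++) m(i, j) = sd * N(rng);
    return m;
  };
  p.w.push_back(he(c.F1, 4 * c.K1, 4 * c.K1));
  p.w.push_back(fmat(c.F1, 1, arma::fill::zeros));
  p.w.push_back(he(c.F2, c.F1 * c.K2, c.F1 * c.K2));
  p.w.push_back(fmat(c.F2, 1, arma::fill::zeros));
  if (c.hidden > 0) {
    p.w.push_back(he(c.hidden, c.nin, c.nin));
    p.w.push_back(fmat(c.hidden, 1, arma::fill::zeros));
  }
  // Zero-initialized regression head (default): initial predictions sit at
  // 0 (the standardized target mean), so the first epochs fit the head
  // instead of unwinding an arbitrarily scaled output, which at small n can
  // stall validation long enough to trigger the LR-decay rule. head_sd > 0
  // draws a random readout instead (used for untrained-network analyses).
  const int head_in = c.hidden > 0 ? c.hidden : c.nin;
  fmat Wo(c.T, head_in, arma::fill::zeros);
  if (head_sd > 0) {
    float sd = (float)head_sd / std::sqrt((float)head_in);
    for (uword j = 0; j < Wo.n_cols; j++)
      for (uword i = 0; i < Wo.n_rows; i++) Wo(i, j) = sd * N(rng);
  }
  p.w.push_back(Wo);
  p.w.push_back(fmat(c.T, 1, arma::fill::zeros));
  return weights_to_list(p, c);
}

// [[Rcpp::export]]
NumericMatrix cpp_forward(IntegerMatrix codes, NumericMatrix table, NumericMatrix hl,
                          List weights, List cfg, int batch) {
  NetConfig c = parse_config(cfg);
  Params p = weights_from_list(weights, c);
  const int N = codes.ncol();
  if (codes.nrow() != c.L) stop("sequence length %d does not match model window %d", codes.nrow(), c.L);
  arma::imat cd(codes.nrow(), N);
  std::copy(codes.begin(), codes.end(), cd.begin());
  fmat tb(4, table.ncol());
  for (int j = 0; j < table.ncol(); j++)
    for (int i = 0; i < 4; i++) tb(i, j) = (float)table(i, j);
  fmat hlf(N, 5);
  for (int i = 0; i < N; i++)
    for (int q = 0; q < 5; q++) hlf(i, q) = (float)hl(i, q);

  NumericMatrix out(N, c.T);
  Batch b;
  for (int s0 = 0; s0 < N; s0 += batch) {
    int s1 = std::min(s0 + batch, N);
    arma::uvec idx(s1 - s0);
    for (int s = s0; s < s1; s++) idx[s - s0] = s;
    forward(p, c, cd, tb, hlf, idx, b, false, nullptr);
    for (int s = s0; s < s1; s++)
      for (int k = 0; k < c.T; k++) out(s, k) = b.O(k, s - s0);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train(IntegerMatrix codes, NumericMatrix table, NumericMatrix hl,
               NumericMatrix Y, IntegerVector train_idx, IntegerVector val_idx,
               List weights, List cfg, List tcfg, int seed) {
  NetConfig c = parse_config(cfg);
  Params p = weights_from_list(weights, c);
  if (codes.nrow() != c.L) stop("sequence length mismatch");
  if (Y.ncol() != c.T) stop("target columns (%d) do not match n_tasks (%d)", Y.ncol(), c.T);

  arma::imat cd(codes.nrow(), codes.ncol());
  std::copy(codes.begin(), codes.end(), cd.begin());
  fmat tb(4, table.ncol());
  for (int j = 0; j < table.ncol(); j++)
    for (int i = 0; i < 4; i++) tb(i, j) = (float)table(i, j);
  fmat hlf(hl.nrow(), 5);
  for (int i = 0; i < hl.nrow(); i++)
    for (int q = 0; q < 5; q++) hlf(i, q) = (float)hl(i, q);

  arma::uvec tr(train_idx.size()), va(val_idx.size());
  for (int i = 0; i < train_idx.size(); i++) tr[i] = train_idx[i] - 1;
  for (int i = 0; i < val_idx.size(); i++) va[i] = val_idx[i] - 1;

  double lr = as<double>(tcfg["initial_lr"]);
  const int patience = as<int>(tcfg["lr_patience"]);
  const double factor = as<double>(tcfg["lr_factor"]);
  const int epochs = as<int>(tcfg["max_epochs"]);
  const int batch = as<int>(tcfg["batch_size"]);

  std::mt19937 rng((uint32_t)seed);

  // Adam state
  std::vector<fmat> m(p.w.size()), v(p.w.size()), g(p.w.size());
  for (size_t i = 0; i < p.w.size(); i++) {
    m[i] = fmat(arma::size(p.w[i]), arma::fill::zeros);
    v[i] = fmat(arma::size(p.w[i]), arma::fill::zeros);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  long step = 0;

  std::vector<double> tr_loss(epochs), va_loss(epochs), lr_hist(epochs);
  Params best = p;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  Batch b;

  for (int ep = 0; ep < epochs; ep++) {
    arma::uvec order = tr;
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (uword s0 = 0; s0 < order.n_elem; s0 += batch) {
      uword s1 = std::min<uword>(s0 + batch, order.n_elem) - 1;
      arma::uvec sub = order.subvec(s0, s1);
      forward(p, c, cd, tb, hlf, sub, b, true, &rng);
      fmat Yt = targets_for(Y, sub);
      double batch_sse = arma::accu(arma::square(b.O - Yt));
      if (!std::isfinite(batch_sse))
        stop("non-finite training loss at epoch %d (lr=%g)", ep + 1, lr);
      sse += batch_sse;
      backward(p, c, Yt, b, g);
      step++;
      float bc1 = 1.f - std::pow(b1, (float)step);
      float bc2 = 1.f - std::pow(b2, (float)step);
      for (size_t i = 0; i < p.w.size(); i++) {
        m[i] = b1 * m[i] + (1.f - b1) * g[i];
        v[i] = b2 * v[i] + (1.f - b2) * arma::square(g[i]);
        p.w[i] -= (float)lr * (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps);
      }
      b.mask.reset();
    }
    tr_loss[ep] = sse / ((double)order.n_elem * c.T);
    va_loss[ep] = eval_mse(p, c, cd, tb, hlf, Y, va, batch);
    lr_hist[ep] = lr;
    if (!std::isfinite(va_loss[ep]))
      stop("non-finite validation loss at epoch %d (lr=%g)", ep + 1, lr);
    if (va_loss[ep] < best_val) {  // strict: earliest epoch wins ties
      best_val = va_loss[ep];
      best = p;
      best_epoch = ep + 1;
      wait = 0;
    } else if (++wait >= patience) {
      lr /= factor;
      wait = 0;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["weights"] = weights_to_list(best, c),
      _["history"] = DataFrame::create(
          _["epoch"] = seq_len(epochs), _["train_loss"] = tr_loss,
          _["val_loss"] = va_loss, _["lr"] = lr_hist),
      _["best_epoch"] = best_epoch, _["best_val_loss"] = best_val);
}

// Full-batch loss and analytic gradients without dropout (for gradient checks).
// [[Rcpp::export]]
List cpp_loss_grad(IntegerMatrix codes, NumericMatrix table, NumericMatrix hl,
                   NumericMatrix Y, List weights, List cfg) {
  NetConfig c = parse_config(cfg);
  NetConfig cnd = c;
  cnd.dropout = 0.f;
  Params p = weights_from_list(weights, c);
  arma::imat cd(codes.nrow(), codes.ncol());
  std::copy(codes.begin(), codes.end(), cd.begin());
  fmat tb(4, table.ncol());
  for (int j = 0; j < table.ncol(); j++)
    for (int i = 0; i < 4; i++) tb(i, j) = (float)table(i, j);
  fmat hlf(hl.nrow(), 5);
  for (int i = 0; i < hl.nrow(); i++)
    for (int q = 0; q < 5; q++) hlf(i, q) = (float)hl(i, q);
  arma::uvec idx(codes.ncol());
  for (int i = 0; i < codes.ncol(); i++) idx[i] = i;
  Batch b;
  forward(p, cnd, cd, tb, hlf, idx, b, false, nullptr);
  fmat Yt = targets_for(Y, idx);
  double loss = arma::accu(arma::square(b.O - Yt)) / ((double)idx.n_elem * c.T);
  std::vector<fmat> g(p.w.size());
  backward(p, cnd, Yt, b, g);
  Params gp;
  gp.w = g;
  return List::create(_["loss"] = loss, _["grads"] = weights_to_list(gp, c));
}
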