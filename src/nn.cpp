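// Small feedforward CNN / Siamese training engine.
//
// Layout conventions:
//  * A feature-map batch is an arma::fmat A of size (H*W*N x C): column ch
//    holds channel ch of all N images back to back; the row index is
//    s + n*H*W with spatial index s = r + c*H (r = row, c = col, 0-based).
//    An (H*W x N) single-channel input batch is exactly this layout with
//    C = 1, so images are passed in without copying.
//  * Convolutions are 2x2, stride 1, evaluated as one gemm per batch on an
//    im2col matrix (H2*W2*N x Cin*4) whose construction is pure memcpy in
//    this layout. "same" padding pads one implicit zero row/column at the
//    bottom/right (so output size is preserved); "valid" shrinks each
//    dimension by 1. Conv weights are stored as (Cin*4 x Cout).
//  * Max pooling is 2x2 with configurable stride (default 1).
//  * The classifier head is fc1 -> relu -> dropout -> fc2 -> relu ->
//    dropout -> 2 sigmoid units trained with binary cross-entropy on
//    one-hot labels, optimized with Adam.
//  * The Siamese variant runs the shared trunk on two single-item images
//    and feeds the elementwise feature difference to the head.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::umat;
using arma::uword;

struct NetCfg {
  int H, W, n_conv, channels, fc1, fc2;
  double dropout, lr, stop_at_val;
  int epochs, batch, pool_stride, val_every;
  bool same_pad, siamese, conv_dropout;
  std::vector<int> hs, ws, cs;   // dims entering each conv block
  std::vector<int> ph, pw;       // dims entering each pool (post-conv)
  int hf, wf, flat_dim;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.H = as<int>(cfg["input_h"]); c.W = as<int>(cfg["input_w"]);
  c.n_conv = as<int>(cfg["n_conv_layers"]);
  c.channels = as<int>(cfg["channels"]);
  IntegerVector fc = cfg["fc_units"];
  c.fc1 = fc[0]; c.fc2 = fc[1];
  c.dropout = as<double>(cfg["dropout"]);
  c.lr = as<double>(cfg["learning_rate"]);
  c.epochs = as<int>(cfg["epochs"]);
  c.batch = as<int>(cfg["batch_size"]);
  c.stop_at_val = as<double>(cfg["stop_at_val"]);
  c.same_pad = as<std::string>(cfg["padding"]) == "same";
  c.pool_stride = as<int>(cfg["pool_stride"]);
  c.val_every = cfg.containsElementNamed("val_every") ? as<int>(cfg["val_every"]) : 1;
  if (c.val_every < 1) c.val_every = 1;
  c.siamese = as<bool>(cfg["siamese"]);
  c.conv_dropout = as<bool>(cfg["conv_dropout"]);
  int h = c.H, w = c.W, ch = 1;
  for (int l = 0; l < c.n_conv; ++l) {
    if (h < 2 || w < 2)
      stop("spatial dimensions collapsed below the 2x2 kernel at conv layer %d", l + 1);
    c.hs.push_back(h); c.ws.push_back(w); c.cs.push_back(ch);
    if (!c.same_pad) { h -= 1; w -= 1; }
    c.ph.push_back(h); c.pw.push_back(w);
    if (h < 2 || w < 2)
      stop("spatial dimensions collapsed below the 2x2 pool at layer %d", l + 1);
    h = (h - 2) / c.pool_stride + 1;
    w = (w - 2) / c.pool_stride + 1;
    ch = c.channels;
  }
  c.hf = h; c.wf = w;
  c.flat_dim = h * w * ch;
  return c;
}

// ---------------------------------------------------------------- im2col --
// A (H*W*N x Cin) -> col (H2*W2*N x Cin*4); contiguous copies per column.
static void im2col(const fmat& A, int H, int W, int N, bool same, fmat& col) {
  const int H2 = same ? H : H - 1, W2 = same ? W : W - 1;
  const int Cin = A.n_cols, HW = H * W, HW2 = H2 * W2;
  col.set_size((uword)HW2 * N, (uword)Cin * 4);
  for (int cin = 0; cin < Cin; ++cin) {
    const float* a = A.colptr(cin);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        float* d = col.colptr(cin * 4 + dr + 2 * dc);
        const int copy_len = std::min(H2, H - dr);
        for (int n = 0; n < N; ++n)
          for (int c2 = 0; c2 < W2; ++c2) {
            const int cc = c2 + dc;
            float* dst = d + (uword)c2 * H2 + (uword)n * HW2;
            if (cc >= W) { std::memset(dst, 0, H2 * sizeof(float)); continue; }
            const float* src = a + dr + (uword)cc * H + (uword)n * HW;
            std::memcpy(dst, src, copy_len * sizeof(float));
            if (copy_len < H2)
              std::memset(dst + copy_len, 0, (H2 - copy_len) * sizeof(float));
          }
      }
  }
}

// dcol (H2*W2*N x Cin*4) -> dA (H*W*N x Cin), accumulating.
static void col2im(const fmat& dcol, int H, int W, int N, bool same, fmat& dA) {
  const int H2 = same ? H : H - 1, W2 = same ? W : W - 1;
  const int Cin = dA.n_cols, HW = H * W, HW2 = H2 * W2;
  dA.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    float* a = dA.colptr(cin);
    for (int dc = 0; dc < 2; ++dc)
      for (int dr = 0; dr < 2; ++dr) {
        const float* d = dcol.colptr(cin * 4 + dr + 2 * dc);
        const int copy_len = std::min(H2, H - dr);
        for (int n = 0; n < N; ++n)
          for (int c2 = 0; c2 < W2; ++c2) {
            const int cc = c2 + dc;
            if (cc >= W) continue;
            const float* src = d + (uword)c2 * H2 + (uword)n * HW2;
            float* dst = a + dr + (uword)cc * H + (uword)n * HW;
            for (int i = 0; i < copy_len; ++i) dst[i] += src[i];
          }
      }
  }
}

// ------------------------------------------------------------------ pool --
static void pool_forward(const fmat& A, int H, int W, int N, int stride,
                         fmat& P, umat& AM) {
  const int C = A.n_cols, HW = H * W;
  const int H2 = (H - 2) / stride + 1, W2 = (W - 2) / stride + 1, HW2 = H2 * W2;
  P.set_size((uword)HW2 * N, C);
  AM.set_size((uword)HW2 * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* a = A.colptr(ch);
    float* p = P.colptr(ch);
    uword* am = AM.colptr(ch);
    for (int n = 0; n < N; ++n)
      for (int c2 = 0; c2 < W2; ++c2) {
        const uword s0 = (uword)c2 * stride * H + (uword)n * HW;
        const uword j0 = (uword)c2 * H2 + (uword)n * HW2;
        for (int r2 = 0; r2 < H2; ++r2) {
          const uword s = s0 + (uword)r2 * stride;
          float best = a[s]; uword bi = s;
          if (a[s + 1] > best) { best = a[s + 1]; bi = s + 1; }
          if (a[s + H] > best) { best = a[s + H]; bi = s + H; }
          if (a[s + H + 1] > best) { best = a[s + H + 1]; bi = s + H + 1; }
          p[j0 + r2] = best; am[j0 + r2] = bi;
        }
      }
  }
}

static void pool_backward(const fmat& dP, const umat& AM, fmat& dA) {
  dA.zeros();
  for (uword ch = 0; ch < dP.n_cols; ++ch) {
    const float* dp = dP.colptr(ch);
    const uword* am = AM.colptr(ch);
    float* da = dA.colptr(ch);
    for (uword j = 0; j < dP.n_rows; ++j) da[am[j]] += dp[j];
  }
}

// ----------------------------------------------------------------- trunk --
struct TrunkCache {
  std::vector<fmat> col;      // im2col matrices
  std::vector<fmat> relu;     // post-relu conv output (post-dropout if any)
  std::vector<fmat> drop;     // inverted-dropout masks (empty if disabled)
  std::vector<umat> am;       // pool argmax
};

// Flatten (HWf*N x C) -> (HWf*C x N); per-(n, ch) blocks are contiguous.
static void flatten(const fmat& A, int HWf, int N, fmat& F) {
  const int C = A.n_cols;
  F.set_size((uword)HWf * C, N);
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch)
      std::memcpy(F.colptr(n) + (uword)ch * HWf,
                  A.colptr(ch) + (uword)n * HWf, HWf * sizeof(float));
}

static void unflatten(const fmat& F, int HWf, int N, fmat& A) {
  const int C = F.n_rows / HWf;
  A.set_size((uword)HWf * N, C);
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch)
      std::memcpy(A.colptr(ch) + (uword)n * HWf,
                  F.colptr(n) + (uword)ch * HWf, HWf * sizeof(float));
}

// Forward through the convolutional trunk. A0 is (H*W*N x 1).
static fmat trunk_forward(const fmat& A0, const NetCfg& cfg,
                          const std::vector<fmat>& Wc, const std::vector<fmat>& bc,
                          int N, TrunkCache* cache,
                          std::mt19937* drop_rng = nullptr) {
  const float keep = 1.0f - (float)cfg.dropout;
  std::uniform_real_distribution<float> U01(0.0f, 1.0f);
  fmat A = A0;
  for (int l = 0; l < cfg.n_conv; ++l) {
    fmat col;
    im2col(A, cfg.hs[l], cfg.ws[l], N, cfg.same_pad, col);
    fmat Y = col * Wc[l];                     // (H1*W1*N x Cout)
    for (uword ch = 0; ch < Y.n_cols; ++ch) {
      float* y = Y.colptr(ch);
      const float b = bc[l].at(ch, 0);
      for (uword i = 0; i < Y.n_rows; ++i) {
        const float v = y[i] + b;
        y[i] = v > 0.0f ? v : 0.0f;
      }
    }
    fmat M;
    if (drop_rng && cfg.conv_dropout && cfg.dropout > 0) {
      M.set_size(Y.n_rows, Y.n_cols);
      for (uword i = 0; i < M.n_elem; ++i)
        M.at(i) = U01(*drop_rng) < keep ? 1.0f / keep : 0.0f;
      Y %= M;
    }
    fmat P; umat AM;
    pool_forward(Y, cfg.ph[l], cfg.pw[l], N, cfg.pool_stride, P, AM);
    if (cache) {
      cache->col.push_back(std::move(col));
      cache->relu.push_back(std::move(Y));
      cache->drop.push_back(std::move(M));
      cache->am.push_back(std::move(AM));
    }
    A = std::move(P);
  }
  fmat F;
  flatten(A, cfg.hf * cfg.wf, N, F);
  return F;
}

// Backward through the trunk, accumulating weight gradients (+=).
static void trunk_backward(const fmat& dF, const NetCfg& cfg,
                           const std::vector<fmat>& Wc, TrunkCache& cache,
                           int N, std::vector<fmat>& gWc, std::vector<fmat>& gbc) {
  fmat dA;
  unflatten(dF, cfg.hf * cfg.wf, N, dA);
  for (int l = cfg.n_conv - 1; l >= 0; --l) {
    const int H1 = cfg.ph[l], W1 = cfg.pw[l];
    fmat dY((uword)H1 * W1 * N, cfg.channels);
    pool_backward(dA, cache.am[l], dY);
    const fmat& Y = cache.relu[l];
    for (uword i = 0; i < dY.n_elem; ++i)
      if (Y.at(i) <= 0.0f) dY.at(i) = 0.0f;
    gWc[l] += cache.col[l].t() * dY;          // (Cin*4 x Cout)
    gbc[l].col(0) += arma::sum(dY, 0).t();
    fmat dcol = dY * Wc[l].t();               // (H1*W1*N x Cin*4)
    dA.set_size((uword)cfg.hs[l] * cfg.ws[l] * N, cfg.cs[l]);
    col2im(dcol, cfg.hs[l], cfg.ws[l], N, cfg.same_pad, dA);
  }
}

// ------------------------------------------------------------------ misc --
static fmat sigmoidf(fmat Z) {
  Z.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  return Z;
}

static fmat as_f(const arma::mat& X) { return arma::conv_to<fmat>::from(X); }

struct Params {
  std::vector<fmat> Wc, bc;
  fmat W1, b1, W2, b2, W3, b3;
  std::vector<fmat*> all() {
    std::vector<fmat*> v;
    for (auto& m : Wc) v.push_back(&m);
    for (auto& m : bc) v.push_back(&m);
    v.push_back(&W1); v.push_back(&b1); v.push_back(&W2); v.push_back(&b2);
    v.push_back(&W3); v.push_back(&b3);
    return v;
  }
};

static Params unpack(const List& weights, const NetCfg& cfg) {
  Params p;
  for (int l = 0; l < cfg.n_conv; ++l) {
    p.Wc.push_back(as_f(as<arma::mat>(weights["conv_W" + std::to_string(l + 1)])));
    p.bc.push_back(as_f(as<arma::mat>(weights["conv_b" + std::to_string(l + 1)])));
  }
  p.W1 = as_f(as<arma::mat>(weights["fc_W1"])); p.b1 = as_f(as<arma::mat>(weights["fc_b1"]));
  p.W2 = as_f(as<arma::mat>(weights["fc_W2"])); p.b2 = as_f(as<arma::mat>(weights["fc_b2"]));
  p.W3 = as_f(as<arma::mat>(weights["out_W"])); p.b3 = as_f(as<arma::mat>(weights["out_b"]));
  return p;
}

static List pack(const Params& p, const NetCfg& cfg) {
  List w;
  for (int l = 0; l < cfg.n_conv; ++l) {
    w["conv_W" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(p.Wc[l]);
    w["conv_b" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(p.bc[l]);
  }
  w["fc_W1"] = arma::conv_to<arma::mat>::from(p.W1);
  w["fc_b1"] = arma::conv_to<arma::mat>::from(p.b1);
  w["fc_W2"] = arma::conv_to<arma::mat>::from(p.W2);
  w["fc_b2"] = arma::conv_to<arma::mat>::from(p.b2);
  w["out_W"] = arma::conv_to<arma::mat>::from(p.W3);
  w["out_b"] = arma::conv_to<arma::mat>::from(p.b3);
  return w;
}

// Forward pass to class probabilities. X is (H*W*N x 1).
static fmat forward_probs(const Params& p, const NetCfg& cfg, const fmat& X,
                          const fmat& X2, int N) {
  fmat F = trunk_forward(X, cfg, p.Wc, p.bc, N, nullptr);
  if (cfg.siamese) F -= trunk_forward(X2, cfg, p.Wc, p.bc, N, nullptr);
  fmat A1 = p.W1 * F; A1.each_col() += p.b1.col(0);
  A1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat A2 = p.W2 * A1; A2.each_col() += p.b2.col(0);
  A2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat Z3 = p.W3 * A2; Z3.each_col() += p.b3.col(0);
  return sigmoidf(Z3);
}

static double accuracy_chunked(const Params& p, const NetCfg& cfg,
                               const fmat& X, const fmat& X2,
                               const arma::ivec& y) {
  const int HW = cfg.H * cfg.W, n = y.n_elem, chunk = 250;
  int correct = 0;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk), m = e - s;
    const fmat Xc(const_cast<float*>(X.memptr()) + (uword)s * HW,
                  (uword)m * HW, 1, false);
    fmat X2c;
    if (cfg.siamese)
      X2c = fmat(const_cast<float*>(X2.memptr()) + (uword)s * HW,
                 (uword)m * HW, 1, false);
    fmat P = forward_probs(p, cfg, Xc, X2c, m);
    for (int i = 0; i < m; ++i)
      if ((P.at(1, i) > P.at(0, i) ? 1 : 0) == y[s + i]) ++correct;
  }
  return (double)correct / n;
}

// ------------------------------------------------------------------ init --
// [[Rcpp::export]]
List cpp_nn_init(List cfg_in, int seed) {
  NetCfg cfg = parse_cfg(cfg_in);
  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int rows, int cols, double fan_in, double fan_out) {
    const float lim = (float)std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<float> U(-lim, lim);
    fmat Wm(rows, cols);
    for (uword i = 0; i < Wm.n_elem; ++i) Wm.at(i) = U(rng);
    return Wm;
  };
  Params p;
  for (int l = 0; l < cfg.n_conv; ++l) {
    const int cin = cfg.cs[l];
    p.Wc.push_back(glorot(cin * 4, cfg.channels, cin * 4.0, cfg.channels * 4.0));
    p.bc.push_back(fmat(cfg.channels, 1, arma::fill::zeros));
  }
  p.W1 = glorot(cfg.fc1, cfg.flat_dim, cfg.flat_dim, cfg.fc1);
  p.b1 = fmat(cfg.fc1, 1, arma::fill::zeros);
  p.W2 = glorot(cfg.fc2, cfg.fc1, cfg.fc1, cfg.fc2);
  p.b2 = fmat(cfg.fc2, 1, arma::fill::zeros);
  p.W3 = glorot(2, cfg.fc2, cfg.fc2, 2.0);
  p.b3 = fmat(2, 1, arma::fill::zeros);
  List w = pack(p, cfg);
  uword count = 0;
  for (auto* m : p.all()) count += m->n_elem;
  w.attr("param_count") = (double)count;
  return w;
}

// ----------------------------------------------------------------- train --
// [[Rcpp::export]]
List cpp_nn_train(List weights, List cfg_in,
                  const arma::mat& Xtr_in, const arma::ivec& ytr,
                  const arma::mat& Xval_in, const arma::ivec& yval,
                  Nullable<NumericMatrix> Xtr2_in, Nullable<NumericMatrix> Xval2_in,
                  int seed) {
  NetCfg cfg = parse_cfg(cfg_in);
  Params p = unpack(weights, cfg);
  const int HW = cfg.H * cfg.W, ntr = ytr.n_elem;
  const fmat Xtr = as_f(Xtr_in), Xval = as_f(Xval_in);
  fmat Xtr2, Xval2;
  if (cfg.siamese) {
    if (Xtr2_in.isNull() || Xval2_in.isNull())
      stop("siamese training needs second-branch images");
    Xtr2 = as_f(as<arma::mat>(Xtr2_in.get()));
    Xval2 = as_f(as<arma::mat>(Xval2_in.get()));
    if (Xtr2.n_rows != Xtr.n_rows || Xtr2.n_cols != Xtr.n_cols)
      stop("siamese branches must have identical input shapes");
  }

  std::mt19937 rng((unsigned)seed + 1234u);
  std::uniform_real_distribution<float> U01(0.0f, 1.0f);
  const float keep = 1.0f - (float)cfg.dropout;

  std::vector<fmat*> params = p.all();
  std::vector<fmat> m_(params.size()), v_(params.size());
  for (size_t i = 0; i < params.size(); ++i) {
    m_[i].zeros(params[i]->n_rows, params[i]->n_cols);
    v_[i].zeros(params[i]->n_rows, params[i]->n_cols);
  }
  const float b1a = 0.9f, b2a = 0.999f, eps = 1e-7f, lr = (float)cfg.lr;
  long tstep = 0;

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  std::vector<double> h_loss, h_tracc, h_valacc;
  int epochs_run = 0;

  for (int ep = 0; ep < cfg.epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; long ep_correct = 0;
    for (int s = 0; s < ntr; s += cfg.batch) {
      const int e = std::min(ntr, s + cfg.batch), B = e - s;
      fmat Xb((uword)B * HW, 1), Xb2;
      if (cfg.siamese) Xb2.set_size((uword)B * HW, 1);
      arma::ivec yb(B);
      for (int i = 0; i < B; ++i) {
        const int idx = order[s + i];
        std::memcpy(Xb.memptr() + (uword)i * HW,
                    Xtr.memptr() + (uword)idx * HW, HW * sizeof(float));
        if (cfg.siamese)
          std::memcpy(Xb2.memptr() + (uword)i * HW,
                      Xtr2.memptr() + (uword)idx * HW, HW * sizeof(float));
        yb[i] = ytr[idx];
      }
      // forward
      TrunkCache ca, cb;
      fmat F = trunk_forward(Xb, cfg, p.Wc, p.bc, B, &ca, &rng);
      if (cfg.siamese) F -= trunk_forward(Xb2, cfg, p.Wc, p.bc, B, &cb, &rng);
      fmat A1 = p.W1 * F; A1.each_col() += p.b1.col(0);
      A1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      fmat M1(A1.n_rows, A1.n_cols);
      for (uword i = 0; i < M1.n_elem; ++i)
        M1.at(i) = U01(rng) < keep ? 1.0f / keep : 0.0f;
      fmat A1d = A1 % M1;
      fmat A2 = p.W2 * A1d; A2.each_col() += p.b2.col(0);
      A2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      fmat M2(A2.n_rows, A2.n_cols);
      for (uword i = 0; i < M2.n_elem; ++i)
        M2.at(i) = U01(rng) < keep ? 1.0f / keep : 0.0f;
      fmat A2d = A2 % M2;
      fmat Z3 = p.W3 * A2d; Z3.each_col() += p.b3.col(0);
      fmat P = sigmoidf(Z3);

      // loss + accuracy on this batch
      fmat Y(2, B);
      for (int i = 0; i < B; ++i) { Y.at(1, i) = (float)yb[i]; Y.at(0, i) = 1.0f - yb[i]; }
      double loss = 0;
      for (uword i = 0; i < P.n_elem; ++i) {
        const double pi = std::min(std::max((double)P.at(i), 1e-7), 1 - 1e-7);
        loss += -(Y.at(i) * std::log(pi) + (1 - Y.at(i)) * std::log(1 - pi));
      }
      loss /= 2.0 * B;
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += loss * B;
      for (int i = 0; i < B; ++i)
        if ((P.at(1, i) > P.at(0, i) ? 1 : 0) == yb[i]) ++ep_correct;

      // backward
      fmat dZ3 = (P - Y) / (2.0f * B);
      fmat gW3 = dZ3 * A2d.t();
      fmat gb3 = arma::sum(dZ3, 1);
      fmat dA2 = (p.W3.t() * dZ3) % M2;
      for (uword i = 0; i < dA2.n_elem; ++i) if (A2.at(i) <= 0.0f) dA2.at(i) = 0.0f;
      fmat gW2 = dA2 * A1d.t();
      fmat gb2 = arma::sum(dA2, 1);
      fmat dA1 = (p.W2.t() * dA2) % M1;
      for (uword i = 0; i < dA1.n_elem; ++i) if (A1.at(i) <= 0.0f) dA1.at(i) = 0.0f;
      fmat gW1 = dA1 * F.t();
      fmat gb1 = arma::sum(dA1, 1);
      fmat dF = p.W1.t() * dA1;

      std::vector<fmat> gWc(cfg.n_conv), gbc(cfg.n_conv);
      for (int l = 0; l < cfg.n_conv; ++l) {
        gWc[l].zeros(p.Wc[l].n_rows, p.Wc[l].n_cols);
        gbc[l].zeros(p.bc[l].n_rows, 1);
      }
      if (cfg.n_conv > 0) {
        trunk_backward(dF, cfg, p.Wc, ca, B, gWc, gbc);
        if (cfg.siamese) {
          fmat dFneg = -dF;
          trunk_backward(dFneg, cfg, p.Wc, cb, B, gWc, gbc);
        }
      }

      // Adam step
      std::vector<fmat*> grads;
      for (auto& g : gWc) grads.push_back(&g);
      for (auto& g : gbc) grads.push_back(&g);
      grads.push_back(&gW1); grads.push_back(&gb1);
      grads.push_back(&gW2); grads.push_back(&gb2);
      grads.push_back(&gW3); grads.push_back(&gb3);
      ++tstep;
      const float bc1 = 1.0f - std::pow(b1a, (float)tstep);
      const float bc2 = 1.0f - std::pow(b2a, (float)tstep);
      for (size_t i = 0; i < params.size(); ++i) {
        m_[i] = b1a * m_[i] + (1.0f - b1a) * (*grads[i]);
        v_[i] = b2a * v_[i] + (1.0f - b2a) * arma::square(*grads[i]);
        *params[i] -= lr * (m_[i] / bc1) / (arma::sqrt(v_[i] / bc2) + eps);
      }
    }
    double val_acc;
    if ((ep + 1) % cfg.val_every == 0 || ep == cfg.epochs - 1 ||
        h_valacc.empty()) {
      val_acc = accuracy_chunked(p, cfg, Xval, Xval2, yval);
    } else {
      val_acc = h_valacc.back();   // carried forward between evaluations
    }
    h_loss.push_back(ep_loss / ntr);
    h_tracc.push_back((double)ep_correct / ntr);
    h_valacc.push_back(val_acc);
    epochs_run = ep + 1;
    Rcpp::checkUserInterrupt();
    if (val_acc >= cfg.stop_at_val) break;
  }

  return List::create(
    _["weights"] = pack(p, cfg),
    _["history"] = DataFrame::create(
      _["epoch"] = seq(1, epochs_run), _["loss"] = h_loss,
      _["train_acc"] = h_tracc, _["val_acc"] = h_valacc),
    _["epochs_run"] = epochs_run);
}

// --------------------------------------------------------------- predict --
// [[Rcpp::export]]
arma::mat cpp_nn_predict(List weights, List cfg_in, const arma::mat& X_in,
                         Nullable<NumericMatrix> X2_in) {
  NetCfg cfg = parse_cfg(cfg_in);
  Params p = unpack(weights, cfg);
  const int HW = cfg.H * cfg.W;
  const int N = X_in.n_cols;
  fmat X = as_f(X_in), X2;
  if (cfg.siamese) {
    if (X2_in.isNull()) stop("siamese prediction needs second-branch images");
    X2 = as_f(as<arma::mat>(X2_in.get()));
  }
  const int chunk = 250;
  arma::mat out(2, N);
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk), m = e - s;
    const fmat Xc(const_cast<float*>(X.memptr()) + (uword)s * HW,
                  (uword)m * HW, 1, false);
    fmat X2c;
    if (cfg.siamese)
      X2c = fmat(const_cast<float*>(X2.memptr()) + (uword)s * HW,
                 (uword)m * HW, 1, false);
    out.cols(s, e - 1) =
      arma::conv_to<arma::mat>::from(forward_probs(p, cfg, Xc, X2c, m));
  }
  return out;
}
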