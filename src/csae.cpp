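// Core of the convolutional supervised auto-encoder (CSAE).
//
// The network is small enough (5 stages max, 3x3x3 kernels) that a direct
// im2col + single-precision GEMM formulation through the BLAS is the fastest
// portable option on a single CPU core.  Feature maps are stored as V x C
// matrices (V = nx*ny*nz voxels, column-major with x fastest), so a 3x3x3
// convolution is one GEMM of the lowered (V x 27*Cin) matrix against the
// (27*Cin x Cout) weight matrix.  Weight rows are ordered with the spatial
// offset fastest (dx, then dy, then dz, offsets -1..1) within each input
// channel; the pure-R reference forward pass in the test suite mirrors this
// layout exactly.

#include <RcppArmadillo.h>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Dims {
  int nx, ny, nz;
  size_t V() const { return (size_t)nx * ny * nz; }
};

static Dims halve(const Dims& d) { return Dims{d.nx / 2, d.ny / 2, d.nz / 2}; }

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3x3 same-padding convolution
// ---------------------------------------------------------------------------

static void im2col3(const fmat& X, const Dims& d, fmat& A) {
  const size_t V = d.V();
  A.set_size(V, 27 * X.n_cols);  // no realloc when dimensions are unchanged
  const size_t rowbytes = (size_t)d.nx * sizeof(float);
  int col = 0;
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          float* dst = A.colptr(col++);
          for (int z = 0; z < d.nz; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= d.nz) {
              std::memset(dst + (size_t)z * d.ny * d.nx, 0, rowbytes * d.ny);
              continue;
            }
            for (int y = 0; y < d.ny; ++y) {
              const int ys = y + dy;
              float* t = dst + ((size_t)z * d.ny + y) * d.nx;
              if (ys < 0 || ys >= d.ny) {
                std::memset(t, 0, rowbytes);
                continue;
              }
              const int x0 = std::max(0, -dx), x1 = std::min(d.nx, d.nx - dx);
              const float* s = src + ((size_t)zs * d.ny + ys) * d.nx + x0 + dx;
              if (x0 > 0) std::memset(t, 0, (size_t)x0 * sizeof(float));
              std::memcpy(t + x0, s, (size_t)(x1 - x0) * sizeof(float));
              if (x1 < d.nx)
                std::memset(t + x1, 0, (size_t)(d.nx - x1) * sizeof(float));
            }
          }
        }
  }
}

// scatter-add transpose of im2col3: dA (V x 27*Cin) -> dX (V x Cin)
static void col2im3(const fmat& dA, const Dims& d, int cin, fmat& dX) {
  dX.zeros(d.V(), cin);
  int col = 0;
  for (int c = 0; c < cin; ++c) {
    float* dst = dX.colptr(c);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const float* src = dA.colptr(col++);
          for (int z = 0; z < d.nz; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= d.nz) continue;
            for (int y = 0; y < d.ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= d.ny) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(d.nx, d.nx - dx);
              float* t = dst + ((size_t)zs * d.ny + ys) * d.nx + x0 + dx;
              const float* s = src + ((size_t)z * d.ny + y) * d.nx + x0;
              for (int x = 0; x < x1 - x0; ++x) t[x] += s[x];
            }
          }
        }
  }
}

// ---------------------------------------------------------------------------
// network definition
// ---------------------------------------------------------------------------

struct ConvP {
  fmat W;     // 27*cin x cout
  frowvec b;  // cout
};

struct Net {
  int S;             // number of stages
  ivec ch;           // channels per stage
  Dims d0;           // input extent
  float slope;       // LeakyReLU negative slope
  float drop;        // 3D (channel-wise) dropout rate
  int K;             // classes
  std::vector<ConvP> conv;  // enc (2S), dec (2(S-1)), out (1)
  fmat Wh;           // nf x K
  frowvec bh;        // K
  int n_conv() const { return 2 * S + 2 * (S - 1) + 1; }
};

static Net net_from_r(const Rcpp::List& weights, const Rcpp::List& config) {
  Net n;
  Rcpp::IntegerVector ext = config["target_extent"];
  n.d0 = Dims{ext[0], ext[1], ext[2]};
  Rcpp::IntegerVector ch = config["channels_per_stage"];
  n.S = ch.size();
  n.ch = ivec(n.S);
  for (int i = 0; i < n.S; ++i) n.ch[i] = ch[i];
  n.slope = (float)Rcpp::as<double>(config["leaky_slope"]);
  n.drop = (float)Rcpp::as<double>(config["dropout_rate"]);
  Rcpp::List convs = weights["conv"];
  if ((int)convs.size() != n.n_conv())
    Rcpp::stop("weight list has %d conv layers, expected %d", (int)convs.size(), n.n_conv());
  for (int i = 0; i < (int)convs.size(); ++i) {
    Rcpp::List l = convs[i];
    ConvP p;
    p.W = conv_to<fmat>::from(Rcpp::as<mat>(l["W"]));
    p.b = conv_to<frowvec>::from(Rcpp::as<rowvec>(l["b"]));
    n.conv.push_back(p);
  }
  Rcpp::List head = weights["head"];
  n.Wh = conv_to<fmat>::from(Rcpp::as<mat>(head["W"]));
  n.bh = conv_to<frowvec>::from(Rcpp::as<rowvec>(head["b"]));
  n.K = n.Wh.n_cols;
  return n;
}

static Rcpp::List net_to_r(const Net& n) {
  Rcpp::List convs(n.conv.size());
  for (size_t i = 0; i < n.conv.size(); ++i) {
    convs[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(n.conv[i].W),
        Rcpp::Named("b") = conv_to<rowvec>::from(n.conv[i].b));
  }
  return Rcpp::List::create(
      Rcpp::Named("conv") = convs,
      Rcpp::Named("head") = Rcpp::List::create(
          Rcpp::Named("W") = conv_to<mat>::from(n.Wh),
          Rcpp::Named("b") = conv_to<rowvec>::from(n.bh)));
}

// ---------------------------------------------------------------------------
// layer primitives (with caches for backprop)
// ---------------------------------------------------------------------------

struct ConvCache {
  fmat A;        // lowered input
  fmat pre;      // pre-activation
  frowvec keep;  // dropout scale per output channel (1 in eval mode)
  Dims d;
  int cin;
};

// conv -> LeakyReLU -> channel dropout
static fmat block_fwd(const Net& net, int li, const fmat& X, const Dims& d,
                      bool training, std::mt19937& rng, ConvCache& cc) {
  cc.d = d;
  cc.cin = X.n_cols;
  im2col3(X, d, cc.A);
  cc.pre = cc.A * net.conv[li].W;
  cc.pre.each_row() += net.conv[li].b;
  fmat out = cc.pre;
  // LeakyReLU
  out.transform([&](float v) { return v > 0.0f ? v : net.slope * v; });
  // 3D dropout: drop whole channels
  cc.keep.ones(out.n_cols);
  if (training && net.drop > 0.0f) {
    std::bernoulli_distribution bern(1.0 - net.drop);
    for (uword c = 0; c < out.n_cols; ++c)
      cc.keep(c) = bern(rng) ? 1.0f / (1.0f - net.drop) : 0.0f;
    out.each_row() %= cc.keep;
  }
  return out;
}

// gradient w.r.t. block input; accumulates dW/db. G is grad w.r.t. block output.
static fmat block_bwd(const Net& net, int li, ConvCache& cc, fmat G,
                      fmat& dW, frowvec& db, bool need_dx, bool guided) {
  if (!guided) {
    G.each_row() %= cc.keep;
    // LeakyReLU derivative from cached pre-activation
    const float slope = net.slope;
    for (uword j = 0; j < G.n_elem; ++j)
      if (cc.pre(j) <= 0.0f) G(j) *= slope;
  } else {
    // guided rule: pass only where forward pre-activation positive AND
    // incoming gradient positive
    for (uword j = 0; j < G.n_elem; ++j)
      if (cc.pre(j) <= 0.0f || G(j) < 0.0f) G(j) = 0.0f;
  }
  if (dW.n_elem > 0) {
    dW += cc.A.t() * G;
    db += sum(G, 0);
  }
  if (!need_dx) return fmat();
  fmat dA = G * net.conv[li].W.t();
  fmat dX;
  col2im3(dA, cc.d, cc.cin, dX);
  return dX;
}

static fmat maxpool_fwd(const fmat& X, const Dims& d, umat& idx) {
  Dims h = halve(d);
  fmat Y(h.V(), X.n_cols);
  idx.set_size(h.V(), X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    uword* ix = idx.colptr(c);
    size_t o = 0;
    for (int z = 0; z < h.nz; ++z)
      for (int y = 0; y < h.ny; ++y)
        for (int x = 0; x < h.nx; ++x, ++o) {
          float best = -std::numeric_limits<float>::infinity();
          size_t besti = 0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                size_t s = ((size_t)(2 * z + kz) * d.ny + (2 * y + ky)) * d.nx +
                           (2 * x + kx);
                if (src[s] > best) { best = src[s]; besti = s; }
              }
          dst[o] = best;
          ix[o] = besti;
        }
  }
  return Y;
}

static fmat maxpool_bwd(const fmat& G, const umat& idx, const Dims& d_in, int C) {
  fmat dX(d_in.V(), C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    const float* g = G.colptr(c);
    const uword* ix = idx.colptr(c);
    for (uword o = 0; o < G.n_rows; ++o) dst[ix[o]] += g[o];
  }
  return dX;
}

// row map for nearest-neighbour x2 upsampling: out voxel -> source voxel
static uvec upsample_map(const Dims& h) {
  Dims d{2 * h.nx, 2 * h.ny, 2 * h.nz};
  uvec map(d.V());
  size_t o = 0;
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x, ++o)
        map(o) = ((size_t)(z / 2) * h.ny + (y / 2)) * h.nx + (x / 2);
  return map;
}

// ---------------------------------------------------------------------------
// full forward / backward
// ---------------------------------------------------------------------------

struct FwdState {
  std::vector<ConvCache> cc;   // one per conv layer, canonical order
  std::vector<umat> poolidx;   // S-1 pools
  std::vector<Dims> dims;      // dims at each stage (0..S-1)
  std::vector<uvec> upmaps;    // S-1 upsample maps (stage order s = S..2)
  fvec z;                      // flattened bottleneck
  fvec logits, probs;
  fvec recon;
  double recon_mse = 0.0, class_term = 0.0, total = 0.0;
};

// encoder + classifier head (always) and decoder + reconstruction (optional)
static void forward_full(const Net& net, const fvec& x, int y /*0-based, -1 if none*/,
                         double lambda, const fvec& cw, bool training,
                         bool with_decoder, std::mt19937& rng, FwdState& st) {
  // caches are kept across calls so buffers are reused sample to sample
  if ((int)st.cc.size() != net.n_conv()) {
    st.cc.assign(net.n_conv(), ConvCache());
    st.poolidx.assign(net.S - 1, umat());
    st.upmaps.assign(net.S - 1, uvec());
  }
  st.dims.clear();

  Dims d = net.d0;
  fmat cur(x);  // V x 1
  int li = 0;
  for (int s = 0; s < net.S; ++s) {
    st.dims.push_back(d);
    cur = block_fwd(net, li, cur, d, training, rng, st.cc[li]); ++li;
    cur = block_fwd(net, li, cur, d, training, rng, st.cc[li]); ++li;
    if (s < net.S - 1) {
      cur = maxpool_fwd(cur, d, st.poolidx[s]);
      d = halve(d);
    }
  }
  // classifier head on flattened bottleneck
  st.z = vectorise(cur);
  st.logits = (net.Wh.t() * st.z) + net.bh.t();
  fvec e = exp(st.logits - st.logits.max());
  st.probs = e / accu(e);
  if (y >= 0) {
    double py = std::max((double)st.probs(y), 1e-12);
    st.class_term = -(double)cw(y) * std::log(py);
  }
  if (with_decoder) {
    // decoder mirrors the encoder: upsample x2, then the stage's conv block
    for (int s = net.S; s >= 2; --s) {
      st.upmaps[net.S - s] = upsample_map(d);
      cur = cur.rows(st.upmaps[net.S - s]);
      d = Dims{2 * d.nx, 2 * d.ny, 2 * d.nz};
      cur = block_fwd(net, li, cur, d, training, rng, st.cc[li]); ++li;
      cur = block_fwd(net, li, cur, d, training, rng, st.cc[li]); ++li;
    }
    // linear output projection back to one channel
    ConvCache& oc = st.cc[li];
    oc.d = d; oc.cin = cur.n_cols;
    im2col3(cur, d, oc.A);
    fmat rec = oc.A * net.conv[li].W;
    rec.each_row() += net.conv[li].b;
    st.recon = rec.col(0);
    fvec diff = st.recon - x;
    st.recon_mse = dot(diff, diff) / (double)diff.n_elem;
  }
  st.total = (1.0 - lambda) * st.recon_mse + lambda * st.class_term;
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<frowvec> db;
  fmat dWh;
  frowvec dbh;
  void zero(const Net& n) {
    dW.resize(n.conv.size());
    db.resize(n.conv.size());
    for (size_t i = 0; i < n.conv.size(); ++i) {
      dW[i].zeros(n.conv[i].W.n_rows, n.conv[i].W.n_cols);
      db[i].zeros(n.conv[i].b.n_elem);
    }
    dWh.zeros(n.Wh.n_rows, n.Wh.n_cols);
    dbh.zeros(n.bh.n_elem);
  }
};

static void backward_full(const Net& net, FwdState& st, const fvec& x, int y,
                          double lambda, const fvec& cw, Grads& g) {
  int li = net.n_conv() - 1;
  // reconstruction branch
  Dims d = net.d0;
  fvec dr = conv_to<fvec>::from(2.0 * (1.0 - lambda) / (double)x.n_elem *
                                (conv_to<vec>::from(st.recon) - conv_to<vec>::from(x)));
  // output conv (linear, no activation/dropout)
  fmat G(dr);
  ConvCache& oc = st.cc[li];
  g.dW[li] += oc.A.t() * G;
  g.db[li] += sum(G, 0);
  fmat dA = G * net.conv[li].W.t();
  fmat dcur;
  col2im3(dA, oc.d, oc.cin, dcur);
  --li;
  // decoder blocks in reverse (fwd order was s = S..2: up, block, block)
  for (int s = 2; s <= net.S; ++s) {
    dcur = block_bwd(net, li, st.cc[li], dcur, g.dW[li], g.db[li], true, false); --li;
    dcur = block_bwd(net, li, st.cc[li], dcur, g.dW[li], g.db[li], true, false); --li;
    // upsample backward: sum the 8 children into each parent
    const uvec& map = st.upmaps[net.S - s];
    fmat acc(map.max() + 1, dcur.n_cols, fill::zeros);
    for (uword c = 0; c < dcur.n_cols; ++c) {
      float* a = acc.colptr(c);
      const float* gc = dcur.colptr(c);
      for (uword o = 0; o < map.n_elem; ++o) a[map(o)] += gc[o];
    }
    dcur = acc;
  }
  // classifier head
  fvec dlogits = st.probs;
  dlogits(y) -= 1.0f;
  dlogits *= (float)(lambda * cw(y));
  g.dWh += st.z * dlogits.t();
  g.dbh += dlogits.t();
  fvec dz = net.Wh * dlogits;
  // bottleneck gradient = decoder path + classifier path
  fmat dbot(dz.memptr(), dcur.n_rows, dcur.n_cols);
  dcur += dbot;
  // encoder in reverse; the pool between stages s-1 and s scatters back to
  // the finer grid st.dims[s-2]
  li = 2 * net.S - 1;
  for (int s = net.S; s >= 1; --s) {
    bool need = (s > 1);  // input gradient not needed for training
    dcur = block_bwd(net, li, st.cc[li], dcur, g.dW[li], g.db[li], true, false); --li;
    dcur = block_bwd(net, li, st.cc[li], dcur, g.dW[li], g.db[li], need, false); --li;
    if (s > 1)
      dcur = maxpool_bwd(dcur, st.poolidx[s - 2], st.dims[s - 2], dcur.n_cols);
  }
}

// ---------------------------------------------------------------------------
// Adam
// ---------------------------------------------------------------------------

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<frowvec> mb, vb;
  fmat mWh, vWh;
  frowvec mbh, vbh;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& n) {
    mW.resize(n.conv.size()); vW.resize(n.conv.size());
    mb.resize(n.conv.size()); vb.resize(n.conv.size());
    for (size_t i = 0; i < n.conv.size(); ++i) {
      mW[i].zeros(size(n.conv[i].W)); vW[i].zeros(size(n.conv[i].W));
      mb[i].zeros(n.conv[i].b.n_elem); vb[i].zeros(n.conv[i].b.n_elem);
    }
    mWh.zeros(size(n.Wh)); vWh.zeros(size(n.Wh));
    mbh.zeros(n.bh.n_elem); vbh.zeros(n.bh.n_elem);
  }
  template <typename M>
  void upd(M& w, M& m, M& v, const M& g, double lr) {
    m = (float)b1 * m + (float)(1.0 - b1) * g;
    v = (float)b2 * v + (float)(1.0 - b2) * (g % g);
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    w -= (float)(lr / c1) * (m / (sqrt(v / (float)c2) + (float)eps));
  }
  void step(Net& n, const Grads& g, double lr) {
    ++t;
    for (size_t i = 0; i < n.conv.size(); ++i) {
      upd(n.conv[i].W, mW[i], vW[i], g.dW[i], lr);
      upd(n.conv[i].b, mb[i], vb[i], g.db[i], lr);
    }
    upd(n.Wh, mWh, vWh, g.dWh, lr);
    upd(n.bh, mbh, vbh, g.dbh, lr);
  }
};

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_csae_train(const arma::mat& Xtr, const Rcpp::IntegerVector& ytr,
                          Rcpp::Nullable<Rcpp::NumericMatrix> Xval_,
                          Rcpp::Nullable<Rcpp::IntegerVector> yval_,
                          const Rcpp::List& weights, const Rcpp::List& config,
                          const Rcpp::List& settings,
                          const arma::vec& class_weights) {
  Net net = net_from_r(weights, config);
  const int epochs = Rcpp::as<int>(settings["epochs"]);
  const int bs = Rcpp::as<int>(settings["batch_size"]);
  const double lr = Rcpp::as<double>(settings["learning_rate"]);
  const double lambda = Rcpp::as<double>(settings["lambda_weight"]);
  const unsigned seed = (unsigned)Rcpp::as<int>(settings["seed"]);
  const bool verbose = settings.containsElementNamed("verbose") ?
      Rcpp::as<bool>(settings["verbose"]) : false;

  fmat X = conv_to<fmat>::from(Xtr);
  const int n = X.n_cols;
  if ((int)ytr.size() != n) Rcpp::stop("length(y) != ncol(x)");
  fvec cw = conv_to<fvec>::from(class_weights);

  fmat Xv;
  std::vector<int> yv;
  bool has_val = Xval_.isNotNull() && yval_.isNotNull();
  if (has_val) {
    Xv = conv_to<fmat>::from(Rcpp::as<mat>(Xval_.get()));
    Rcpp::IntegerVector tmp(yval_.get());
    yv.assign(tmp.begin(), tmp.end());
  }

  std::mt19937 rng(seed);
  Adam opt;
  opt.init(net);
  Grads g;
  FwdState st;

  mat history(epochs, 7);
  history.fill(datum::nan);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_rec = 0, tr_cls = 0, tr_tot = 0;
    for (int start = 0; start < n; start += bs) {
      int stop_ = std::min(start + bs, n);
      g.zero(net);
      for (int i = start; i < stop_; ++i) {
        int idx = order[i];
        fvec x = X.col(idx);
        int y = ytr[idx] - 1;
        forward_full(net, x, y, lambda, cw, true, true, rng, st);
        if (!std::isfinite(st.total))
          Rcpp::stop("non-finite training loss at epoch %d, sample %d "
                     "(recon=%g, class=%g); try a lower learning rate",
                     ep + 1, idx + 1, st.recon_mse, st.class_term);
        tr_rec += st.recon_mse; tr_cls += st.class_term; tr_tot += st.total;
        backward_full(net, st, x, y, lambda, cw, g);
      }
      // mean gradient over the batch
      double sc = 1.0 / (double)(stop_ - start);
      for (size_t l = 0; l < g.dW.size(); ++l) { g.dW[l] *= sc; g.db[l] *= sc; }
      g.dWh *= sc; g.dbh *= sc;
      opt.step(net, g, lr);
      Rcpp::checkUserInterrupt();
    }
    history(ep, 0) = ep + 1;
    history(ep, 1) = tr_rec / n;
    history(ep, 2) = tr_cls / n;
    history(ep, 3) = tr_tot / n;
    if (has_val) {
      double v_rec = 0, v_cls = 0, v_tot = 0;
      for (uword i = 0; i < Xv.n_cols; ++i) {
        fvec x = Xv.col(i);
        forward_full(net, x, yv[i] - 1, lambda, cw, false, true, rng, st);
        v_rec += st.recon_mse; v_cls += st.class_term; v_tot += st.total;
      }
      history(ep, 4) = v_rec / Xv.n_cols;
      history(ep, 5) = v_cls / Xv.n_cols;
      history(ep, 6) = v_tot / Xv.n_cols;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " train total "
                  << history(ep, 3) << "\n";
  }

  return Rcpp::List::create(Rcpp::Named("weights") = net_to_r(net),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
Rcpp::List cpp_csae_forward(const arma::mat& Xnew, const Rcpp::List& weights,
                            const Rcpp::List& config, bool return_recon) {
  Net net = net_from_r(weights, config);
  fmat X = conv_to<fmat>::from(Xnew);
  const int n = X.n_cols;
  mat logits(n, net.K), probs(n, net.K);
  vec recon_mse(n);
  mat recon;
  if (return_recon) recon.set_size(X.n_rows, n);
  std::mt19937 rng(0);
  FwdState st;
  fvec cw(net.K, fill::ones);
  for (int i = 0; i < n; ++i) {
    fvec x = X.col(i);
    forward_full(net, x, -1, 0.5, cw, false, true, rng, st);
    logits.row(i) = conv_to<rowvec>::from(st.logits.t());
    probs.row(i) = conv_to<rowvec>::from(st.probs.t());
    recon_mse(i) = st.recon_mse;
    if (return_recon) recon.col(i) = conv_to<vec>::from(st.recon);
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("logits") = logits,
                                      Rcpp::Named("probs") = probs,
                                      Rcpp::Named("recon_mse") = recon_mse);
  if (return_recon) out["recon"] = recon;
  return out;
}

// loss and full analytic gradient for one sample, evaluation mode (no
// dropout); used by finite-difference checks in the test suite.
// [[Rcpp::export]]
Rcpp::List cpp_csae_loss_grad(const arma::vec& x, int y, const Rcpp::List& weights,
                              const Rcpp::List& config, double lambda,
                              const arma::vec& class_weights) {
  Net net = net_from_r(weights, config);
  fvec xf = conv_to<fvec>::from(x);
  fvec cw = conv_to<fvec>::from(class_weights);
  std::mt19937 rng(0);
  FwdState st;
  forward_full(net, xf, y - 1, lambda, cw, false, true, rng, st);
  Grads g;
  g.zero(net);
  backward_full(net, st, xf, y - 1, lambda, cw, g);
  Rcpp::List convs(g.dW.size());
  for (size_t i = 0; i < g.dW.size(); ++i)
    convs[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(g.dW[i]),
        Rcpp::Named("b") = conv_to<rowvec>::from(g.db[i]));
  return Rcpp::List::create(
      Rcpp::Named("total") = st.total,
      Rcpp::Named("reconstruction_term") = st.recon_mse,
      Rcpp::Named("classification_term") = st.class_term,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("conv") = convs,
          Rcpp::Named("head") = Rcpp::List::create(
              Rcpp::Named("W") = conv_to<mat>::from(g.dWh),
              Rcpp::Named("b") = conv_to<rowvec>::from(g.dbh))));
}

// guided backpropagation: gradient of the target-class score (logit) w.r.t.
// the input, with the guided gate at every LeakyReLU of the encoder.  The
// decoder has no path into the class score, so only the encoder is traversed.
// [[Rcpp::export]]
arma::vec cpp_guided_backprop(const arma::vec& x, int target,
                              const Rcpp::List& weights, const Rcpp::List& config) {
  Net net = net_from_r(weights, config);
  if (target < 1 || target > net.K) Rcpp::stop("invalid target class index");
  fvec xf = conv_to<fvec>::from(x);
  std::mt19937 rng(0);
  FwdState st;
  fvec cw(net.K, fill::ones);
  forward_full(net, xf, -1, 0.0, cw, false, false, rng, st);

  // d(logit_target)/dz
  fvec dz = net.Wh.col(target - 1);
  int li = 2 * net.S - 1;
  Dims d = net.d0;
  // bottleneck dims/channels
  int Cb = net.ch[net.S - 1];
  fmat dcur(dz.memptr(), dz.n_elem / Cb, Cb);
  fmat dummyW;
  frowvec dummyb;
  for (int s = net.S; s >= 1; --s) {
    dcur = block_bwd(net, li, st.cc[li], dcur, dummyW, dummyb, true, true); --li;
    dcur = block_bwd(net, li, st.cc[li], dcur, dummyW, dummyb, true, true); --li;
    if (s > 1)
      dcur = maxpool_bwd(dcur, st.poolidx[s - 2], st.dims[s - 2], dcur.n_cols);
  }
  return conv_to<vec>::from(dcur.col(0));
}
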