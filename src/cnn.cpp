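// Compact CNN engine for the multimodal spectral-tensor classifier.
//
// Geometry: feature maps are stored channel-major as C x Ncol float
// matrices, where columns enumerate zero-padded spatial positions
// ((H+2) x (W+2) per sample, samples concatenated).  3x3 "same"
// convolutions are computed as 9 shifted GEMMs against the padded map,
// which keeps all heavy arithmetic inside single-threaded BLAS and
// avoids an im2col buffer.  Kernel offset j = (dw+1)*3 + (dh+1) selects
// weight columns [j*Cin, (j+1)*Cin) of a Cout x 9*Cin weight matrix.
//
// The network topology is fixed: two 2-conv stems (amplitude / phase
// branches), channel concatenation, an optional post-stem pool, a trunk
// of 3x3 conv layers with max-pools after configured layers, flatten,
// concatenation of the 2-element age/sex vector, and dense layers
// 128 -> 32 -> 1 with a sigmoid output.  All parameters live in an R
// list so that initialisation, checkpointing and serialisation stay on
// the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct PoolSpec { int ph, pw; };

struct Arch {
  int H0, W0;            // input map extent (leads x frequency bins)
  int stem_ch;
  std::vector<int> trunk_ch;
  PoolSpec stem_pool;               // after concat; {1,1} = none
  std::vector<PoolSpec> pool_after; // per trunk conv; {1,1} = none
  int d1, d2;                       // dense widths (output is 1)
};

Arch parse_arch(const Rcpp::List& a) {
  Arch out;
  out.H0 = Rcpp::as<int>(a["n_leads"]);
  out.W0 = Rcpp::as<int>(a["n_freq"]);
  out.stem_ch = Rcpp::as<int>(a["stem_channels"]);
  out.trunk_ch = Rcpp::as<std::vector<int>>(a["trunk_channels"]);
  Rcpp::IntegerVector sp = a["stem_pool"];
  out.stem_pool = {sp[0], sp[1]};
  Rcpp::IntegerMatrix pa = a["pool_after"];
  for (int i = 0; i < pa.nrow(); ++i)
    out.pool_after.push_back({pa(i, 0), pa(i, 1)});
  Rcpp::IntegerVector du = a["dense_units"];
  out.d1 = du[0]; out.d2 = du[1];
  if ((int)out.pool_after.size() != (int)out.trunk_ch.size())
    Rcpp::stop("pool_after must have one row per trunk conv layer");
  return out;
}

inline int pad_cols(int H, int W, int B) { return (H + 2) * (W + 2) * B; }
inline int pcol(int H, int W, int b, int h, int w) {
  // h, w are interior coordinates in [0, H) x [0, W)
  return b * (H + 2) * (W + 2) + (w + 1) * (H + 2) + (h + 1);
}

void zero_pads(fmat& A, int H, int W, int B) {
  const int PS = (H + 2) * (W + 2), Hp = H + 2;
  for (int b = 0; b < B; ++b) {
    A.cols(b * PS, b * PS + Hp - 1).zeros();             // w = 0 strip
    A.cols(b * PS + (W + 1) * Hp, (b + 1) * PS - 1).zeros(); // w = W+1 strip
    for (int w = 1; w <= W; ++w) {
      A(span::all, b * PS + w * Hp) *= 0.0f;             // h = 0
      A(span::all, b * PS + w * Hp + Hp - 1) *= 0.0f;    // h = H+1
    }
  }
}

// Scatter an unpadded C x (H*W*B) matrix into padded layout.
fmat to_padded(const fmat& X, int H, int W, int B) {
  fmat A(X.n_rows, pad_cols(H, W, B), fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      A.cols(pcol(H, W, b, 0, w), pcol(H, W, b, H - 1, w)) =
        X.cols((size_t)(b * W + w) * H, (size_t)(b * W + w) * H + H - 1);
  return A;
}

// offsets for kernel position j = (dw+1)*3 + (dh+1)
inline int koffset(int j, int Hp) {
  int dh = j % 3 - 1, dw = j / 3 - 1;
  return dw * Hp + dh;
}

// Y = relu(conv(A) + b) in padded layout.  A has pads zeroed.
fmat conv_forward(const fmat& A, const fmat& W, const fvec& bias,
                  int H, int Wd, int B) {
  const int Cin = A.n_rows, N = A.n_cols, Hp = H + 2;
  fmat Y(W.n_rows, N, fill::zeros);
  for (int j = 0; j < 9; ++j) {
    const int off = koffset(j, Hp);
    const fmat Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
    const int lo = std::max(0, -off), hi = N - 1 - std::max(0, off);
    Y.cols(lo, hi) += Wj * A.cols(lo + off, hi + off);
  }
  Y.each_col() += bias;
  Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  zero_pads(Y, H, Wd, B);
  return Y;
}

// Backward through relu(conv(.) + b).  dY is the gradient at the layer
// output (pads zero); Y the stored output; Ain the stored input.
void conv_backward(const fmat& dY, const fmat& Y, const fmat& Ain,
                   const fmat& W, int H, int Wd, int B,
                   fmat& dW, fvec& db, fmat& dAin, bool need_dAin) {
  const int Cin = Ain.n_rows, N = Ain.n_cols, Hp = H + 2;
  fmat dZ = dY % conv_to<fmat>::from(Y > 0.0f);
  db = sum(dZ, 1);
  dW.set_size(W.n_rows, W.n_cols);
  if (need_dAin) dAin.zeros(Cin, N);
  for (int j = 0; j < 9; ++j) {
    const int off = koffset(j, Hp);
    const int lo = std::max(0, -off), hi = N - 1 - std::max(0, off);
    dW.cols(j * Cin, (j + 1) * Cin - 1) =
      dZ.cols(lo, hi) * Ain.cols(lo + off, hi + off).t();
    if (need_dAin) {
      const fmat Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
      dAin.cols(lo + off, hi + off) += Wj.t() * dZ.cols(lo, hi);
    }
  }
  if (need_dAin) zero_pads(dAin, H, Wd, B);
}

struct PoolCache { umat src; int Hi, Wi, Ho, Wo; };

// Max-pool ph x pw on padded maps; returns padded output.
fmat pool_forward(const fmat& A, int H, int Wd, int B, PoolSpec p,
                  PoolCache& cache) {
  if (p.ph == 1 && p.pw == 1) { cache.Ho = -1; return A; }
  const int Ho = H / p.ph, Wo = Wd / p.pw, C = A.n_rows;
  fmat Y(C, pad_cols(Ho, Wo, B), fill::zeros);
  cache.src.set_size(C, (size_t)Ho * Wo * B);
  cache.Hi = H; cache.Wi = Wd; cache.Ho = Ho; cache.Wo = Wo;
  size_t k = 0;
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho, ++k) {
        const int oc = pcol(Ho, Wo, b, ho, wo);
        for (int c = 0; c < C; ++c) {
          float best = -std::numeric_limits<float>::infinity();
          int bestcol = -1;
          for (int dw = 0; dw < p.pw; ++dw)
            for (int dh = 0; dh < p.ph; ++dh) {
              const int ic = pcol(H, Wd, b, ho * p.ph + dh, wo * p.pw + dw);
              if (A(c, ic) > best) { best = A(c, ic); bestcol = ic; }
            }
          Y(c, oc) = best;
          cache.src(c, k) = bestcol;
        }
      }
  return Y;
}

fmat pool_backward(const fmat& dY, const fmat& Ain, int B,
                   const PoolCache& cache) {
  if (cache.Ho < 0) return dY;
  const int C = dY.n_rows;
  fmat dA(C, Ain.n_cols, fill::zeros);
  size_t k = 0;
  for (int b = 0; b < B; ++b)
    for (int wo = 0; wo < cache.Wo; ++wo)
      for (int ho = 0; ho < cache.Ho; ++ho, ++k) {
        const int oc = pcol(cache.Ho, cache.Wo, b, ho, wo);
        for (int c = 0; c < C; ++c)
          dA(c, cache.src(c, k)) += dY(c, oc);
      }
  return dA;
}

// ---- parameter bundle -------------------------------------------------

struct Params {
  std::vector<fmat> convW;  // 18: amp1, amp2, pha1, pha2, trunk 1..14
  std::vector<fvec> convB;
  fmat W1, W2, W3;
  fvec b1, b2, b3;
};

Params params_from_list(const Rcpp::List& pl) {
  Params p;
  const Rcpp::List conv = pl["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List layer = conv[i];
    p.convW.push_back(conv_to<fmat>::from(Rcpp::as<mat>(layer["W"])));
    p.convB.push_back(conv_to<fvec>::from(Rcpp::as<vec>(layer["b"])));
  }
  const Rcpp::List dense = pl["dense"];
  Rcpp::List d1 = dense[0], d2 = dense[1], d3 = dense[2];
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(d1["W"]));
  p.b1 = conv_to<fvec>::from(Rcpp::as<vec>(d1["b"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(d2["W"]));
  p.b2 = conv_to<fvec>::from(Rcpp::as<vec>(d2["b"]));
  p.W3 = conv_to<fmat>::from(Rcpp::as<mat>(d3["W"]));
  p.b3 = conv_to<fvec>::from(Rcpp::as<vec>(d3["b"]));
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  Rcpp::List conv(p.convW.size());
  for (size_t i = 0; i < p.convW.size(); ++i)
    conv[i] = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(p.convW[i]),
      Rcpp::Named("b") = conv_to<vec>::from(p.convB[i]));
  Rcpp::List dense = Rcpp::List::create(
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(p.W1),
                       Rcpp::Named("b") = conv_to<vec>::from(p.b1)),
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(p.W2),
                       Rcpp::Named("b") = conv_to<vec>::from(p.b2)),
    Rcpp::List::create(Rcpp::Named("W") = conv_to<mat>::from(p.W3),
                       Rcpp::Named("b") = conv_to<vec>::from(p.b3)));
  return Rcpp::List::create(Rcpp::Named("conv") = conv,
                            Rcpp::Named("dense") = dense);
}

// ---- forward / backward over the whole net ---------------------------

struct Cache {
  // activations in padded layout, in forward order
  std::vector<fmat> acts;       // stored layer outputs
  std::vector<fmat> stem_in;    // padded amp / phase inputs
  std::vector<int> actH, actW;  // interior extents per stored activation
  fmat ampS1, ampS2, phaS1, phaS2, cat;
  int catH, catW;
  std::vector<fmat> trunk;      // output of each trunk conv (post relu)
  std::vector<fmat> pooled;     // after optional pool of each trunk conv
  std::vector<PoolCache> pc;    // per trunk conv
  PoolCache stem_pc;
  fmat stem_pooled;
  int Hf, Wf;                   // final map extent
  fmat X;                       // flatten + meta, D x B
  fmat Z1, Z2;
  frowvec logit, prob;
};

// xamp/xpha: (H0*W0) x B unpadded, column-major with h fastest.
void forward(const Arch& a, const Params& p, const fmat& xamp,
             const fmat& xpha, const fmat& meta, int B, Cache& c,
             bool keep = true) {
  // reshape inputs: rows = 1 channel, cols = spatial
  fmat amp0 = to_padded(reshape(xamp, 1, (size_t)a.H0 * a.W0 * B),
                        a.H0, a.W0, B);
  fmat pha0 = to_padded(reshape(xpha, 1, (size_t)a.H0 * a.W0 * B),
                        a.H0, a.W0, B);
  c.stem_in = {amp0, pha0};
  c.ampS1 = conv_forward(amp0, p.convW[0], p.convB[0], a.H0, a.W0, B);
  c.ampS2 = conv_forward(c.ampS1, p.convW[1], p.convB[1], a.H0, a.W0, B);
  c.phaS1 = conv_forward(pha0, p.convW[2], p.convB[2], a.H0, a.W0, B);
  c.phaS2 = conv_forward(c.phaS1, p.convW[3], p.convB[3], a.H0, a.W0, B);
  c.cat = join_cols(c.ampS2, c.phaS2);
  c.catH = a.H0; c.catW = a.W0;
  c.stem_pooled = pool_forward(c.cat, a.H0, a.W0, B, a.stem_pool, c.stem_pc);
  int H = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1) ? a.H0
                                                       : a.H0 / a.stem_pool.ph;
  int Wd = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1) ? a.W0
                                                        : a.W0 / a.stem_pool.pw;
  const int nt = a.trunk_ch.size();
  c.trunk.assign(nt, fmat());
  c.pooled.assign(nt, fmat());
  c.pc.assign(nt, PoolCache());
  const fmat* in = &c.stem_pooled;
  for (int i = 0; i < nt; ++i) {
    c.trunk[i] = conv_forward(*in, p.convW[4 + i], p.convB[4 + i], H, Wd, B);
    c.pooled[i] = pool_forward(c.trunk[i], H, Wd, B, a.pool_after[i], c.pc[i]);
    if (c.pc[i].Ho >= 0) { H = c.pc[i].Ho; Wd = c.pc[i].Wo; }
    in = &c.pooled[i];
  }
  c.Hf = H; c.Wf = Wd;
  // flatten interior + meta
  const fmat& last = c.pooled[nt - 1];
  const int C = last.n_rows, D = C * H * Wd;
  c.X.set_size(D + meta.n_rows, B);
  for (int b = 0; b < B; ++b) {
    size_t k = 0;
    for (int w = 0; w < Wd; ++w)
      for (int h = 0; h < H; ++h, k += C)
        c.X.col(b).subvec(k, k + C - 1) = last.col(pcol(H, Wd, b, h, w));
    c.X.col(b).subvec(D, D + meta.n_rows - 1) = meta.col(b);
  }
  c.Z1 = p.W1 * c.X; c.Z1.each_col() += p.b1;
  c.Z1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.Z2 = p.W2 * c.Z1; c.Z2.each_col() += p.b2;
  c.Z2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.logit = conv_to<frowvec>::from(p.W3 * c.Z2) + p.b3(0);
  c.prob = 1.0f / (1.0f + exp(-c.logit));
  (void)keep;
}

struct Grads {
  std::vector<fmat> convW;
  std::vector<fvec> convB;
  fmat W1, W2, W3;
  fvec b1, b2, b3;
};

// dlogit: 1 x B gradient at the logit.  If cam_layer >= 0 the gradient
// at that conv layer's post-relu output is stored in cam_grad and the
// backward pass stops there (no parameter gradients are needed then).
// cam_layer indexes convs as 0,1 = amp stem, 4..17-like trunk offset
// handled by caller: here 0/1 = amp stem, >= 2 means trunk conv (i-2).
void backward(const Arch& a, const Params& p, const Cache& c,
              const frowvec& dlogit, int B, Grads& g,
              int cam_layer = -1, fmat* cam_grad = nullptr) {
  const int nt = a.trunk_ch.size();
  const bool for_cam = cam_layer >= 0;
  g.convW.assign(18, fmat());
  g.convB.assign(18, fvec());
  // dense
  fmat dZ2 = p.W3.t() * fmat(dlogit);
  dZ2 %= conv_to<fmat>::from(c.Z2 > 0.0f);
  g.W3 = fmat(dlogit) * c.Z2.t(); g.b3 = fvec(1); g.b3(0) = accu(dlogit);
  fmat dZ1 = p.W2.t() * dZ2;
  dZ1 %= conv_to<fmat>::from(c.Z1 > 0.0f);
  g.W2 = dZ2 * c.Z1.t(); g.b2 = sum(dZ2, 1);
  fmat dX = p.W1.t() * dZ1;
  g.W1 = dZ1 * c.X.t(); g.b1 = sum(dZ1, 1);
  // unflatten
  const fmat& last = c.pooled[nt - 1];
  const int C = last.n_rows, H = c.Hf, Wd = c.Wf;
  fmat dLast(C, last.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b) {
    size_t k = 0;
    for (int w = 0; w < Wd; ++w)
      for (int h = 0; h < H; ++h, k += C)
        dLast.col(pcol(H, Wd, b, h, w)) = dX.col(b).subvec(k, k + C - 1);
  }
  // trunk, reverse
  fmat d = dLast;
  for (int i = nt - 1; i >= 0; --i) {
    // through pool
    d = pool_backward(d, c.trunk[i], B, c.pc[i]);
    // recompute this layer's extents by walking the pool schedule
    int He = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1)
                 ? a.H0 : a.H0 / a.stem_pool.ph;
    int We = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1)
                 ? a.W0 : a.W0 / a.stem_pool.pw;
    for (int q = 0; q < i; ++q)
      if (c.pc[q].Ho >= 0) { He = c.pc[q].Ho; We = c.pc[q].Wo; }
    if (for_cam && cam_layer == 2 + i) {
      *cam_grad = d;
      return;
    }
    const fmat& in = (i == 0) ? c.stem_pooled : c.pooled[i - 1];
    fmat dIn;
    conv_backward(d, c.trunk[i], in, p.convW[4 + i], He, We, B,
                  g.convW[4 + i], g.convB[4 + i], dIn,
                  i > 0 || true);
    d = dIn;
  }
  // through stem pool
  d = pool_backward(d, c.cat, B, c.stem_pc);
  // split channels
  const int S = a.stem_ch;
  fmat dAmp2 = d.rows(0, S - 1), dPha2 = d.rows(S, 2 * S - 1);
  if (for_cam && cam_layer == 1) { *cam_grad = dAmp2; return; }
  fmat dAmp1;
  conv_backward(dAmp2, c.ampS2, c.ampS1, p.convW[1], a.H0, a.W0, B,
                g.convW[1], g.convB[1], dAmp1, true);
  if (for_cam && cam_layer == 0) { *cam_grad = dAmp1; return; }
  fmat dumA;
  conv_backward(dAmp1, c.ampS1, c.stem_in[0], p.convW[0], a.H0, a.W0, B,
                g.convW[0], g.convB[0], dumA, false);
  fmat dPha1, dumP;
  conv_backward(dPha2, c.phaS2, c.phaS1, p.convW[3], a.H0, a.W0, B,
                g.convW[3], g.convB[3], dPha1, true);
  conv_backward(dPha1, c.phaS1, c.stem_in[1], p.convW[2], a.H0, a.W0, B,
                g.convW[2], g.convB[2], dumP, false);
}

// ---- Adam ------------------------------------------------------------

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mB, vB;
  fmat mW1, vW1, mW2, vW2, mW3, vW3;
  fvec mb1, vb1, mb2, vb2, mb3, vb3;
  long t = 0;
  void init(const Params& p) {
    for (auto& w : p.convW) { mW.push_back(zeros<fmat>(size(w)));
                              vW.push_back(zeros<fmat>(size(w))); }
    for (auto& b : p.convB) { mB.push_back(zeros<fvec>(size(b)));
                              vB.push_back(zeros<fvec>(size(b))); }
    mW1 = zeros<fmat>(size(p.W1)); vW1 = mW1;
    mW2 = zeros<fmat>(size(p.W2)); vW2 = mW2;
    mW3 = zeros<fmat>(size(p.W3)); vW3 = mW3;
    mb1 = zeros<fvec>(size(p.b1)); vb1 = mb1;
    mb2 = zeros<fvec>(size(p.b2)); vb2 = mb2;
    mb3 = zeros<fvec>(size(p.b3)); vb3 = mb3;
  }
  template <typename T>
  void upd1(T& w, const T& g, T& m, T& v, float lr) {
    const float b1c = 1.0f - std::pow(0.9f, (float)t);
    const float b2c = 1.0f - std::pow(0.999f, (float)t);
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    w -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-7f);
  }
  void step(Params& p, const Grads& g, float lr) {
    ++t;
    for (size_t i = 0; i < p.convW.size(); ++i) {
      upd1(p.convW[i], g.convW[i], mW[i], vW[i], lr);
      upd1(p.convB[i], g.convB[i], mB[i], vB[i], lr);
    }
    upd1(p.W1, g.W1, mW1, vW1, lr); upd1(p.b1, g.b1, mb1, vb1, lr);
    upd1(p.W2, g.W2, mW2, vW2, lr); upd1(p.b2, g.b2, mb2, vb2, lr);
    upd1(p.W3, g.W3, mW3, vW3, lr); upd1(p.b3, g.b3, mb3, vb3, lr);
  }
};

fmat pick_cols(const fmat& X, const std::vector<int>& idx) {
  fmat out(X.n_rows, idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out.col(i) = X.col(idx[i]);
  return out;
}

double bce(const frowvec& prob, const fvec& y) {
  double s = 0.0;
  for (size_t i = 0; i < y.n_elem; ++i) {
    const double p = std::min(std::max((double)prob(i), 1e-7), 1.0 - 1e-7);
    s += y(i) > 0.5 ? -std::log(p) : -std::log(1.0 - p);
  }
  return s / y.n_elem;
}

double eval_loss(const Arch& a, const Params& p, const fmat& xamp,
                 const fmat& xpha, const fmat& meta, const fvec& y,
                 const std::vector<int>& idx) {
  const int chunk = 64;
  double s = 0.0;
  for (size_t lo = 0; lo < idx.size(); lo += chunk) {
    const size_t hi = std::min(idx.size(), lo + chunk);
    std::vector<int> sub(idx.begin() + lo, idx.begin() + hi);
    Cache c;
    forward(a, p, pick_cols(xamp, sub), pick_cols(xpha, sub),
            pick_cols(meta, sub), sub.size(), c);
    fvec ys(sub.size());
    for (size_t i = 0; i < sub.size(); ++i) ys(i) = y(sub[i]);
    s += bce(c.prob, ys) * sub.size();
  }
  return s / idx.size();
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::List params, Rcpp::List arch,
                                    Rcpp::NumericMatrix xamp,
                                    Rcpp::NumericMatrix xpha,
                                    Rcpp::NumericMatrix meta) {
  const Arch a = parse_arch(arch);
  const Params p = params_from_list(params);
  const int n = xamp.ncol();
  fmat XA = conv_to<fmat>::from(Rcpp::as<mat>(xamp));
  fmat XP = conv_to<fmat>::from(Rcpp::as<mat>(xpha));
  fmat M = conv_to<fmat>::from(Rcpp::as<mat>(meta));
  Rcpp::NumericVector out(n);
  const int chunk = 64;
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(n, lo + chunk);
    Cache c;
    forward(a, p, XA.cols(lo, hi - 1), XP.cols(lo, hi - 1),
            M.cols(lo, hi - 1), hi - lo, c);
    for (int i = lo; i < hi; ++i) out[i] = c.prob(i - lo);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List params, Rcpp::List arch,
                         Rcpp::NumericMatrix xamp, Rcpp::NumericMatrix xpha,
                         Rcpp::NumericMatrix meta, Rcpp::NumericVector y,
                         Rcpp::IntegerVector train_idx,
                         Rcpp::IntegerVector val_idx,
                         int epochs, int batch, double lr, int seed) {
  const Arch a = parse_arch(arch);
  Params p = params_from_list(params);
  fmat XA = conv_to<fmat>::from(Rcpp::as<mat>(xamp));
  fmat XP = conv_to<fmat>::from(Rcpp::as<mat>(xpha));
  fmat M = conv_to<fmat>::from(Rcpp::as<mat>(meta));
  fvec Y = conv_to<fvec>::from(Rcpp::as<vec>(y));
  std::vector<int> tr = Rcpp::as<std::vector<int>>(train_idx);
  std::vector<int> va = Rcpp::as<std::vector<int>>(val_idx);
  Adam opt; opt.init(p);
  std::mt19937 rng((unsigned)seed);
  std::vector<double> train_curve, val_curve;
  Params best = p;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0.0; long nseen = 0;
    for (size_t lo = 0; lo < tr.size(); lo += batch) {
      const size_t hi = std::min(tr.size(), lo + batch);
      std::vector<int> sub(tr.begin() + lo, tr.begin() + hi);
      const int B = sub.size();
      Cache c;
      forward(a, p, pick_cols(XA, sub), pick_cols(XP, sub),
              pick_cols(M, sub), B, c);
      fvec ys(B);
      for (int i = 0; i < B; ++i) ys(i) = Y(sub[i]);
      ep_loss += bce(c.prob, ys) * B; nseen += B;
      frowvec dlogit(B);
      for (int i = 0; i < B; ++i) dlogit(i) = (c.prob(i) - ys(i)) / B;
      Grads g;
      backward(a, p, c, dlogit, B, g);
      opt.step(p, g, (float)lr);
    }
    Rcpp::checkUserInterrupt();
    train_curve.push_back(ep_loss / nseen);
    const double vl = eval_loss(a, p, XA, XP, M, Y, va);
    val_curve.push_back(vl);
    if (vl < best_val) { best_val = vl; best = p; best_epoch = e + 1; }
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(best),
    Rcpp::Named("params_final") = params_to_list(p),
    Rcpp::Named("train_loss") = train_curve,
    Rcpp::Named("val_loss") = val_curve,
    Rcpp::Named("selected_epoch") = best_epoch);
}

// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::List params, Rcpp::List arch,
                        Rcpp::NumericMatrix xamp, Rcpp::NumericMatrix xpha,
                        Rcpp::NumericMatrix meta, Rcpp::NumericVector y) {
  // mean-BCE gradient over the batch, for optimiser-free gradient checks
  const Arch a = parse_arch(arch);
  const Params p = params_from_list(params);
  const int B = xamp.ncol();
  fmat XA = conv_to<fmat>::from(Rcpp::as<mat>(xamp));
  fmat XP = conv_to<fmat>::from(Rcpp::as<mat>(xpha));
  fmat M = conv_to<fmat>::from(Rcpp::as<mat>(meta));
  Cache c;
  forward(a, p, XA, XP, M, B, c);
  frowvec dlogit(B);
  for (int i = 0; i < B; ++i)
    dlogit(i) = (c.prob(i) - (float)y[i]) / B;
  Grads g;
  backward(a, p, c, dlogit, B, g);
  Params gp;
  gp.convW = g.convW; gp.convB = g.convB;
  gp.W1 = g.W1; gp.W2 = g.W2; gp.W3 = g.W3;
  gp.b1 = g.b1; gp.b2 = g.b2; gp.b3 = g.b3;
  fvec ys(B);
  for (int i = 0; i < B; ++i) ys(i) = y[i];
  Rcpp::List out = params_to_list(gp);
  out["loss"] = bce(c.prob, ys);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_gradcam_cpp(Rcpp::List params, Rcpp::List arch,
                           Rcpp::NumericMatrix xamp, Rcpp::NumericMatrix xpha,
                           Rcpp::NumericMatrix meta, int cam_layer) {
  // cam_layer: 0-based engine index (0,1 = amplitude stem convs,
  // 2..15 = trunk convs); caller maps the user-facing conv index.
  const Arch a = parse_arch(arch);
  const Params p = params_from_list(params);
  fmat XA = conv_to<fmat>::from(Rcpp::as<mat>(xamp));
  fmat XP = conv_to<fmat>::from(Rcpp::as<mat>(xpha));
  fmat M = conv_to<fmat>::from(Rcpp::as<mat>(meta));
  Cache c;
  forward(a, p, XA, XP, M, 1, c);
  frowvec dlogit(1); dlogit(0) = 1.0f;  // gradient of the raw logit
  Grads g; fmat cam_grad;
  backward(a, p, c, dlogit, 1, g, cam_layer, &cam_grad);
  // locate the stored activation and its extent
  fmat act;
  int H = a.H0, Wd = a.W0;
  if (cam_layer <= 1) {
    act = (cam_layer == 0) ? c.ampS1 : c.ampS2;
  } else {
    const int i = cam_layer - 2;
    act = c.trunk[i];
    H = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1) ? a.H0
                                                     : a.H0 / a.stem_pool.ph;
    Wd = (a.stem_pool.ph == 1 && a.stem_pool.pw == 1) ? a.W0
                                                      : a.W0 / a.stem_pool.pw;
    for (int q = 0; q < i; ++q)
      if (c.pc[q].Ho >= 0) { H = c.pc[q].Ho; Wd = c.pc[q].Wo; }
  }
  // strip padding, return H x W x C cubes
  const int C = act.n_rows;
  cube fmap(H, Wd, C), grad(H, Wd, C);
  for (int w = 0; w < Wd; ++w)
    for (int h = 0; h < H; ++h) {
      const int col = pcol(H, Wd, 0, h, w);
      for (int ch = 0; ch < C; ++ch) {
        fmap(h, w, ch) = act(ch, col);
        grad(h, w, ch) = cam_grad(ch, col);
      }
    }
  return Rcpp::List::create(
    Rcpp::Named("fmap") = fmap,
    Rcpp::Named("grad") = grad,
    Rcpp::Named("prob") = (double)c.prob(0),
    Rcpp::Named("logit") = (double)c.logit(0));
}
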