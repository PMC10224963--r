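// Compiled U-Net: encoder-decoder with skip connections, trained with the
// Tversky loss under Adam and a reduce-on-plateau schedule. Convolutions
// are 3x3 same-padded, realized as im2col + single-precision GEMM. Feature
// maps are stored channels x pixels with the minibatch concatenated along
// the pixel axis (pixel index b*H*W + r*W + c), so every layer is one GEMM
// over the whole batch. Single-threaded, fully determined by one seed.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

struct ConvSpec { int cin, cout, k; };

static std::vector<ConvSpec> conv_specs(int depth, int F, int Cin) {
  std::vector<ConvSpec> s;
  int c = Cin;
  for (int i = 0; i < depth; ++i) {
    int f = F << i;
    s.push_back({c, f, 3}); s.push_back({f, f, 3});
    c = f;
  }
  int fb = F << depth;
  s.push_back({c, fb, 3}); s.push_back({fb, fb, 3});
  for (int i = depth - 1; i >= 0; --i) {
    int f = F << i, fu = F << (i + 1);
    s.push_back({fu, f, 3});      // conv after nearest-neighbor upsample
    s.push_back({2 * f, f, 3});   // conv after skip concatenation
    s.push_back({f, f, 3});
  }
  s.push_back({F, 1, 1});         // final 1x1 -> sigmoid
  return s;
}

// ---- spatial primitives (batched along the pixel axis) ------------------

// grow-only scratch memory shared by all convolutions of one network pass
struct Workspace {
  std::vector<float> col, dcol;
  fmat as_col(int rows, size_t cols) {
    if (col.size() < (size_t)rows * cols) col.resize((size_t)rows * cols);
    return fmat(col.data(), rows, cols, false, true);
  }
  fmat as_dcol(int rows, size_t cols) {
    if (dcol.size() < (size_t)rows * cols) dcol.resize((size_t)rows * cols);
    return fmat(dcol.data(), rows, cols, false, true);
  }
};

static void im2col3(const fmat &X, int H, int W, int B, fmat &col) {
  const int C = X.n_rows, P = H * W;
  for (int b = 0; b < B; ++b) {
    const int o = b * P;
    int k = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc, ++k) {
        const int r_lo = std::max(0, -dr), r_hi = std::min(H, H - dr);
        const int c_lo = std::max(0, -dc), c_hi = std::min(W, W - dc);
        for (int r = 0; r < H; ++r) {
          if (r < r_lo || r >= r_hi) {  // whole padded row
            col.submat(k * C, o + r * W, (k + 1) * C - 1, o + r * W + W - 1)
              .zeros();
            continue;
          }
          if (c_lo > 0)
            col.submat(k * C, o + r * W, (k + 1) * C - 1,
                       o + r * W + c_lo - 1).zeros();
          if (c_hi < W)
            col.submat(k * C, o + r * W + c_hi, (k + 1) * C - 1,
                       o + r * W + W - 1).zeros();
          col.submat(k * C, o + r * W + c_lo,
                     (k + 1) * C - 1, o + r * W + c_hi - 1) =
            X.cols(o + (r + dr) * W + c_lo + dc,
                   o + (r + dr) * W + c_hi - 1 + dc);
        }
      }
    }
  }
}

static void col2im3(const fmat &dcol, int H, int W, int B, fmat &dX) {
  const int C = dcol.n_rows / 9, P = H * W;
  dX.zeros(C, (size_t)B * P);
  for (int b = 0; b < B; ++b) {
    const int o = b * P;
    int k = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc, ++k) {
        const int r_lo = std::max(0, -dr), r_hi = std::min(H, H - dr);
        const int c_lo = std::max(0, -dc), c_hi = std::min(W, W - dc);
        if (c_lo >= c_hi) continue;
        for (int r = r_lo; r < r_hi; ++r) {
          dX.cols(o + (r + dr) * W + c_lo + dc,
                  o + (r + dr) * W + c_hi - 1 + dc) +=
            dcol.submat(k * C, o + r * W + c_lo,
                        (k + 1) * C - 1, o + r * W + c_hi - 1);
        }
      }
    }
  }
}

static fmat maxpool2(const fmat &X, int H, int W, int B, umat &arg) {
  const int C = X.n_rows, Ho = H / 2, Wo = W / 2, Po = Ho * Wo;
  fmat Y(C, (size_t)B * Po);
  arg.set_size(C, (size_t)B * Po);
  const float *x = X.memptr();
  float *y = Y.memptr();
  arma::uword *a = arg.memptr();
  for (int b = 0; b < B; ++b) {
    const int oi = b * H * W, oo = b * Po;
    for (int ro = 0; ro < Ho; ++ro) {
      for (int co = 0; co < Wo; ++co) {
        const size_t po = (size_t)(oo + ro * Wo + co) * C;
        const int p00 = oi + 2 * ro * W + 2 * co;
        const size_t cand[4] = {(size_t)p00 * C, (size_t)(p00 + 1) * C,
                                (size_t)(p00 + W) * C,
                                (size_t)(p00 + W + 1) * C};
        for (int ch = 0; ch < C; ++ch) {
          float best = x[cand[0] + ch]; size_t bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            const float v = x[cand[q] + ch];
            if (v > best) { best = v; bi = cand[q]; }
          }
          y[po + ch] = best;
          a[po + ch] = bi / C;
        }
      }
    }
  }
  return Y;
}

static fmat maxpool2_bw(const fmat &dY, const umat &arg, int H, int W, int B) {
  const int C = dY.n_rows;
  fmat dX(C, (size_t)B * H * W, arma::fill::zeros);
  for (arma::uword p = 0; p < dY.n_cols; ++p)
    for (int ch = 0; ch < C; ++ch)
      dX(ch, arg(ch, p)) += dY(ch, p);
  return dX;
}

static fmat upsample2(const fmat &X, int H, int W, int B) {
  const int C = X.n_rows, Ho = 2 * H, Wo = 2 * W;
  fmat Y(C, (size_t)B * Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const int oi = b * H * W, oo = b * Ho * Wo;
    for (int ro = 0; ro < Ho; ++ro) {
      const int r = ro / 2;
      for (int co = 0; co < Wo; ++co)
        Y.col(oo + ro * Wo + co) = X.col(oi + r * W + co / 2);
    }
  }
  return Y;
}

static fmat upsample2_bw(const fmat &dY, int H, int W, int B) {
  // H, W are the coarse (input) dimensions
  const int C = dY.n_rows, Wo = 2 * W;
  fmat dX(C, (size_t)B * H * W, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int oi = b * H * W, oo = b * 4 * H * W;
    for (int ro = 0; ro < 2 * H; ++ro) {
      const int r = ro / 2;
      for (int co = 0; co < Wo; ++co)
        dX.col(oi + r * W + co / 2) += dY.col(oo + ro * Wo + co);
    }
  }
  return dX;
}

// ---- network ------------------------------------------------------------

struct Net {
  int depth, F, Cin;
  std::vector<ConvSpec> specs;
  std::vector<fmat> Wts;
  std::vector<fvec> bs;
};

struct Cache {
  std::vector<fmat> conv_in, conv_out;
  std::vector<std::pair<int,int>> conv_hw;
  std::vector<umat> pool_arg;
  fmat drop_mask;
  int B;
};

static fmat conv_fwd(const Net &net, int ci, const fmat &X, int H, int W,
                     int B, bool relu, Cache *cache, Workspace &ws) {
  fmat Y;
  if (net.specs[ci].k == 1) {
    Y = net.Wts[ci] * X;
  } else {
    fmat col = ws.as_col(9 * net.specs[ci].cin, (size_t)B * H * W);
    im2col3(X, H, W, B, col);
    Y = net.Wts[ci] * col;
  }
  Y.each_col() += net.bs[ci];
  if (relu) Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (cache) {
    cache->conv_in[ci] = X;
    cache->conv_out[ci] = Y;
    cache->conv_hw[ci] = {H, W};
  }
  return Y;
}

static fmat conv_bwd(const Net &net, int ci, fmat dY, const Cache &cache,
                     bool relu, std::vector<fmat> &gW, std::vector<fvec> &gb,
                     Workspace &ws) {
  if (relu) dY %= arma::conv_to<fmat>::from(cache.conv_out[ci] > 0.0f);
  const int H = cache.conv_hw[ci].first, W = cache.conv_hw[ci].second;
  if (net.specs[ci].k == 1) {
    gW[ci] += dY * cache.conv_in[ci].t();
    gb[ci] += arma::sum(dY, 1);
    return net.Wts[ci].t() * dY;
  }
  const size_t BP = (size_t)cache.B * H * W;
  fmat col = ws.as_col(9 * net.specs[ci].cin, BP);
  im2col3(cache.conv_in[ci], H, W, cache.B, col);
  gW[ci] += dY * col.t();
  gb[ci] += arma::sum(dY, 1);
  fmat dcol = ws.as_dcol(9 * net.specs[ci].cin, BP);
  dcol = net.Wts[ci].t() * dY;
  fmat dX;
  col2im3(dcol, H, W, cache.B, dX);
  return dX;
}

static fmat forward(const Net &net, const fmat &X0, int H0, int W0, int B,
                    Cache *cache, float dropout, std::mt19937 *rng,
                    Workspace &ws) {
  const int D = net.depth;
  fmat cur = X0;
  int H = H0, W = W0, ci = 0;
  std::vector<fmat> skips(D);
  if (cache) {
    cache->conv_in.resize(net.specs.size());
    cache->conv_out.resize(net.specs.size());
    cache->conv_hw.resize(net.specs.size());
    cache->pool_arg.resize(D);
    cache->B = B;
  }
  for (int i = 0; i < D; ++i) {
    cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
    cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
    skips[i] = cur;
    umat arg;
    cur = maxpool2(cur, H, W, B, arg);
    if (cache) cache->pool_arg[i] = arg;
    H /= 2; W /= 2;
  }
  cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
  cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
  if (dropout > 0.0f && rng) {  // inverted dropout on the bottleneck
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    fmat mask(cur.n_rows, cur.n_cols);
    for (arma::uword j = 0; j < mask.n_elem; ++j)
      mask(j) = U(*rng) < dropout ? 0.0f : 1.0f / (1.0f - dropout);
    cur %= mask;
    if (cache) cache->drop_mask = mask;
  }
  for (int i = D - 1; i >= 0; --i) {
    cur = upsample2(cur, H, W, B);
    H *= 2; W *= 2;
    cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
    cur = arma::join_cols(skips[i], cur);
    cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
    cur = conv_fwd(net, ci++, cur, H, W, B, true, cache, ws);
  }
  fmat z = conv_fwd(net, ci, cur, H, W, B, false, cache, ws);
  z.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  return z;  // 1 x (B*H0*W0) probabilities
}

static void backward(const Net &net, const Cache &cache, fmat dz,
                     std::vector<fmat> &gW, std::vector<fvec> &gb,
                     float dropout, Workspace &ws) {
  const int D = net.depth;
  const int B = cache.B;
  const int fin = 5 * D + 2;
  fmat d = conv_bwd(net, fin, dz, cache, false, gW, gb, ws);
  std::vector<fmat> dskip(D);
  // decoder levels were created for i = D-1 .. 0; unwind in reverse
  for (int i = 0; i < D; ++i) {
    const int base = 2 * D + 2 + 3 * (D - 1 - i);
    d = conv_bwd(net, base + 2, d, cache, true, gW, gb, ws);
    d = conv_bwd(net, base + 1, d, cache, true, gW, gb, ws);
    const int f = net.F << i;
    dskip[i] = d.rows(0, f - 1);
    fmat dup = d.rows(f, 2 * f - 1);
    dup = conv_bwd(net, base, dup, cache, true, gW, gb, ws);
    const int Hc = cache.conv_hw[base].first / 2;
    const int Wc = cache.conv_hw[base].second / 2;
    d = upsample2_bw(dup, Hc, Wc, B);
  }
  if (dropout > 0.0f && cache.drop_mask.n_elem) d %= cache.drop_mask;
  d = conv_bwd(net, 2 * D + 1, d, cache, true, gW, gb, ws);
  d = conv_bwd(net, 2 * D, d, cache, true, gW, gb, ws);
  for (int i = D - 1; i >= 0; --i) {
    const int Hc = cache.conv_hw[2 * i].first;
    const int Wc = cache.conv_hw[2 * i].second;
    d = maxpool2_bw(d, cache.pool_arg[i], Hc, Wc, B);
    d += dskip[i];
    d = conv_bwd(net, 2 * i + 1, d, cache, true, gW, gb, ws);
    d = conv_bwd(net, 2 * i, d, cache, true, gW, gb, ws);
  }
}

// Tversky loss of one sample and (optionally) its probability gradient
static double tversky(const fmat &p, const fmat &t, double a, double b,
                      double s, fmat *dp) {
  const double TP = arma::accu(p % t);
  const double FP = arma::accu(p) - TP;
  const double FN = arma::accu(t) - TP;
  const double N = TP + s, Dm = TP + a * FP + b * FN + s;
  if (dp) {
    // d/dp_i: TP' = t_i, FP' = 1 - t_i, FN' = -t_i
    const float af = (float)a, bf = (float)b;
    fmat dD = t * (1.0f - af - bf) + af;
    *dp = -(t * (float)Dm - (float)N * dD) / (float)(Dm * Dm);
  }
  return 1.0 - N / Dm;
}

// ---- R interface --------------------------------------------------------

static Net make_net(int depth, int F, int Cin) {
  Net net;
  net.depth = depth; net.F = F; net.Cin = Cin;
  net.specs = conv_specs(depth, F, Cin);
  net.Wts.resize(net.specs.size());
  net.bs.resize(net.specs.size());
  return net;
}

static void weights_from_list(Net &net, const List &weights) {
  if ((int)weights.size() != (int)net.specs.size() * 2)
    stop("weight list does not match the architecture");
  for (size_t i = 0; i < net.specs.size(); ++i) {
    NumericMatrix Wm = weights[2 * i];
    NumericVector bv = weights[2 * i + 1];
    const int K = net.specs[i].k == 3 ? 9 * net.specs[i].cin : net.specs[i].cin;
    if (Wm.nrow() != net.specs[i].cout || Wm.ncol() != K)
      stop("weight %d has wrong shape", (int)i + 1);
    net.Wts[i] = arma::conv_to<fmat>::from(
      arma::mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
    net.bs[i] = arma::conv_to<fvec>::from(
      arma::vec(bv.begin(), bv.size(), false));
  }
}

static List weights_to_list(const Net &net) {
  List out(2 * net.specs.size());
  for (size_t i = 0; i < net.specs.size(); ++i) {
    out[2 * i] = wrap(arma::conv_to<arma::mat>::from(net.Wts[i]));
    out[2 * i + 1] = wrap(arma::conv_to<arma::vec>::from(net.bs[i]));
  }
  return out;
}

// [[Rcpp::export]]
List unet_init_cpp(int depth, int base_filters, int in_channels, int seed) {
  Net net = make_net(depth, base_filters, in_channels);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  for (size_t i = 0; i < net.specs.size(); ++i) {
    const int K = net.specs[i].k == 3 ? 9 * net.specs[i].cin
                                      : net.specs[i].cin;
    std::normal_distribution<float> N(0.0f, std::sqrt(2.0f / K));
    net.Wts[i].set_size(net.specs[i].cout, K);
    for (arma::uword j = 0; j < net.Wts[i].n_elem; ++j) net.Wts[i](j) = N(rng);
    net.bs[i].zeros(net.specs[i].cout);
  }
  // note: the output bias stays at 0 (initial p = 0.5 everywhere). For a
  // ratio loss like Tversky the soft-TP mass of an uncommitted start is
  // what keeps gradient on the rare positives; biasing the start towards
  // the class prior strands training in the all-background minimum.
  return weights_to_list(net);
}

// gather samples `which` (0-based) of an (H, W, C, N) R array into the
// batched channels x (B*H*W) layout
static fmat gather_batch(const double *base, int H, int W, int C,
                         const std::vector<int> &which) {
  const int P = H * W, B = (int)which.size();
  fmat X(C, (size_t)B * P);
  for (int b = 0; b < B; ++b) {
    const double *s = base + (size_t)which[b] * P * C;
    const int o = b * P;
    for (int ch = 0; ch < C; ++ch)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          X(ch, o + r * W + c) = (float)s[r + (size_t)H * (c + (size_t)W * ch)];
  }
  return X;
}

static fmat gather_masks(const double *base, int H, int W,
                         const std::vector<int> &which) {
  const int P = H * W, B = (int)which.size();
  fmat t(1, (size_t)B * P);
  for (int b = 0; b < B; ++b) {
    const double *s = base + (size_t)which[b] * P;
    const int o = b * P;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        t(0, o + r * W + c) = (float)s[r + (size_t)H * c];
  }
  return t;
}

// [[Rcpp::export]]
List unet_train_cpp(NumericVector images, NumericVector masks,
                    IntegerVector train_idx, IntegerVector val_idx,
                    int depth, int base_filters, double dropout_rate,
                    double learning_rate, double fp_weight, double fn_weight,
                    double smooth, int batch_size, int epochs,
                    double plateau_factor, int plateau_patience, int seed,
                    double abort_threshold, int abort_epoch,
                    int warmup_epochs, double warmup_fn_weight) {
  IntegerVector idim = images.attr("dim");
  const int H = idim[0], W = idim[1], C = idim[2];
  const int P = H * W;
  if ((H >> depth) << depth != H || (W >> depth) << depth != W)
    stop("input size not divisible by 2^depth");
  Net net = make_net(depth, base_filters, C);
  { // seeded He-normal init (same stream as unet_init_cpp)
    List w0 = unet_init_cpp(depth, base_filters, C, seed);
    weights_from_list(net, w0);
  }

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto &i : tr) --i;
  for (auto &i : va) --i;

  std::vector<fmat> mW(net.specs.size()), vW(net.specs.size()),
      gW(net.specs.size());
  std::vector<fvec> mB(net.specs.size()), vB(net.specs.size()),
      gB(net.specs.size());
  for (size_t i = 0; i < net.specs.size(); ++i) {
    mW[i].zeros(arma::size(net.Wts[i])); vW[i].zeros(arma::size(net.Wts[i]));
    gW[i].zeros(arma::size(net.Wts[i]));
    mB[i].zeros(net.specs[i].cout); vB[i].zeros(net.specs[i].cout);
    gB[i].zeros(net.specs[i].cout);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  long adam_t = 0;
  float lr = (float)learning_rate;

  std::mt19937 rng(static_cast<uint32_t>(seed) ^ 0x9e3779b9u);
  std::vector<double> train_hist, val_hist, lr_hist;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  std::vector<fmat> bestW = net.Wts;
  std::vector<fvec> bestB = net.bs;

  Cache cache;
  Workspace ws;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (size_t off = 0; off < tr.size(); off += batch_size) {
      const size_t hi = std::min(off + (size_t)batch_size, tr.size());
      std::vector<int> bidx(tr.begin() + off, tr.begin() + hi);
      const int B = (int)bidx.size();
      fmat X = gather_batch(images.begin(), H, W, C, bidx);
      fmat T = gather_masks(masks.begin(), H, W, bidx);
      for (size_t i = 0; i < net.specs.size(); ++i) {
        gW[i].zeros(); gB[i].zeros();
      }
      // recall-heavy warmup weights keep early training out of the
      // all-background minimum; validation always uses the target weights
      const double a_tr = ep < warmup_epochs ? 1.0 - warmup_fn_weight
                                             : fp_weight;
      const double b_tr = ep < warmup_epochs ? warmup_fn_weight : fn_weight;
      fmat p = forward(net, X, H, W, B, &cache, (float)dropout_rate, &rng, ws);
      fmat dz(1, p.n_cols);
      double batch_loss = 0.0;
      for (int b = 0; b < B; ++b) {  // loss is per sample, then averaged
        fmat pb = p.cols((size_t)b * P, (size_t)(b + 1) * P - 1);
        fmat tb = T.cols((size_t)b * P, (size_t)(b + 1) * P - 1);
        fmat dp;
        batch_loss += tversky(pb, tb, a_tr, b_tr, smooth, &dp);
        dz.cols((size_t)b * P, (size_t)(b + 1) * P - 1) =
          (dp % pb % (1.0f - pb)) / (float)B;
      }
      backward(net, cache, dz, gW, gB, (float)dropout_rate, ws);
      ++adam_t;
      const float corr = std::sqrt(1.0f - std::pow(b2, (float)adam_t)) /
                         (1.0f - std::pow(b1, (float)adam_t));
      for (size_t i = 0; i < net.specs.size(); ++i) {
        mW[i] = b1 * mW[i] + (1.0f - b1) * gW[i];
        vW[i] = b2 * vW[i] + (1.0f - b2) * (gW[i] % gW[i]);
        net.Wts[i] -= lr * corr * mW[i] / (arma::sqrt(vW[i]) + eps);
        mB[i] = b1 * mB[i] + (1.0f - b1) * gB[i];
        vB[i] = b2 * vB[i] + (1.0f - b2) * (gB[i] % gB[i]);
        net.bs[i] -= lr * corr * mB[i] / (arma::sqrt(vB[i]) + eps);
      }
      ep_loss += batch_loss / B;
      ++n_batches;
      Rcpp::checkUserInterrupt();
    }
    // validation in forward-only batches
    double vloss = 0.0;
    for (size_t off = 0; off < va.size(); off += batch_size) {
      const size_t hi = std::min(off + (size_t)batch_size, va.size());
      std::vector<int> bidx(va.begin() + off, va.begin() + hi);
      const int B = (int)bidx.size();
      fmat X = gather_batch(images.begin(), H, W, C, bidx);
      fmat T = gather_masks(masks.begin(), H, W, bidx);
      fmat p = forward(net, X, H, W, B, nullptr, 0.0f, nullptr, ws);
      for (int b = 0; b < B; ++b) {
        fmat pb = p.cols((size_t)b * P, (size_t)(b + 1) * P - 1);
        fmat tb = T.cols((size_t)b * P, (size_t)(b + 1) * P - 1);
        vloss += tversky(pb, tb, fp_weight, fn_weight, smooth, nullptr);
      }
    }
    vloss /= va.size();
    train_hist.push_back(ep_loss / std::max(n_batches, 1));
    val_hist.push_back(vloss);
    lr_hist.push_back(lr);
    if (vloss < best_val - 1e-12) {
      best_val = vloss; best_epoch = ep + 1; wait = 0;
      bestW = net.Wts; bestB = net.bs;
    } else if (++wait >= plateau_patience) {
      lr *= (float)plateau_factor;
      wait = 0;
    }
    // a run still at its trivial-solution loss this late will not recover;
    // stop early so the caller can restart from a different seed
    if (abort_epoch > 0 && ep + 1 >= abort_epoch &&
        best_val >= abort_threshold)
      break;
  }
  net.Wts = bestW; net.bs = bestB;
  return List::create(_["weights"] = weights_to_list(net),
                      _["train_loss"] = wrap(train_hist),
                      _["val_loss"] = wrap(val_hist),
                      _["lr"] = wrap(lr_hist),
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
NumericVector unet_predict_cpp(NumericVector images, List weights,
                               int depth, int base_filters) {
  IntegerVector idim = images.attr("dim");
  const int H = idim[0], W = idim[1], C = idim[2], N = idim[3];
  const int P = H * W;
  if ((H >> depth) << depth != H || (W >> depth) << depth != W)
    stop("input size not divisible by 2^depth");
  Net net = make_net(depth, base_filters, C);
  weights_from_list(net, weights);
  NumericVector out((size_t)P * N);
  out.attr("dim") = IntegerVector::create(H, W, N);
  Workspace ws;
  const int chunk = 16;
  for (int n0 = 0; n0 < N; n0 += chunk) {
    std::vector<int> bidx;
    for (int n = n0; n < std::min(n0 + chunk, N); ++n) bidx.push_back(n);
    fmat X = gather_batch(images.begin(), H, W, C, bidx);
    fmat p = forward(net, X, H, W, (int)bidx.size(), nullptr, 0.0f, nullptr, ws);
    for (size_t b = 0; b < bidx.size(); ++b) {
      double *o = out.begin() + (size_t)bidx[b] * P;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          o[r + (size_t)H * c] = p(0, (size_t)b * P + r * W + c);
    }
  }
  return out;
}
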