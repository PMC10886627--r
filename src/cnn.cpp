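// Minimal convolutional-network engine used by the classifier module.
//
// Supported layer stack: [conv 3x3 same + ReLU | maxpool 2x2]* ->
// [dense + ReLU | dropout]* -> dense + softmax.  Training minimizes
// class-weighted cross-entropy with Adam.  All randomness (weight init,
// batch shuffling, flip augmentation, dropout masks) flows from one
// std::mt19937 seed, so runs are reproducible within an environment.
//
// Activation layout: feature maps are (channels x H*W) matrices, column
// index i = y*W + x (row-major spatial, y down); flattened vectors are
// channel-planar, v[c*H*W + i].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum LType { CONV, POOL, DENSE, DROPOUT, OUTPUT };

struct LayerSpec {
  LType type;
  int units = 0;      // dense/output width, conv filters
  double p = 0.0;     // dropout probability
  int inH = 0, inW = 0, inC = 0, outH = 0, outW = 0, outC = 0;
  int in_dim = 0, out_dim = 0;  // dense dims
};

static std::vector<LayerSpec> parse_arch(const List& arch, int& H, int& W,
                                         int& C, int& n_classes) {
  IntegerVector input = arch["input"];
  H = input[0]; W = input[1]; C = input[2];
  List layers = arch["layers"];
  std::vector<LayerSpec> specs;
  int h = H, w = W, c = C;
  bool flat = false;
  int dim = 0;
  for (int i = 0; i < layers.size(); ++i) {
    List ly(layers[i]);
    std::string ty = as<std::string>(ly["type"]);
    LayerSpec s;
    if (ty == "conv") {
      if (flat) stop("conv layer after flatten is unsupported");
      s.type = CONV;
      s.units = as<int>(ly["filters"]);
      s.inH = h; s.inW = w; s.inC = c;
      s.outH = h; s.outW = w; s.outC = s.units;
      c = s.units;
    } else if (ty == "pool") {
      if (flat) stop("pool layer after flatten is unsupported");
      s.type = POOL;
      s.inH = h; s.inW = w; s.inC = c;
      s.outH = h / 2; s.outW = w / 2; s.outC = c;
      if (s.outH < 1 || s.outW < 1)
        stop("input size incompatible with backbone downsampling");
      h = s.outH; w = s.outW;
    } else if (ty == "dense" || ty == "output") {
      if (!flat) { dim = h * w * c; flat = true; }
      s.type = (ty == "dense") ? DENSE : OUTPUT;
      s.units = as<int>(ly["units"]);
      s.in_dim = dim; s.out_dim = s.units;
      dim = s.units;
      if (s.type == OUTPUT) n_classes = s.units;
    } else if (ty == "dropout") {
      if (!flat) stop("dropout only supported between dense layers");
      s.type = DROPOUT;
      s.p = as<double>(ly["p"]);
      s.in_dim = dim; s.out_dim = dim;
    } else {
      stop("unknown layer type: %s", ty.c_str());
    }
    specs.push_back(s);
  }
  if (specs.empty() || specs.back().type != OUTPUT)
    stop("last layer must be the softmax output layer");
  return specs;
}

// ---- im2col / col2im for 3x3, stride 1, zero pad 1 ----------------------

static void im2col3(const arma::mat& in, int H, int W, arma::mat& col) {
  int C = in.n_rows, HW = H * W;
  col.set_size(C * 9, HW);
  col.zeros();
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        int r = c * 9 + ky * 3 + kx;
        for (int y = 0; y < H; ++y) {
          int sy = y + ky - 1;
          if (sy < 0 || sy >= H) continue;
          for (int x = 0; x < W; ++x) {
            int sx = x + kx - 1;
            if (sx < 0 || sx >= W) continue;
            col(r, y * W + x) = in(c, sy * W + sx);
          }
        }
      }
}

static void col2im3(const arma::mat& dcol, int H, int W, arma::mat& din) {
  int C = din.n_rows;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        int r = c * 9 + ky * 3 + kx;
        for (int y = 0; y < H; ++y) {
          int sy = y + ky - 1;
          if (sy < 0 || sy >= H) continue;
          for (int x = 0; x < W; ++x) {
            int sx = x + kx - 1;
            if (sx < 0 || sx >= W) continue;
            din(c, sy * W + sx) += dcol(r, y * W + x);
          }
        }
      }
}

// ---- parameter containers ----------------------------------------------

struct Params {
  std::vector<arma::mat> Wm;
  std::vector<arma::vec> b;
};

static Params params_from_list(const List& plist,
                               const std::vector<LayerSpec>& specs) {
  Params P;
  P.Wm.resize(specs.size());
  P.b.resize(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    if (specs[i].type == CONV || specs[i].type == DENSE ||
        specs[i].type == OUTPUT) {
      List pi(plist[i]);
      P.Wm[i] = as<arma::mat>(pi["W"]);
      P.b[i] = as<arma::vec>(pi["b"]);
    }
  }
  return P;
}

static List params_to_list(const Params& P,
                           const std::vector<LayerSpec>& specs) {
  List out(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    if (specs[i].type == CONV || specs[i].type == DENSE ||
        specs[i].type == OUTPUT)
      out[i] = List::create(Named("W") = P.Wm[i], Named("b") = P.b[i]);
    else
      out[i] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(List arch, int seed) {
  int H, W, C, K = 0;
  std::vector<LayerSpec> specs = parse_arch(arch, H, W, C, K);
  std::mt19937 gen((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Params P;
  P.Wm.resize(specs.size());
  P.b.resize(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    if (s.type == CONV) {
      int fan_in = s.inC * 9;
      double sd = std::sqrt(2.0 / fan_in);
      arma::mat Wm(s.units, fan_in);
      for (arma::uword j = 0; j < Wm.n_elem; ++j) Wm(j) = sd * nd(gen);
      P.Wm[i] = Wm;
      P.b[i] = arma::vec(s.units, arma::fill::zeros);
    } else if (s.type == DENSE || s.type == OUTPUT) {
      double sd = std::sqrt(2.0 / s.in_dim);
      arma::mat Wm(s.in_dim, s.out_dim);
      for (arma::uword j = 0; j < Wm.n_elem; ++j) Wm(j) = sd * nd(gen);
      P.Wm[i] = Wm;
      P.b[i] = arma::vec(s.out_dim, arma::fill::zeros);
    }
  }
  return params_to_list(P, specs);
}

// ---- conv-stack forward (one sample) ------------------------------------
// Returns flattened feature vector; optionally caches activations.

struct SampleCache {
  std::vector<arma::mat> act;    // post-activation output of each conv/pool
  std::vector<arma::umat> amax;  // pool argmax input columns
};

static arma::vec conv_forward(const arma::vec& x,
                              const std::vector<LayerSpec>& specs,
                              const Params& P, int H, int W, int C,
                              SampleCache* cache) {
  // inputs arrive in [0, 1]; center at 0 for better first-layer
  // conditioning (part of the model, applied identically at train and
  // inference time)
  arma::mat cur(C, H * W);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < H * W; ++i)
      cur(c, i) = x((arma::uword)c * H * W + i) - 0.5;
  if (cache) {
    cache->act.assign(specs.size(), arma::mat());
    cache->amax.assign(specs.size(), arma::umat());
  }
  arma::mat col;
  size_t i = 0;
  for (; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    if (s.type == CONV) {
      im2col3(cur, s.inH, s.inW, col);
      arma::mat out = P.Wm[i] * col;
      out.each_col() += P.b[i];
      out.transform([](double v) { return v > 0.0 ? v : 0.0; });
      cur = out;
    } else if (s.type == POOL) {
      int H2 = s.outH, W2 = s.outW, Ch = s.inC;
      arma::mat out(Ch, H2 * W2);
      arma::umat am(Ch, H2 * W2);
      for (int c = 0; c < Ch; ++c)
        for (int y = 0; y < H2; ++y)
          for (int x2 = 0; x2 < W2; ++x2) {
            int base = (2 * y) * s.inW + 2 * x2;
            int idx[4] = {base, base + 1, base + s.inW, base + s.inW + 1};
            double best = cur(c, idx[0]);
            int bi = idx[0];
            for (int k = 1; k < 4; ++k)
              if (cur(c, idx[k]) > best) { best = cur(c, idx[k]); bi = idx[k]; }
            out(c, y * W2 + x2) = best;
            am(c, y * W2 + x2) = (arma::uword)bi;
          }
      if (cache) cache->amax[i] = am;
      cur = out;
    } else {
      break;  // dense stage starts
    }
    if (cache) cache->act[i] = cur;
  }
  // flatten channel-planar
  return arma::vectorise(cur.t());
}

static void conv_backward(const arma::vec& x, const arma::vec& dflat,
                          const std::vector<LayerSpec>& specs,
                          const Params& P, const SampleCache& cache,
                          int H, int W, int C, size_t n_conv_stage,
                          Params& G) {
  // rebuild input map (centered exactly as in the forward pass)
  arma::mat in0(C, H * W);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < H * W; ++i)
      in0(c, i) = x((arma::uword)c * H * W + i) - 0.5;
  // unflatten gradient at top of conv stack
  int topC, topHW;
  if (n_conv_stage == 0) { topC = C; topHW = H * W; }
  else {
    const LayerSpec& t = specs[n_conv_stage - 1];
    topC = t.outC; topHW = t.outH * t.outW;
  }
  arma::mat dcur(topC, topHW);
  for (int c = 0; c < topC; ++c)
    for (int i = 0; i < topHW; ++i)
      dcur(c, i) = dflat((arma::uword)c * topHW + i);
  arma::mat col;
  for (size_t ii = n_conv_stage; ii-- > 0;) {
    const LayerSpec& s = specs[ii];
    const arma::mat& input =
        (ii == 0) ? in0 : cache.act[ii - 1];
    if (s.type == CONV) {
      const arma::mat& out = cache.act[ii];
      arma::mat dpre = dcur % arma::conv_to<arma::mat>::from(out > 0.0);
      im2col3(input, s.inH, s.inW, col);
      G.Wm[ii] += dpre * col.t();
      G.b[ii] += arma::sum(dpre, 1);
      arma::mat dcol = P.Wm[ii].t() * dpre;
      arma::mat din(s.inC, s.inH * s.inW, arma::fill::zeros);
      col2im3(dcol, s.inH, s.inW, din);
      dcur = din;
    } else if (s.type == POOL) {
      const arma::umat& am = cache.amax[ii];
      arma::mat din(s.inC, s.inH * s.inW, arma::fill::zeros);
      for (int c = 0; c < s.inC; ++c)
        for (arma::uword j = 0; j < am.n_cols; ++j)
          din(c, am(c, j)) += dcur(c, j);
      dcur = din;
    }
  }
}

// ---- dense stage ---------------------------------------------------------

static arma::mat softmax_rows(arma::mat Z) {
  Z.each_col() -= arma::max(Z, 1);
  Z = arma::exp(Z);
  arma::vec s = arma::sum(Z, 1);
  Z.each_col() /= s;
  return Z;
}

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward(List arch, List plist, const arma::mat& X) {
  int H, W, C, K = 0;
  std::vector<LayerSpec> specs = parse_arch(arch, H, W, C, K);
  Params P = params_from_list(plist, specs);
  if ((int)X.n_cols != H * W * C)
    stop("tile matrix has %d columns; model expects %d", (int)X.n_cols,
         H * W * C);
  size_t n_conv_stage = 0;
  while (n_conv_stage < specs.size() &&
         (specs[n_conv_stage].type == CONV || specs[n_conv_stage].type == POOL))
    ++n_conv_stage;
  int flat_dim = (n_conv_stage == 0)
                     ? H * W * C
                     : specs[n_conv_stage - 1].outC *
                           specs[n_conv_stage - 1].outH *
                           specs[n_conv_stage - 1].outW;
  arma::mat F(X.n_rows, flat_dim);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec xi = X.row(i).t();
    F.row(i) = conv_forward(xi, specs, P, H, W, C, nullptr).t();
  }
  arma::mat Z = F;
  for (size_t i = n_conv_stage; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    if (s.type == DENSE) {
      Z = Z * P.Wm[i];
      Z.each_row() += P.b[i].t();
      Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    } else if (s.type == OUTPUT) {
      Z = Z * P.Wm[i];
      Z.each_row() += P.b[i].t();
      Z = softmax_rows(Z);
    }
    // dropout: identity at inference
  }
  return Z;
}

// weighted cross-entropy over a probability matrix
static double wce(const arma::mat& Pr, const arma::ivec& y,
                  const arma::vec& w) {
  double L = 0;
  for (arma::uword i = 0; i < Pr.n_rows; ++i)
    L += -w(y(i)) * std::log(std::max(Pr(i, y(i)), 1e-12));
  return L / Pr.n_rows;
}

static double acc(const arma::mat& Pr, const arma::ivec& y) {
  int ok = 0;
  for (arma::uword i = 0; i < Pr.n_rows; ++i)
    if ((arma::sword)Pr.row(i).index_max() == y(i)) ++ok;
  return (double)ok / Pr.n_rows;
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List arch, List plist, const arma::mat& X,
               const arma::ivec& y, const arma::vec& classw,
               const arma::mat& Xval, const arma::ivec& yval, int epochs,
               int batch_size, double lr, int seed, bool augment) {
  int H, W, C, K = 0;
  std::vector<LayerSpec> specs = parse_arch(arch, H, W, C, K);
  Params P = params_from_list(plist, specs);
  if ((int)X.n_cols != H * W * C) stop("tile matrix width mismatch");
  size_t nL = specs.size();
  size_t n_conv_stage = 0;
  while (n_conv_stage < nL && (specs[n_conv_stage].type == CONV ||
                               specs[n_conv_stage].type == POOL))
    ++n_conv_stage;

  // Adam state
  Params M, V;
  M.Wm.resize(nL); M.b.resize(nL); V.Wm.resize(nL); V.b.resize(nL);
  for (size_t i = 0; i < nL; ++i)
    if (!P.Wm[i].is_empty()) {
      M.Wm[i] = arma::mat(arma::size(P.Wm[i]), arma::fill::zeros);
      V.Wm[i] = arma::mat(arma::size(P.Wm[i]), arma::fill::zeros);
      M.b[i] = arma::vec(P.b[i].n_elem, arma::fill::zeros);
      V.b[i] = arma::vec(P.b[i].n_elem, arma::fill::zeros);
    }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;

  std::mt19937 gen((unsigned)seed);
  std::bernoulli_distribution coin(0.5);
  int n = X.n_rows;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  // flip permutations on the flattened channel-planar layout
  std::vector<arma::uvec> flipH_perm(1), flipV_perm(1);
  arma::uvec ph(H * W * C), pv(H * W * C);
  for (int c = 0; c < C; ++c)
    for (int yy = 0; yy < H; ++yy)
      for (int xx = 0; xx < W; ++xx) {
        arma::uword d = (arma::uword)c * H * W + yy * W + xx;
        ph(d) = (arma::uword)c * H * W + yy * W + (W - 1 - xx);
        pv(d) = (arma::uword)c * H * W + (H - 1 - yy) * W + xx;
      }

  int n_epoch_cols = 5;
  arma::mat history(epochs, n_epoch_cols);

  for (int ep = 0; ep < epochs; ++ep) {
    // cosine learning-rate decay to 10% of the initial rate
    double lr_ep =
        lr * (0.55 + 0.45 * std::cos(M_PI * ep / std::max(1, epochs - 1)));
    std::shuffle(idx.begin(), idx.end(), gen);
    double ep_loss = 0;
    long ep_ok = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bn = std::min(batch_size, n - start);
      // gradients
      Params G;
      G.Wm.resize(nL); G.b.resize(nL);
      for (size_t i = 0; i < nL; ++i)
        if (!P.Wm[i].is_empty()) {
          G.Wm[i] = arma::mat(arma::size(P.Wm[i]), arma::fill::zeros);
          G.b[i] = arma::vec(P.b[i].n_elem, arma::fill::zeros);
        }
      // assemble batch (with augmentation)
      std::vector<arma::vec> xs(bn);
      arma::ivec yb(bn);
      for (int j = 0; j < bn; ++j) {
        arma::vec xi = X.row(idx[start + j]).t();
        if (augment) {
          bool fh = coin(gen), fv = coin(gen);
          if (fh) xi = xi.elem(ph);
          if (fv) xi = xi.elem(pv);
        }
        xs[j] = xi;
        yb(j) = y(idx[start + j]);
      }
      // conv forward with caches
      std::vector<SampleCache> caches(bn);
      int flat_dim = (n_conv_stage == 0)
                         ? H * W * C
                         : specs[n_conv_stage - 1].outC *
                               specs[n_conv_stage - 1].outH *
                               specs[n_conv_stage - 1].outW;
      arma::mat F(bn, flat_dim);
      for (int j = 0; j < bn; ++j)
        F.row(j) = conv_forward(xs[j], specs, P, H, W, C, &caches[j]).t();
      // dense forward with caches
      std::vector<arma::mat> Zs(nL + 1);
      std::vector<arma::mat> dropmask(nL);
      Zs[n_conv_stage] = F;
      arma::mat Z = F;
      for (size_t i = n_conv_stage; i < nL; ++i) {
        const LayerSpec& s = specs[i];
        if (s.type == DENSE) {
          Z = Z * P.Wm[i];
          Z.each_row() += P.b[i].t();
          Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
        } else if (s.type == DROPOUT) {
          arma::mat mask(Z.n_rows, Z.n_cols);
          std::bernoulli_distribution keep(1.0 - s.p);
          for (arma::uword e = 0; e < mask.n_elem; ++e)
            mask(e) = keep(gen) ? 1.0 / (1.0 - s.p) : 0.0;
          dropmask[i] = mask;
          Z = Z % mask;
        } else if (s.type == OUTPUT) {
          Z = Z * P.Wm[i];
          Z.each_row() += P.b[i].t();
          Z = softmax_rows(Z);
        }
        Zs[i + 1] = Z;
      }
      const arma::mat& Pr = Zs[nL];
      ep_loss += wce(Pr, yb, classw) * bn;
      for (int j = 0; j < bn; ++j)
        if ((arma::sword)Pr.row(j).index_max() == yb(j)) ++ep_ok;
      // backward: dlogits
      arma::mat dZ = Pr;
      for (int j = 0; j < bn; ++j) {
        dZ.row(j)(yb(j)) -= 1.0;
        dZ.row(j) *= classw(yb(j)) / bn;
      }
      for (size_t i = nL; i-- > n_conv_stage;) {
        const LayerSpec& s = specs[i];
        if (s.type == OUTPUT || s.type == DENSE) {
          arma::mat dpre = dZ;
          if (s.type == DENSE) {
            // ReLU mask on this layer's post-activation (pre-dropout)
            dpre = dZ % arma::conv_to<arma::mat>::from(Zs[i + 1] > 0.0);
            // note Zs[i+1] is post-relu (and this is called before the
            // dropout layer's own backward multiplies its mask)
          }
          G.Wm[i] += Zs[i].t() * dpre;
          G.b[i] += arma::sum(dpre, 0).t();
          dZ = dpre * P.Wm[i].t();
        } else if (s.type == DROPOUT) {
          dZ = dZ % dropmask[i];
        }
      }
      // conv backward per sample
      if (n_conv_stage > 0) {
        for (int j = 0; j < bn; ++j) {
          arma::vec dflat = dZ.row(j).t();
          conv_backward(xs[j], dflat, specs, P, caches[j], H, W, C,
                        n_conv_stage, G);
        }
      }
      // Adam step
      ++tstep;
      double bc1 = 1.0 - std::pow(b1, (double)tstep);
      double bc2 = 1.0 - std::pow(b2, (double)tstep);
      for (size_t i = 0; i < nL; ++i) {
        if (P.Wm[i].is_empty()) continue;
        M.Wm[i] = b1 * M.Wm[i] + (1 - b1) * G.Wm[i];
        V.Wm[i] = b2 * V.Wm[i] + (1 - b2) * arma::square(G.Wm[i]);
        P.Wm[i] -=
            lr_ep * (M.Wm[i] / bc1) / (arma::sqrt(V.Wm[i] / bc2) + eps);
        M.b[i] = b1 * M.b[i] + (1 - b1) * G.b[i];
        V.b[i] = b2 * V.b[i] + (1 - b2) * arma::square(G.b[i]);
        P.b[i] -= lr_ep * (M.b[i] / bc1) / (arma::sqrt(V.b[i] / bc2) + eps);
      }
      if (!std::isfinite(ep_loss))
        stop("non-finite training loss at epoch %d", ep + 1);
    }
    history(ep, 0) = ep + 1;
    history(ep, 1) = ep_loss / n;
    history(ep, 2) = (double)ep_ok / n;
    if (Xval.n_rows > 0) {
      List pl = params_to_list(P, specs);
      arma::mat Pv = cnn_forward(arch, pl, Xval);
      history(ep, 3) = wce(Pv, yval, classw);
      history(ep, 4) = acc(Pv, yval);
    } else {
      history(ep, 3) = NA_REAL;
      history(ep, 4) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("params") = params_to_list(P, specs),
                      Named("history") = history);
}
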