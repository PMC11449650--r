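// Convolutional autoencoder engine for voltammogram heatmaps.
//
// Encoder: separable 2D convolution (depthwise 3x3 + pointwise 1x1) ->
// batch norm -> ReLU -> 2x2 max pool, repeated. A dense head (dropout +
// hidden layer + linear 3-way output) reads the flattened 2D latent for
// concentration regression; a decoder (2D convolution -> ReLU -> 2x2
// nearest-neighbour upsampling, ending in a sigmoid-squashed 1-channel
// convolution) reconstructs the [0,1] input. Losses: RMSE on scaled labels
// and pixelwise binary cross-entropy; optimizer: Adam with
// reduce-on-plateau LR schedule and early stopping on validation loss.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// ---- small conv helpers (odd kernel, same padding, cross-correlation) ----

static void xcorr_same_acc(const mat& X, const mat& K, mat& out) {
  const int H = X.n_rows, W = X.n_cols, kh = K.n_rows, kw = K.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b) {
        int jj = j + b - pw;
        if (jj < 0 || jj >= W) continue;
        for (int a = 0; a < kh; ++a) {
          int ii = i + a - ph;
          if (ii < 0 || ii >= H) continue;
          acc += X(ii, jj) * K(a, b);
        }
      }
      out(i, j) += acc;
    }
  }
}

// dX += xcorr_same backward: spread dY through K
static void xcorr_same_back_acc(const mat& dY, const mat& K, mat& dX) {
  const int H = dY.n_rows, W = dY.n_cols, kh = K.n_rows, kw = K.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double g = dY(i, j);
      if (g == 0.0) continue;
      for (int b = 0; b < kw; ++b) {
        int jj = j + b - pw;
        if (jj < 0 || jj >= W) continue;
        for (int a = 0; a < kh; ++a) {
          int ii = i + a - ph;
          if (ii < 0 || ii >= H) continue;
          dX(ii, jj) += g * K(a, b);
        }
      }
    }
  }
}

static void kernel_grad_acc(const mat& X, const mat& dY, mat& dK) {
  const int H = X.n_rows, W = X.n_cols, kh = dK.n_rows, kw = dK.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  for (int b = 0; b < kw; ++b) {
    for (int a = 0; a < kh; ++a) {
      double acc = 0.0;
      for (int j = 0; j < W; ++j) {
        int jj = j + b - pw;
        if (jj < 0 || jj >= W) continue;
        for (int i = 0; i < H; ++i) {
          int ii = i + a - ph;
          if (ii < 0 || ii >= H) continue;
          acc += X(ii, jj) * dY(i, j);
        }
      }
      dK(a, b) += acc;
    }
  }
}

// ---- parameters -----------------------------------------------------------

struct Param {
  std::string name;
  vec value, grad, m, v;
  uvec dims;               // original array dims (for round-trip to R)
  bool trainable;
};

struct Net {
  int rows0, cols0, n_enc, kernel, pool, depth_mult;
  std::vector<int> enc_f, dec_f, head_u;
  double dropout;
  bool has_head;
  std::vector<Param> params;
  std::map<std::string, int> index;

  Param& P(const std::string& nm) {
    auto it = index.find(nm);
    if (it == index.end()) Rcpp::stop("missing weight block: " + nm);
    return params[it->second];
  }
  bool has(const std::string& nm) const { return index.count(nm) > 0; }

  // typed zero-copy views over a parameter's value vector
  cube as_cube(Param& p) {
    return cube(p.value.memptr(), p.dims(0), p.dims(1), p.dims(2), false, true);
  }
  mat as_mat(Param& p) {
    return mat(p.value.memptr(), p.dims(0), p.dims(1), false, true);
  }
  cube grad_cube(Param& p) {
    return cube(p.grad.memptr(), p.dims(0), p.dims(1), p.dims(2), false, true);
  }
  mat grad_mat(Param& p) {
    return mat(p.grad.memptr(), p.dims(0), p.dims(1), false, true);
  }
};

static Net build_net(const Rcpp::List& weights, const Rcpp::List& arch) {
  Net net;
  Rcpp::IntegerVector shape = arch["input_shape"];
  net.rows0 = shape[0]; net.cols0 = shape[1];
  Rcpp::IntegerVector ef = arch["enc_filters"], df = arch["dec_filters"],
                      hu = arch["head_units"];
  net.enc_f.assign(ef.begin(), ef.end());
  net.dec_f.assign(df.begin(), df.end());
  net.head_u.assign(hu.begin(), hu.end());
  net.n_enc = net.enc_f.size();
  net.kernel = Rcpp::as<int>(arch["kernel"]);
  net.pool = Rcpp::as<int>(arch["pool"]);
  net.depth_mult = Rcpp::as<int>(arch["depth_multiplier"]);
  net.dropout = Rcpp::as<double>(arch["dropout"]);
  Rcpp::CharacterVector nms = weights.names();
  net.has_head = false;
  for (int i = 0; i < nms.size(); ++i)
    if (std::string(nms[i]).rfind("head", 0) == 0) net.has_head = true;
  for (int i = 0; i < weights.size(); ++i) {
    Rcpp::NumericVector w = weights[i];
    Param p;
    p.name = std::string(nms[i]);
    p.value = vec(w.begin(), w.size());
    Rcpp::RObject dm = w.attr("dim");
    if (dm.isNULL()) p.dims = uvec({(uword)w.size(), 1, 1});
    else {
      Rcpp::IntegerVector d(dm);
      p.dims = uvec(3, fill::ones);
      for (int k = 0; k < d.size() && k < 3; ++k) p.dims(k) = d[k];
    }
    p.grad = zeros<vec>(p.value.n_elem);
    p.m = zeros<vec>(p.value.n_elem);
    p.v = zeros<vec>(p.value.n_elem);
    // batch-norm running stats are updated by forward passes, not by Adam
    p.trainable = !(p.name.find("_rm") != std::string::npos ||
                    p.name.find("_rv") != std::string::npos);
    net.index[p.name] = net.params.size();
    net.params.push_back(p);
  }
  return net;
}

static Rcpp::List export_weights(Net& net) {
  Rcpp::List out;
  for (auto& p : net.params) {
    Rcpp::NumericVector w(p.value.begin(), p.value.end());
    if (p.dims(2) > 1)
      w.attr("dim") = Rcpp::IntegerVector::create(p.dims(0), p.dims(1), p.dims(2));
    else if (p.dims(1) > 1)
      w.attr("dim") = Rcpp::IntegerVector::create(p.dims(0), p.dims(1));
    out[p.name] = w;
  }
  return out;
}

// ---- caches ---------------------------------------------------------------

struct EncCache {
  std::vector<cube> x;        // block input
  std::vector<cube> dconv;    // depthwise output
  std::vector<cube> zhat;     // normalized pre-activation
  std::vector<cube> relu_out; // post-ReLU, pre-pool
  std::vector<Cube<uword>> argmax;
  vec mu, invstd;             // per-channel batch stats
};

struct DecCache {
  std::vector<cube> x;        // conv input
  std::vector<cube> relu_out; // post-ReLU (pre-upsample)
};

struct FwdCache {
  std::vector<EncCache> enc;
  std::vector<cube> latent;
  std::vector<std::vector<vec>> head_h; // per-layer activations per sample
  std::vector<vec> drop_mask;
  std::vector<DecCache> dec;
  std::vector<cube> out_x;   // input to final conv
  std::vector<mat> recon;    // sigmoid output (single channel)
};

static cube maxpool(const cube& x, int pool, Cube<uword>& arg) {
  int H = x.n_rows / pool, W = x.n_cols / pool, C = x.n_slices;
  cube out(H, W, C);
  arg.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int b = 0; b < pool; ++b)
          for (int a = 0; a < pool; ++a) {
            uword ii = i * pool + a, jj = j * pool + b;
            double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + jj * x.n_rows; }
          }
        out(i, j, c) = best;
        arg(i, j, c) = bi;
      }
  return out;
}

static cube upsample(const cube& x, int f) {
  cube out(x.n_rows * f, x.n_cols * f, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        double v = x(i, j, c);
        for (int b = 0; b < f; ++b)
          for (int a = 0; a < f; ++a)
            out(i * f + a, j * f + b, c) = v;
      }
  return out;
}

static cube upsample_back(const cube& dy, int f) {
  cube dx(dy.n_rows / f, dy.n_cols / f, dy.n_slices, fill::zeros);
  for (uword c = 0; c < dy.n_slices; ++c)
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        dx(i / f, j / f, c) += dy(i, j, c);
  return dx;
}

// forward one batch; fills cache. X entries are rows0 x cols0 single-channel.
static void forward_batch(Net& net, const std::vector<mat>& Xb, bool training,
                          bool use_head, bool use_decoder, FwdCache& cc,
                          mat& pred, std::mt19937& rng) {
  const int N = Xb.size();
  cc.enc.assign(net.n_enc, EncCache());
  cc.latent.assign(N, cube());
  std::vector<cube> cur(N);
  for (int s = 0; s < N; ++s) {
    cur[s] = cube(net.rows0, net.cols0, 1);
    cur[s].slice(0) = Xb[s];
  }
  for (int l = 0; l < net.n_enc; ++l) {
    EncCache& ec = cc.enc[l];
    ec.x = cur;
    const int Cin = cur[0].n_slices, Cout = net.enc_f[l];
    Param& dwP = net.P("enc" + std::to_string(l) + "_dw");
    Param& pwP = net.P("enc" + std::to_string(l) + "_pw");
    Param& bP  = net.P("enc" + std::to_string(l) + "_b");
    cube dw = net.as_cube(dwP);
    mat pw = net.as_mat(pwP);
    ec.dconv.assign(N, cube());
    std::vector<cube> z(N);
    const int H = cur[0].n_rows, W = cur[0].n_cols;
    const int DM = net.depth_mult;
    for (int s = 0; s < N; ++s) {
      cube dc(H, W, Cin * DM, fill::zeros);
      for (int c = 0; c < Cin; ++c)
        for (int m = 0; m < DM; ++m)
          xcorr_same_acc(cur[s].slice(c), dw.slice(c * DM + m),
                         dc.slice(c * DM + m));
      ec.dconv[s] = dc;
      mat D(dc.memptr(), H * W, Cin * DM, false, true);
      mat Z = D * pw;
      Z.each_row() += bP.value.t();
      z[s] = cube(H, W, Cout);
      std::memcpy(z[s].memptr(), Z.memptr(), sizeof(double) * Z.n_elem);
    }
    // batch norm per channel
    Param& gP = net.P("enc" + std::to_string(l) + "_gamma");
    Param& btP = net.P("enc" + std::to_string(l) + "_beta");
    Param& rmP = net.P("enc" + std::to_string(l) + "_rm");
    Param& rvP = net.P("enc" + std::to_string(l) + "_rv");
    ec.mu.set_size(Cout); ec.invstd.set_size(Cout);
    const double M = (double)N * H * W;
    for (int c = 0; c < Cout; ++c) {
      double mu, var;
      if (training) {
        double sum = 0, sq = 0;
        for (int s = 0; s < N; ++s) {
          sum += accu(z[s].slice(c));
          sq += accu(square(z[s].slice(c)));
        }
        mu = sum / M;
        var = sq / M - mu * mu;
        if (var < 0) var = 0;
        rmP.value(c) = (1 - BN_MOMENTUM) * rmP.value(c) + BN_MOMENTUM * mu;
        rvP.value(c) = (1 - BN_MOMENTUM) * rvP.value(c) + BN_MOMENTUM * var;
      } else {
        mu = rmP.value(c);
        var = rvP.value(c);
      }
      ec.mu(c) = mu;
      ec.invstd(c) = 1.0 / std::sqrt(var + BN_EPS);
    }
    ec.zhat.assign(N, cube());
    ec.relu_out.assign(N, cube());
    ec.argmax.assign(N, Cube<uword>());
    std::vector<cube> pooled(N);
    for (int s = 0; s < N; ++s) {
      cube zh(H, W, Cout), act(H, W, Cout);
      for (int c = 0; c < Cout; ++c) {
        zh.slice(c) = (z[s].slice(c) - ec.mu(c)) * ec.invstd(c);
        act.slice(c) = gP.value(c) * zh.slice(c) + btP.value(c);
      }
      act.transform([](double v) { return v > 0 ? v : 0.0; });
      ec.zhat[s] = zh;
      ec.relu_out[s] = act;
      pooled[s] = maxpool(act, net.pool, ec.argmax[s]);
    }
    cur = pooled;
  }
  cc.latent = cur;

  // regression head
  const int latent_dim = cur[0].n_elem;
  pred.set_size(N, 3);
  if (use_head && net.has_head) {
    cc.head_h.assign(N, std::vector<vec>());
    cc.drop_mask.assign(N, vec());
    std::bernoulli_distribution keep(1.0 - net.dropout);
    for (int s = 0; s < N; ++s) {
      vec h(cur[s].memptr(), latent_dim);
      vec mask(latent_dim, fill::ones);
      if (training && net.dropout > 0) {
        for (int i = 0; i < latent_dim; ++i)
          mask(i) = keep(rng) ? 1.0 / (1.0 - net.dropout) : 0.0;
      }
      h %= mask;
      cc.drop_mask[s] = mask;
      cc.head_h[s].clear();
      cc.head_h[s].push_back(h);
      for (size_t j = 0; j < net.head_u.size(); ++j) {
        Param& W = net.P("head" + std::to_string(j) + "_W");
        Param& b = net.P("head" + std::to_string(j) + "_b");
        vec o = net.as_mat(W).t() * h + b.value;
        if (j + 1 < net.head_u.size())
          o.transform([](double v) { return v > 0 ? v : 0.0; });
        cc.head_h[s].push_back(o);
        h = o;
      }
      pred.row(s) = h.t();
    }
  } else pred.zeros();

  // decoder
  if (use_decoder) {
    cc.dec.assign(net.dec_f.size(), DecCache());
    std::vector<cube> d = cur;
    for (size_t l = 0; l < net.dec_f.size(); ++l) {
      DecCache& dc = cc.dec[l];
      dc.x = d;
      const int Cin = d[0].n_slices, Cout = net.dec_f[l];
      const int H = d[0].n_rows, W = d[0].n_cols;
      Param& WP = net.P("dec" + std::to_string(l) + "_W");
      Param& bP = net.P("dec" + std::to_string(l) + "_b");
      cube Wc = net.as_cube(WP);
      dc.relu_out.assign(N, cube());
      std::vector<cube> up(N);
      for (int s = 0; s < N; ++s) {
        cube o(H, W, Cout);
        for (int co = 0; co < Cout; ++co) o.slice(co).fill(bP.value(co));
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            xcorr_same_acc(d[s].slice(ci), Wc.slice(ci * Cout + co), o.slice(co));
        o.transform([](double v) { return v > 0 ? v : 0.0; });
        dc.relu_out[s] = o;
        up[s] = upsample(o, net.pool);
      }
      d = up;
    }
    Param& oW = net.P("out_W");
    Param& ob = net.P("out_b");
    cube oWc = net.as_cube(oW);
    const int Cd = d[0].n_slices;
    cc.out_x = d;
    cc.recon.assign(N, mat());
    for (int s = 0; s < N; ++s) {
      mat o(net.rows0, net.cols0, fill::value(ob.value(0)));
      for (int ci = 0; ci < Cd; ++ci)
        xcorr_same_acc(d[s].slice(ci), oWc.slice(ci), o);
      cc.recon[s] = 1.0 / (1.0 + exp(-o));
    }
  }
}

// backward one batch. dpred: N x 3 (zeroed if head unused); drecon_z:
// per-sample dL/dz at the final sigmoid pre-activation (empty if no decoder).
static void backward_batch(Net& net, const std::vector<mat>& Xb,
                           FwdCache& cc, const mat& dpred,
                           const std::vector<mat>& drecon_z,
                           bool use_head, bool use_decoder) {
  const int N = Xb.size();
  for (auto& p : net.params) p.grad.zeros();
  std::vector<cube> dlatent(N);
  for (int s = 0; s < N; ++s)
    dlatent[s] = cube(cc.latent[s].n_rows, cc.latent[s].n_cols,
                      cc.latent[s].n_slices, fill::zeros);

  // decoder backward
  if (use_decoder && !drecon_z.empty()) {
    Param& oW = net.P("out_W");
    Param& ob = net.P("out_b");
    cube oWc = net.as_cube(oW);
    cube oWg = net.grad_cube(oW);
    const int Cd = cc.out_x[0].n_slices;
    std::vector<cube> dd(N);
    for (int s = 0; s < N; ++s) {
      const mat& dz = drecon_z[s];
      ob.grad(0) += accu(dz);
      dd[s] = cube(net.rows0, net.cols0, Cd, fill::zeros);
      for (int ci = 0; ci < Cd; ++ci) {
        kernel_grad_acc(cc.out_x[s].slice(ci), dz, oWg.slice(ci));
        xcorr_same_back_acc(dz, oWc.slice(ci), dd[s].slice(ci));
      }
    }
    for (int l = (int)net.dec_f.size() - 1; l >= 0; --l) {
      DecCache& dc = cc.dec[l];
      Param& WP = net.P("dec" + std::to_string(l) + "_W");
      Param& bP = net.P("dec" + std::to_string(l) + "_b");
      cube Wc = net.as_cube(WP);
      cube Wg = net.grad_cube(WP);
      const int Cin = dc.x[0].n_slices, Cout = net.dec_f[l];
      std::vector<cube> dprev(N);
      for (int s = 0; s < N; ++s) {
        cube drelu = upsample_back(dd[s], net.pool);
        for (int co = 0; co < Cout; ++co)
          drelu.slice(co) %= conv_to<mat>::from(dc.relu_out[s].slice(co) > 0);
        for (int co = 0; co < Cout; ++co) bP.grad(co) += accu(drelu.slice(co));
        dprev[s] = cube(dc.x[s].n_rows, dc.x[s].n_cols, Cin, fill::zeros);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co) {
            kernel_grad_acc(dc.x[s].slice(ci), drelu.slice(co),
                            Wg.slice(ci * Cout + co));
            xcorr_same_back_acc(drelu.slice(co), Wc.slice(ci * Cout + co),
                                dprev[s].slice(ci));
          }
      }
      dd = dprev;
    }
    for (int s = 0; s < N; ++s) dlatent[s] += dd[s];
  }

  // head backward
  if (use_head && net.has_head) {
    const int latent_dim = cc.latent[0].n_elem;
    for (int s = 0; s < N; ++s) {
      vec dh = dpred.row(s).t();
      for (int j = (int)net.head_u.size() - 1; j >= 0; --j) {
        Param& W = net.P("head" + std::to_string(j) + "_W");
        Param& b = net.P("head" + std::to_string(j) + "_b");
        if (j + 1 < (int)net.head_u.size()) {
          const vec& o = cc.head_h[s][j + 1];
          for (uword i = 0; i < dh.n_elem; ++i) if (o(i) <= 0) dh(i) = 0;
        }
        const vec& hin = cc.head_h[s][j];
        net.grad_mat(W) += hin * dh.t();
        b.grad += dh;
        dh = net.as_mat(W) * dh;
      }
      dh %= cc.drop_mask[s];
      cube dl(dh.memptr(), cc.latent[s].n_rows, cc.latent[s].n_cols,
              cc.latent[s].n_slices);
      dlatent[s] += dl;
    }
  }

  // encoder backward
  std::vector<cube> dcur = dlatent;
  for (int l = net.n_enc - 1; l >= 0; --l) {
    EncCache& ec = cc.enc[l];
    const int Cout = net.enc_f[l];
    const int H = ec.relu_out[0].n_rows, W = ec.relu_out[0].n_cols;
    const int Cin = ec.x[0].n_slices;
    Param& dwP = net.P("enc" + std::to_string(l) + "_dw");
    Param& pwP = net.P("enc" + std::to_string(l) + "_pw");
    Param& bP  = net.P("enc" + std::to_string(l) + "_b");
    Param& gP  = net.P("enc" + std::to_string(l) + "_gamma");
    Param& btP = net.P("enc" + std::to_string(l) + "_beta");
    cube dw = net.as_cube(dwP);
    mat pw = net.as_mat(pwP);
    // unpool + ReLU
    std::vector<cube> dact(N);
    for (int s = 0; s < N; ++s) {
      dact[s] = cube(H, W, Cout, fill::zeros);
      const Cube<uword>& am = ec.argmax[s];
      for (uword c = 0; c < (uword)Cout; ++c)
        for (uword j = 0; j < am.n_cols; ++j)
          for (uword i = 0; i < am.n_rows; ++i) {
            uword lin = am(i, j, c);
            dact[s](lin % H, lin / H, c) += dcur[s](i, j, c);
          }
      for (int c = 0; c < Cout; ++c)
        dact[s].slice(c) %= conv_to<mat>::from(ec.relu_out[s].slice(c) > 0);
    }
    // batch norm backward (per channel, batch statistics)
    const double M = (double)N * H * W;
    std::vector<cube> dz(N, cube(H, W, Cout));
    for (int c = 0; c < Cout; ++c) {
      double sum_dzh = 0, sum_dzh_zh = 0, dgamma = 0, dbeta = 0;
      for (int s = 0; s < N; ++s) {
        const mat& dy = dact[s].slice(c);
        const mat& zh = ec.zhat[s].slice(c);
        dgamma += accu(dy % zh);
        dbeta += accu(dy);
        sum_dzh += gP.value(c) * accu(dy);
        sum_dzh_zh += gP.value(c) * accu(dy % zh);
      }
      gP.grad(c) += dgamma;
      btP.grad(c) += dbeta;
      for (int s = 0; s < N; ++s) {
        const mat& dy = dact[s].slice(c);
        const mat& zh = ec.zhat[s].slice(c);
        dz[s].slice(c) = ec.invstd(c) *
          (gP.value(c) * dy - sum_dzh / M - zh * (sum_dzh_zh / M));
      }
    }
    // pointwise + depthwise backward
    std::vector<cube> dprev(N);
    const int DM = net.depth_mult;
    for (int s = 0; s < N; ++s) {
      mat dZ(dz[s].memptr(), H * W, Cout, false, true);
      mat D(ec.dconv[s].memptr(), H * W, Cin * DM, false, true);
      net.grad_mat(pwP) += D.t() * dZ;
      bP.grad += sum(dZ, 0).t();
      mat dD = dZ * pw.t();
      cube dDc(dD.memptr(), H, W, Cin * DM);
      dprev[s] = cube(H, W, Cin, fill::zeros);
      cube dwg = net.grad_cube(dwP);
      for (int c = 0; c < Cin; ++c)
        for (int m = 0; m < DM; ++m) {
          kernel_grad_acc(ec.x[s].slice(c), dDc.slice(c * DM + m),
                          dwg.slice(c * DM + m));
          xcorr_same_back_acc(dDc.slice(c * DM + m), dw.slice(c * DM + m),
                              dprev[s].slice(c));
        }
    }
    dcur = dprev;
  }
}

// ---- losses ---------------------------------------------------------------

static double bce_loss(const std::vector<mat>& target,
                       const std::vector<mat>& p) {
  double acc = 0; double n = 0;
  for (size_t s = 0; s < p.size(); ++s) {
    mat pc = clamp(p[s], 1e-7, 1 - 1e-7);
    acc += accu(-(target[s] % log(pc) + (1 - target[s]) % log(1 - pc)));
    n += pc.n_elem;
  }
  return acc / n;
}

// ---- Adam -----------------------------------------------------------------

static void adam_step(Net& net, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
  for (auto& p : net.params) {
    if (!p.trainable) continue;
    p.m = b1 * p.m + (1 - b1) * p.grad;
    p.v = b2 * p.v + (1 - b2) * square(p.grad);
    p.value -= lr * (p.m / bc1) / (sqrt(p.v / bc2) + eps);
  }
}

// ---- evaluation helper ----------------------------------------------------

struct LossParts { double total, reg, rec; };

static LossParts eval_loss(Net& net, const std::vector<mat>& X, const mat& Y,
                           bool use_head, bool use_decoder,
                           double w_reg, double w_rec, std::mt19937& rng) {
  FwdCache cc;
  mat pred;
  forward_batch(net, X, false, use_head, use_decoder, cc, pred, rng);
  LossParts lp{0, 0, 0};
  if (use_head) {
    mat e = pred - Y;
    lp.reg = std::sqrt(accu(square(e)) / e.n_elem);
  }
  if (use_decoder) lp.rec = bce_loss(X, cc.recon);
  lp.total = w_reg * lp.reg * use_head + w_rec * lp.rec * use_decoder;
  return lp;
}

// [[Rcpp::export]]
Rcpp::List dn_train_cpp(Rcpp::List weights, Rcpp::List arch,
                        Rcpp::NumericVector X_, Rcpp::NumericMatrix Y_,
                        Rcpp::NumericVector Xval_, Rcpp::NumericMatrix Yval_,
                        Rcpp::List cfg) {
  Net net = build_net(weights, arch);
  Rcpp::IntegerVector xd = X_.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2];
  std::vector<mat> X(N);
  for (int s = 0; s < N; ++s)
    X[s] = mat(&X_[(size_t)s * H * W], H, W);
  mat Y(Y_.begin(), Y_.nrow(), Y_.ncol());
  std::vector<mat> Xv;
  mat Yv;
  if (Xval_.size() > 0) {
    Rcpp::IntegerVector vd = Xval_.attr("dim");
    for (int s = 0; s < vd[2]; ++s)
      Xv.push_back(mat(&Xval_[(size_t)s * H * W], H, W));
    Yv = mat(Yval_.begin(), Yval_.nrow(), Yval_.ncol());
  }
  const bool use_head = Rcpp::as<bool>(cfg["use_head"]);
  const bool use_decoder = Rcpp::as<bool>(cfg["use_decoder"]);
  const double w_reg = Rcpp::as<double>(cfg["w_reg"]);
  const double w_rec = Rcpp::as<double>(cfg["w_rec"]);
  double lr = Rcpp::as<double>(cfg["initial_lr"]);
  const int lr_patience = Rcpp::as<int>(cfg["lr_patience"]);
  const double lr_factor = Rcpp::as<double>(cfg["lr_factor"]);
  const double lr_min = Rcpp::as<double>(cfg["lr_min"]);
  const int max_epochs = Rcpp::as<int>(cfg["max_epochs"]);
  const int stop_patience = Rcpp::as<int>(cfg["stop_patience"]);
  const int batch_size = Rcpp::as<int>(cfg["batch_size"]);
  std::mt19937 rng(Rcpp::as<unsigned int>(cfg["seed"]));

  std::vector<double> h_lr, h_tr, h_tr_reg, h_tr_rec, h_val, h_val_reg,
      h_val_rec;
  double best_val = datum::inf;
  int lr_wait = 0, stop_wait = 0, adam_t = 0;
  std::vector<vec> best_weights;
  for (auto& p : net.params) best_weights.push_back(p.value);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_tot = 0, ep_reg = 0, ep_rec = 0, ep_n = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int nb = std::min(batch_size, N - start);
      std::vector<mat> Xb(nb);
      mat Yb(nb, 3);
      for (int s = 0; s < nb; ++s) {
        Xb[s] = X[order[start + s]];
        if (use_head) Yb.row(s) = Y.row(order[start + s]);
      }
      FwdCache cc;
      mat pred;
      forward_batch(net, Xb, true, use_head, use_decoder, cc, pred, rng);
      mat dpred(nb, 3, fill::zeros);
      double l_reg = 0, l_rec = 0;
      if (use_head) {
        mat e = pred - Yb;
        l_reg = std::sqrt(accu(square(e)) / e.n_elem);
        if (l_reg > 1e-12) dpred = w_reg * e / (e.n_elem * l_reg);
      }
      std::vector<mat> drecon;
      if (use_decoder) {
        l_rec = bce_loss(Xb, cc.recon);
        double npix = (double)nb * H * W;
        for (int s = 0; s < nb; ++s)
          drecon.push_back(w_rec * (cc.recon[s] - Xb[s]) / npix);
      }
      backward_batch(net, Xb, cc, dpred, drecon, use_head, use_decoder);
      adam_step(net, lr, ++adam_t);
      double l_tot = w_reg * l_reg * use_head + w_rec * l_rec * use_decoder;
      ep_tot += l_tot * nb; ep_reg += l_reg * nb; ep_rec += l_rec * nb;
      ep_n += nb;
    }
    LossParts vl;
    if (!Xv.empty()) vl = eval_loss(net, Xv, Yv, use_head, use_decoder,
                                    w_reg, w_rec, rng);
    else vl = LossParts{ep_tot / ep_n, ep_reg / ep_n, ep_rec / ep_n};
    h_lr.push_back(lr);
    h_tr.push_back(ep_tot / ep_n);
    h_tr_reg.push_back(ep_reg / ep_n);
    h_tr_rec.push_back(ep_rec / ep_n);
    h_val.push_back(vl.total);
    h_val_reg.push_back(vl.reg);
    h_val_rec.push_back(vl.rec);
    // plateau schedule + early stopping on validation loss
    if (vl.total < best_val - 1e-12) {
      best_val = vl.total;
      lr_wait = 0; stop_wait = 0;
      for (size_t i = 0; i < net.params.size(); ++i)
        best_weights[i] = net.params[i].value;
    } else {
      ++lr_wait; ++stop_wait;
      if (lr_wait >= lr_patience) {
        lr = std::max(lr / lr_factor, lr_min);
        lr_wait = 0;
      }
      if (stop_wait >= stop_patience) break;
    }
  }
  for (size_t i = 0; i < net.params.size(); ++i)
    net.params[i].value = best_weights[i];

  return Rcpp::List::create(
    Rcpp::Named("weights") = export_weights(net),
    Rcpp::Named("history") = Rcpp::List::create(
      Rcpp::Named("lr") = h_lr,
      Rcpp::Named("train_total") = h_tr,
      Rcpp::Named("train_reg") = h_tr_reg,
      Rcpp::Named("train_rec") = h_tr_rec,
      Rcpp::Named("val_total") = h_val,
      Rcpp::Named("val_reg") = h_val_reg,
      Rcpp::Named("val_rec") = h_val_rec));
}

// Loss and analytic gradient of one batch (training-mode batch norm, no
// dropout); used to verify backpropagation against finite differences.
// [[Rcpp::export]]
Rcpp::List dn_lossgrad_cpp(Rcpp::List weights, Rcpp::List arch,
                           Rcpp::NumericVector X_, Rcpp::NumericMatrix Y_,
                           bool use_head, bool use_decoder,
                           double w_reg, double w_rec) {
  Net net = build_net(weights, arch);
  net.dropout = 0.0;
  Rcpp::IntegerVector xd = X_.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2];
  std::vector<mat> Xb(N);
  for (int s = 0; s < N; ++s)
    Xb[s] = mat(&X_[(size_t)s * H * W], H, W);
  mat Y(Y_.begin(), Y_.nrow(), Y_.ncol());
  FwdCache cc;
  mat pred;
  std::mt19937 rng(1);
  forward_batch(net, Xb, true, use_head, use_decoder, cc, pred, rng);
  mat dpred(N, 3, fill::zeros);
  double l_reg = 0, l_rec = 0;
  if (use_head) {
    mat e = pred - Y;
    l_reg = std::sqrt(accu(square(e)) / e.n_elem);
    if (l_reg > 1e-12) dpred = w_reg * e / (e.n_elem * l_reg);
  }
  std::vector<mat> drecon;
  if (use_decoder) {
    l_rec = bce_loss(Xb, cc.recon);
    double npix = (double)N * H * W;
    for (int s = 0; s < N; ++s)
      drecon.push_back(w_rec * (cc.recon[s] - Xb[s]) / npix);
  }
  backward_batch(net, Xb, cc, dpred, drecon, use_head, use_decoder);
  Rcpp::List grads;
  for (auto& p : net.params) {
    Rcpp::NumericVector g(p.grad.begin(), p.grad.end());
    grads[p.name] = g;
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = w_reg * l_reg * use_head + w_rec * l_rec * use_decoder,
    Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::List dn_forward_cpp(Rcpp::List weights, Rcpp::List arch,
                          Rcpp::NumericVector X_, bool use_head,
                          bool use_decoder) {
  Net net = build_net(weights, arch);
  Rcpp::IntegerVector xd = X_.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2];
  std::vector<mat> X(N);
  for (int s = 0; s < N; ++s)
    X[s] = mat(&X_[(size_t)s * H * W], H, W);
  FwdCache cc;
  mat pred;
  std::mt19937 rng(1);
  forward_batch(net, X, false, use_head, use_decoder, cc, pred, rng);
  Rcpp::NumericVector recon;
  if (use_decoder) {
    recon = Rcpp::NumericVector((size_t)H * W * N);
    for (int s = 0; s < N; ++s)
      std::copy(cc.recon[s].begin(), cc.recon[s].end(),
                recon.begin() + (size_t)s * H * W);
    recon.attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("recon") = recon);
}
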