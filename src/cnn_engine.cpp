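// Minimal CNN training engine used by the RANet and QNN-head models.
// Layers: conv2d (stride 1, zero padding), relu, batchnorm, 2x2 maxpool
// (floor semantics), global average pooling, flatten, dense.  Losses:
// softmax + categorical cross-entropy, sigmoid + binary cross-entropy.
// Optimizers: plain SGD (optional momentum) and Adam.  All randomness
// (init, shuffling) comes from one std::mt19937 seeded from R.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

enum LType { L_CONV, L_RELU, L_BN, L_POOL, L_GAP, L_FLAT, L_DENSE };

struct Layer {
  int type = 0;
  // conv
  int kh = 0, kw = 0, cin = 0, cout = 0, pad = 0;
  // dense
  int nin = 0, nout = 0;
  // shapes at this layer's output
  int out_h = 0, out_w = 0, out_c = 0;
  bool spatial_in = true, spatial_out = true;
  // parameters
  mat W;  vec b;                      // conv: cout x (kh*kw*cin); dense: nout x nin
  vec gamma, beta, rmean, rvar;       // batchnorm
  // gradients
  mat dW; vec db; vec dgamma, dbeta;
  // optimizer state
  mat mW, vW; vec mb, vb, mg, vg, mbe, vbe;
  // caches (per batch)
  std::vector<mat> cols;              // conv im2col inputs
  std::vector<cube> xhat;             // bn normalized inputs
  vec bn_invstd;
  std::vector<ucube> argmax;          // pool argmax linear index into input slice
  mat flat_in;                        // dense input (N x nin)
  std::vector<cube> sp_out;           // spatial output
  mat fl_out;                         // flat output (N x d)
};

struct Net {
  std::vector<Layer> layers;
  int in_h = 0, in_w = 0, in_c = 0;
  std::string loss;                   // "cce" or "bce"
  double bn_momentum = 0.99, bn_eps = 1e-3;
  std::mt19937 rng;

  void build(Rcpp::List lspec, int H, int W, int C) {
    in_h = H; in_w = W; in_c = C;
    int h = H, w = W, c = C;
    bool spatial = true;
    for (int i = 0; i < lspec.size(); i++) {
      Rcpp::List ls = lspec[i];
      std::string ty = Rcpp::as<std::string>(ls["type"]);
      Layer L;
      L.spatial_in = spatial;
      if (ty == "conv") {
        L.type = L_CONV;
        L.kh = Rcpp::as<int>(ls["k"]); L.kw = L.kh;
        L.cin = c; L.cout = Rcpp::as<int>(ls["out"]);
        L.pad = Rcpp::as<int>(ls["pad"]);
        h = h + 2 * L.pad - L.kh + 1;
        w = w + 2 * L.pad - L.kw + 1;
        if (h < 1 || w < 1) Rcpp::stop("conv output size collapsed");
        c = L.cout;
      } else if (ty == "relu") {
        L.type = L_RELU;
      } else if (ty == "bn") {
        L.type = L_BN;
      } else if (ty == "pool") {
        L.type = L_POOL;
        h = h / 2; w = w / 2;
        if (h < 1 || w < 1) Rcpp::stop("pool output size collapsed");
      } else if (ty == "gap") {
        L.type = L_GAP; spatial = false;
      } else if (ty == "flat") {
        L.type = L_FLAT; spatial = false;
      } else if (ty == "dense") {
        L.type = L_DENSE;
        L.nin = spatial ? h * w * c : c;
        if (!L.spatial_in) L.nin = c;
        L.nout = Rcpp::as<int>(ls["out"]);
        c = L.nout;
      } else Rcpp::stop("unknown layer type: " + ty);
      if (L.type == L_FLAT) c = h * w * c;
      L.out_h = h; L.out_w = w; L.out_c = c;
      L.spatial_out = spatial;
      layers.push_back(L);
    }
  }

  void init_params(int seed) {
    rng.seed((unsigned)seed);
    for (auto &L : layers) {
      if (L.type == L_CONV) {
        double lim = std::sqrt(6.0 / (L.kh * L.kw * L.cin));
        std::uniform_real_distribution<double> U(-lim, lim);
        L.W.set_size(L.cout, L.kh * L.kw * L.cin);
        for (uword j = 0; j < L.W.n_elem; j++) L.W(j) = U(rng);
        L.b.zeros(L.cout);
      } else if (L.type == L_DENSE) {
        double lim = std::sqrt(6.0 / L.nin);
        std::uniform_real_distribution<double> U(-lim, lim);
        L.W.set_size(L.nout, L.nin);
        for (uword j = 0; j < L.W.n_elem; j++) L.W(j) = U(rng);
        L.b.zeros(L.nout);
      } else if (L.type == L_BN) {
        int ch = L.out_c;
        if (!L.spatial_in) ch = L.out_c;  // bn only used spatially here
        L.gamma.ones(ch); L.beta.zeros(ch);
        L.rmean.zeros(ch); L.rvar.ones(ch);
      }
    }
  }

  // ---- forward ----------------------------------------------------------

  static mat im2col(const cube &x, int kh, int kw, int pad) {
    int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
    mat out(kh * kw * C, Ho * Wo);
    for (int c = 0; c < C; c++) {
      const mat &sl = x.slice(c);
      for (int dj = 0; dj < kw; dj++) for (int di = 0; di < kh; di++) {
        int r = c * kh * kw + dj * kh + di;
        for (int j = 0; j < Wo; j++) {
          int sj = j + dj - pad;
          double *op = out.colptr(0) + r;  // row r, strided access
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < Ho; i++) out(r, i + j * Ho) = 0.0;
            continue;
          }
          for (int i = 0; i < Ho; i++) {
            int si = i + di - pad;
            out(r, i + j * Ho) = (si >= 0 && si < H) ? sl(si, sj) : 0.0;
          }
          (void)op;
        }
      }
    }
    return out;
  }

  static void col2im(const mat &cols, cube &dx, int kh, int kw, int pad) {
    int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
    int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
    for (int c = 0; c < C; c++) {
      mat &sl = dx.slice(c);
      for (int dj = 0; dj < kw; dj++) for (int di = 0; di < kh; di++) {
        int r = c * kh * kw + dj * kh + di;
        for (int j = 0; j < Wo; j++) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; i++) {
            int si = i + di - pad;
            if (si >= 0 && si < H) sl(si, sj) += cols(r, i + j * Ho);
          }
        }
      }
    }
  }

  // Forward a batch.  `training` toggles batch statistics + caching.
  // Returns final logits (N x out_dim).
  mat forward(const std::vector<cube> &input, bool training) {
    size_t N = input.size();
    std::vector<cube> sp = input;
    mat fl;
    bool spatial = true;
    for (auto &L : layers) {
      if (L.type == L_CONV) {
        std::vector<cube> out(N);
        if (training) L.cols.assign(N, mat());
        for (size_t n = 0; n < N; n++) {
          mat cols = im2col(sp[n], L.kh, L.kw, L.pad);
          mat O = L.W * cols;
          O.each_col() += L.b;
          cube oc(L.out_h, L.out_w, L.cout);
          for (int cch = 0; cch < L.cout; cch++)
            oc.slice(cch) = reshape(O.row(cch), L.out_h, L.out_w);
          out[n] = std::move(oc);
          if (training) L.cols[n] = std::move(cols);
        }
        sp = std::move(out);
      } else if (L.type == L_RELU) {
        if (spatial) { for (auto &x : sp) x.transform([](double v){ return v > 0 ? v : 0.0; }); }
        else fl.transform([](double v){ return v > 0 ? v : 0.0; });
      } else if (L.type == L_BN) {
        int C = sp[0].n_slices;
        double m = (double)(N * sp[0].n_rows * sp[0].n_cols);
        if (training) {
          vec mu(C), va(C);
          for (int c = 0; c < C; c++) {
            double s = 0, s2 = 0;
            for (size_t n = 0; n < N; n++) {
              s += accu(sp[n].slice(c));
              s2 += accu(square(sp[n].slice(c)));
            }
            mu(c) = s / m;
            va(c) = s2 / m - mu(c) * mu(c);
            if (va(c) < 0) va(c) = 0;
          }
          L.bn_invstd = 1.0 / sqrt(va + bn_eps);
          L.xhat.assign(N, cube(sp[0].n_rows, sp[0].n_cols, C));
          for (size_t n = 0; n < N; n++) {
            for (int c = 0; c < C; c++) {
              L.xhat[n].slice(c) = (sp[n].slice(c) - mu(c)) * L.bn_invstd(c);
              sp[n].slice(c) = L.gamma(c) * L.xhat[n].slice(c) + L.beta(c);
            }
          }
          L.rmean = bn_momentum * L.rmean + (1 - bn_momentum) * mu;
          L.rvar = bn_momentum * L.rvar + (1 - bn_momentum) * va;
        } else {
          for (size_t n = 0; n < N; n++)
            for (int c = 0; c < C; c++)
              sp[n].slice(c) = L.gamma(c) * (sp[n].slice(c) - L.rmean(c)) /
                std::sqrt(L.rvar(c) + bn_eps) + L.beta(c);
        }
      } else if (L.type == L_POOL) {
        std::vector<cube> out(N);
        if (training) L.argmax.assign(N, ucube());
        for (size_t n = 0; n < N; n++) {
          int Hi = sp[n].n_rows, Wi = sp[n].n_cols, C = sp[n].n_slices;
          int Ho = Hi / 2, Wo = Wi / 2;
          cube oc(Ho, Wo, C);
          ucube am(Ho, Wo, C);
          for (int c = 0; c < C; c++) {
            const mat &sl = sp[n].slice(c);
            for (int j = 0; j < Wo; j++) for (int i = 0; i < Ho; i++) {
              int bi = 2 * i, bj = 2 * j;
              double best = sl(bi, bj); uword idx = bi + bj * Hi;
              if (sl(bi + 1, bj) > best) { best = sl(bi + 1, bj); idx = bi + 1 + bj * Hi; }
              if (sl(bi, bj + 1) > best) { best = sl(bi, bj + 1); idx = bi + (bj + 1) * Hi; }
              if (sl(bi + 1, bj + 1) > best) { best = sl(bi + 1, bj + 1); idx = bi + 1 + (bj + 1) * Hi; }
              oc(i, j, c) = best;
              am(i, j, c) = idx;
            }
          }
          out[n] = std::move(oc);
          if (training) L.argmax[n] = std::move(am);
        }
        sp = std::move(out);
      } else if (L.type == L_GAP) {
        fl.set_size(N, sp[0].n_slices);
        for (size_t n = 0; n < N; n++)
          for (uword c = 0; c < sp[0].n_slices; c++)
            fl(n, c) = accu(sp[n].slice(c)) / (double)(sp[n].n_rows * sp[n].n_cols);
        spatial = false;
      } else if (L.type == L_FLAT) {
        fl.set_size(N, sp[0].n_elem);
        for (size_t n = 0; n < N; n++)
          fl.row(n) = vectorise(sp[n]).t();
        spatial = false;
      } else if (L.type == L_DENSE) {
        if (training) L.flat_in = fl;
        fl = fl * L.W.t();
        fl.each_row() += L.b.t();
      }
      if (training) { if (spatial) L.sp_out = sp; else L.fl_out = fl; }
    }
    return fl;
  }

  // Backward from dlogits (already averaged over batch); accumulates grads.
  void backward(const std::vector<cube> &input, const mat &dlogits) {
    size_t N = input.size();
    mat dfl = dlogits;
    std::vector<cube> dsp;
    for (int li = (int)layers.size() - 1; li >= 0; li--) {
      Layer &L = layers[li];
      // input to this layer:
      const std::vector<cube> *sp_in = nullptr;
      const mat *fl_in = nullptr;
      if (li == 0) sp_in = &input;
      else {
        Layer &P = layers[li - 1];
        if (P.spatial_out) sp_in = &P.sp_out; else fl_in = &P.fl_out;
      }
      if (L.type == L_DENSE) {
        L.dW += dfl.t() * L.flat_in;
        L.db += sum(dfl, 0).t();
        dfl = dfl * L.W;
      } else if (L.type == L_RELU) {
        if (L.spatial_out) {
          for (size_t n = 0; n < N; n++)
            dsp[n] %= conv_to<cube>::from(L.sp_out[n] > 0);
        } else {
          dfl %= conv_to<mat>::from(L.fl_out > 0);
        }
      } else if (L.type == L_GAP) {
        const std::vector<cube> &xin = *sp_in;
        dsp.assign(N, cube(xin[0].n_rows, xin[0].n_cols, xin[0].n_slices));
        double hw = (double)(xin[0].n_rows * xin[0].n_cols);
        for (size_t n = 0; n < N; n++)
          for (uword c = 0; c < xin[0].n_slices; c++)
            dsp[n].slice(c).fill(dfl(n, c) / hw);
      } else if (L.type == L_FLAT) {
        const std::vector<cube> &xin = *sp_in;
        dsp.assign(N, cube(xin[0].n_rows, xin[0].n_cols, xin[0].n_slices));
        for (size_t n = 0; n < N; n++) {
          vec v = dfl.row(n).t();
          dsp[n] = cube(v.memptr(), xin[0].n_rows, xin[0].n_cols, xin[0].n_slices);
        }
      } else if (L.type == L_POOL) {
        const std::vector<cube> &xin = *sp_in;
        std::vector<cube> dout(N);
        for (size_t n = 0; n < N; n++) {
          cube d(xin[n].n_rows, xin[n].n_cols, xin[n].n_slices, fill::zeros);
          for (uword c = 0; c < d.n_slices; c++) {
            mat &dslice = d.slice(c);
            for (uword j = 0; j < dsp[n].n_cols; j++)
              for (uword i = 0; i < dsp[n].n_rows; i++)
                dslice(L.argmax[n](i, j, c)) += dsp[n](i, j, c);
          }
          dout[n] = std::move(d);
        }
        dsp = std::move(dout);
      } else if (L.type == L_BN) {
        int C = dsp[0].n_slices;
        double m = (double)(N * dsp[0].n_rows * dsp[0].n_cols);
        vec dg(C, fill::zeros), db(C, fill::zeros);
        for (int c = 0; c < C; c++) {
          for (size_t n = 0; n < N; n++) {
            dg(c) += accu(dsp[n].slice(c) % L.xhat[n].slice(c));
            db(c) += accu(dsp[n].slice(c));
          }
        }
        L.dgamma += dg; L.dbeta += db;
        for (size_t n = 0; n < N; n++)
          for (int c = 0; c < C; c++)
            dsp[n].slice(c) = (L.gamma(c) * L.bn_invstd(c)) *
              (dsp[n].slice(c) - db(c) / m - L.xhat[n].slice(c) * dg(c) / m);
      } else if (L.type == L_CONV) {
        const std::vector<cube> &xin = *sp_in;
        std::vector<cube> dout(N);
        for (size_t n = 0; n < N; n++) {
          mat dO(L.cout, L.out_h * L.out_w);
          for (int c = 0; c < L.cout; c++)
            dO.row(c) = vectorise(dsp[n].slice(c)).t();
          L.dW += dO * L.cols[n].t();
          L.db += sum(dO, 1);
          mat dcols = L.W.t() * dO;
          cube d(xin[n].n_rows, xin[n].n_cols, xin[n].n_slices, fill::zeros);
          col2im(dcols, d, L.kh, L.kw, L.pad);
          dout[n] = std::move(d);
        }
        dsp = std::move(dout);
      }
      // transition flat -> spatial happens inside GAP/FLAT above
      (void)fl_in;
    }
  }

  void zero_grads() {
    for (auto &L : layers) {
      if (L.type == L_CONV || L.type == L_DENSE) {
        L.dW.zeros(L.W.n_rows, L.W.n_cols);
        L.db.zeros(L.b.n_elem);
      } else if (L.type == L_BN) {
        L.dgamma.zeros(L.gamma.n_elem);
        L.dbeta.zeros(L.beta.n_elem);
      }
    }
  }

  void step_sgd(double lr, double momentum) {
    for (auto &L : layers) {
      if (L.type == L_CONV || L.type == L_DENSE) {
        if (momentum > 0) {
          if (L.mW.n_elem == 0) { L.mW.zeros(size(L.W)); L.mb.zeros(L.b.n_elem); }
          L.mW = momentum * L.mW + L.dW;
          L.mb = momentum * L.mb + L.db;
          L.W -= lr * L.mW; L.b -= lr * L.mb;
        } else {
          L.W -= lr * L.dW; L.b -= lr * L.db;
        }
      } else if (L.type == L_BN) {
        L.gamma -= lr * L.dgamma; L.beta -= lr * L.dbeta;
      }
    }
  }

  int adam_t = 0;
  void step_adam(double lr, double b1, double b2, double eps) {
    adam_t++;
    double c1 = 1 - std::pow(b1, adam_t), c2 = 1 - std::pow(b2, adam_t);
    for (auto &L : layers) {
      if (L.type == L_CONV || L.type == L_DENSE) {
        if (L.mW.n_elem == 0) {
          L.mW.zeros(size(L.W)); L.vW.zeros(size(L.W));
          L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
        }
        L.mW = b1 * L.mW + (1 - b1) * L.dW;
        L.vW = b2 * L.vW + (1 - b2) * square(L.dW);
        L.mb = b1 * L.mb + (1 - b1) * L.db;
        L.vb = b2 * L.vb + (1 - b2) * square(L.db);
        L.W -= lr * (L.mW / c1) / (sqrt(L.vW / c2) + eps);
        L.b -= lr * (L.mb / c1) / (sqrt(L.vb / c2) + eps);
      } else if (L.type == L_BN) {
        if (L.mg.n_elem == 0) {
          L.mg.zeros(L.gamma.n_elem); L.vg.zeros(L.gamma.n_elem);
          L.mbe.zeros(L.beta.n_elem); L.vbe.zeros(L.beta.n_elem);
        }
        L.mg = b1 * L.mg + (1 - b1) * L.dgamma;
        L.vg = b2 * L.vg + (1 - b2) * square(L.dgamma);
        L.mbe = b1 * L.mbe + (1 - b1) * L.dbeta;
        L.vbe = b2 * L.vbe + (1 - b2) * square(L.dbeta);
        L.gamma -= lr * (L.mg / c1) / (sqrt(L.vg / c2) + eps);
        L.beta -= lr * (L.mbe / c1) / (sqrt(L.vbe / c2) + eps);
      }
    }
  }

  void clear_caches() {
    for (auto &L : layers) {
      L.cols.clear(); L.xhat.clear(); L.argmax.clear();
      L.sp_out.clear(); L.fl_out.reset(); L.flat_in.reset();
    }
  }
};

// ---- R interface ---------------------------------------------------------

static std::vector<cube> slice_batch(const double *xp, int H, int W, int C,
                                     const std::vector<int> &idx) {
  std::vector<cube> out(idx.size());
  size_t per = (size_t)H * W * C;
  for (size_t k = 0; k < idx.size(); k++)
    out[k] = cube(const_cast<double *>(xp + per * idx[k]), H, W, C, true);
  return out;
}

static mat activate_output(const mat &logits, const std::string &loss) {
  if (loss == "cce") {
    mat z = logits;
    z.each_col() -= max(z, 1);
    mat e = exp(z);
    e.each_col() /= sum(e, 1);
    return e;
  }
  return 1.0 / (1.0 + exp(-logits));
}

static double loss_value(const mat &prob, const mat &y, const std::string &loss) {
  double eps = 1e-12;
  if (loss == "cce") return -accu(y % log(prob + eps)) / prob.n_rows;
  return -accu(y % log(prob + eps) + (1 - y) % log(1 - prob + eps)) / prob.n_rows;
}

static double accuracy(const mat &prob, const mat &y, const std::string &loss) {
  int correct = 0;
  for (uword n = 0; n < prob.n_rows; n++) {
    if (loss == "cce") {
      if (y(n, prob.row(n).index_max()) > 0.5) correct++;
    } else {
      if ((prob(n, 0) > 0.5) == (y(n, 0) > 0.5)) correct++;
    }
  }
  return (double)correct / prob.n_rows;
}

static Rcpp::List export_weights(const Net &net) {
  Rcpp::List out;
  for (auto &L : net.layers) {
    Rcpp::List lw;
    if (L.type == L_CONV || L.type == L_DENSE) {
      lw["W"] = Rcpp::wrap(L.W); lw["b"] = Rcpp::wrap(L.b);
    } else if (L.type == L_BN) {
      lw["gamma"] = Rcpp::wrap(L.gamma); lw["beta"] = Rcpp::wrap(L.beta);
      lw["rmean"] = Rcpp::wrap(L.rmean); lw["rvar"] = Rcpp::wrap(L.rvar);
    }
    out.push_back(lw);
  }
  return out;
}

static void import_weights(Net &net, Rcpp::List w) {
  for (size_t i = 0; i < net.layers.size(); i++) {
    Layer &L = net.layers[i];
    Rcpp::List lw = w[i];
    if (L.type == L_CONV || L.type == L_DENSE) {
      L.W = Rcpp::as<mat>(lw["W"]); L.b = Rcpp::as<vec>(lw["b"]);
    } else if (L.type == L_BN) {
      L.gamma = Rcpp::as<vec>(lw["gamma"]); L.beta = Rcpp::as<vec>(lw["beta"]);
      L.rmean = Rcpp::as<vec>(lw["rmean"]); L.rvar = Rcpp::as<vec>(lw["rvar"]);
    }
  }
}

static Net make_net(Rcpp::List layers, Rcpp::IntegerVector dims,
                    std::string loss, double bn_momentum, double bn_eps) {
  Net net;
  net.loss = loss;
  net.bn_momentum = bn_momentum;
  net.bn_eps = bn_eps;
  net.build(layers, dims[0], dims[1], dims[2]);
  return net;
}

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(Rcpp::List layers, Rcpp::IntegerVector in_dim, int seed) {
  Net net = make_net(layers, in_dim, "cce", 0.99, 1e-3);
  net.init_params(seed);
  return export_weights(net);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List layers, Rcpp::NumericVector X,
                         Rcpp::NumericMatrix Y, Rcpp::NumericVector Xval,
                         Rcpp::NumericMatrix Yval, Rcpp::List opts) {
  Rcpp::IntegerVector xd = X.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::string loss = Rcpp::as<std::string>(opts["loss"]);
  Net net = make_net(layers, Rcpp::IntegerVector::create(H, W, C), loss,
                     Rcpp::as<double>(opts["bn_momentum"]),
                     Rcpp::as<double>(opts["bn_eps"]));
  int seed = Rcpp::as<int>(opts["seed"]);
  net.init_params(seed);
  if (opts.containsElementNamed("weights") &&
      !Rf_isNull(opts["weights"])) import_weights(net, opts["weights"]);

  std::string optim = Rcpp::as<std::string>(opts["optimizer"]);
  double lr = Rcpp::as<double>(opts["lr"]);
  double momentum = Rcpp::as<double>(opts["momentum"]);
  int batch = Rcpp::as<int>(opts["batch_size"]);
  int epochs = Rcpp::as<int>(opts["epochs"]);
  mat y = Rcpp::as<mat>(Y);

  bool has_val = Xval.size() > 0;
  int Nv = 0, eval_batch = 64;
  mat yv;
  if (has_val) {
    Rcpp::IntegerVector vd = Xval.attr("dim");
    Nv = vd[3];
    yv = Rcpp::as<mat>(Yval);
  }

  std::vector<int> order(N);
  for (int i = 0; i < N; i++) order[i] = i;

  mat history(epochs, 4);  // train loss, train acc, val loss, val acc
  double best_val = -1;
  int best_epoch = -1;
  Rcpp::List best_weights = R_NilValue;

  for (int ep = 0; ep < epochs; ep++) {
    std::shuffle(order.begin(), order.end(), net.rng);
    double tr_loss = 0, tr_acc = 0;
    int nb = 0;
    for (int start = 0; start < N; start += batch) {
      int end = std::min(N, start + batch);
      std::vector<int> idx(order.begin() + start, order.begin() + end);
      std::vector<cube> xb = slice_batch(X.begin(), H, W, C, idx);
      mat yb(idx.size(), y.n_cols);
      for (size_t k = 0; k < idx.size(); k++) yb.row(k) = y.row(idx[k]);
      net.zero_grads();
      mat logits = net.forward(xb, true);
      mat prob = activate_output(logits, loss);
      tr_loss += loss_value(prob, yb, loss);
      tr_acc += accuracy(prob, yb, loss);
      nb++;
      mat dlogits = (prob - yb) / (double)idx.size();
      net.backward(xb, dlogits);
      if (optim == "adam") net.step_adam(lr, 0.9, 0.999, 1e-8);
      else net.step_sgd(lr, momentum);
    }
    net.clear_caches();
    history(ep, 0) = tr_loss / nb;
    history(ep, 1) = tr_acc / nb;
    double v_loss = NA_REAL, v_acc = NA_REAL;
    if (has_val) {
      double vl = 0, va = 0; int vn = 0;
      for (int start = 0; start < Nv; start += eval_batch) {
        int end = std::min(Nv, start + eval_batch);
        std::vector<int> idx;
        for (int i = start; i < end; i++) idx.push_back(i);
        std::vector<cube> xb = slice_batch(Xval.begin(), H, W, C, idx);
        mat logits = net.forward(xb, false);
        mat prob = activate_output(logits, loss);
        mat yb(idx.size(), yv.n_cols);
        for (size_t k = 0; k < idx.size(); k++) yb.row(k) = yv.row(idx[k]);
        vl += loss_value(prob, yb, loss) * idx.size();
        va += accuracy(prob, yb, loss) * idx.size();
        vn += idx.size();
      }
      v_loss = vl / vn; v_acc = va / vn;
      if (v_acc > best_val) {
        best_val = v_acc; best_epoch = ep + 1;
        best_weights = export_weights(net);
      }
    }
    history(ep, 2) = v_loss;
    history(ep, 3) = v_acc;
    Rcpp::checkUserInterrupt();
  }
  if (!has_val) { best_weights = export_weights(net); best_epoch = epochs; best_val = NA_REAL; }
  return Rcpp::List::create(
    Rcpp::Named("weights") = export_weights(net),
    Rcpp::Named("best_weights") = best_weights,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_accuracy") = best_val,
    Rcpp::Named("history") = Rcpp::wrap(history));
}

// Forward pass in inference mode.  upto = 0 returns activated final output
// (probabilities); upto = k (1-based layer index) returns that layer's
// output flattened to N x d (column-major within a sample).
// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_forward_cpp(Rcpp::List layers, Rcpp::List weights,
                                    Rcpp::NumericVector X, std::string loss,
                                    double bn_eps, int upto) {
  Rcpp::IntegerVector xd = X.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Net net = make_net(layers, Rcpp::IntegerVector::create(H, W, C), loss,
                     0.99, bn_eps);
  net.init_params(1);
  import_weights(net, weights);
  if (upto > 0) {
    // truncate the network after layer `upto`
    net.layers.resize(upto);
  }
  int chunk = 64;
  Rcpp::NumericMatrix out;
  bool first = true;
  int dcols = 0;
  for (int start = 0; start < N; start += chunk) {
    int end = std::min(N, start + chunk);
    std::vector<int> idx;
    for (int i = start; i < end; i++) idx.push_back(i);
    std::vector<cube> xb = slice_batch(X.begin(), H, W, C, idx);
    mat res;
    if (upto > 0 && net.layers.back().spatial_out) {
      // run forward manually then flatten spatial output
      mat dummy = net.forward(xb, true);  // training=true caches sp_out
      const std::vector<cube> &so = net.layers.back().sp_out;
      res.set_size(idx.size(), so[0].n_elem);
      for (size_t k = 0; k < idx.size(); k++) res.row(k) = vectorise(so[k]).t();
      net.clear_caches();
    } else {
      mat logits = net.forward(xb, false);
      res = (upto == 0) ? activate_output(logits, loss) : logits;
    }
    if (first) { dcols = res.n_cols; out = Rcpp::NumericMatrix(N, dcols); first = false; }
    for (size_t k = 0; k < idx.size(); k++)
      for (int j = 0; j < dcols; j++) out(start + k, j) = res(k, j);
  }
  return out;
}

// Gradients of the mean loss w.r.t. all parameters, for finite-difference
// testing.  Uses training-mode forward (batch statistics).
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::List layers, Rcpp::List weights,
                        Rcpp::NumericVector X, Rcpp::NumericMatrix Y,
                        std::string loss, double bn_eps) {
  Rcpp::IntegerVector xd = X.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Net net = make_net(layers, Rcpp::IntegerVector::create(H, W, C), loss,
                     0.99, bn_eps);
  net.init_params(1);
  import_weights(net, weights);
  std::vector<int> idx;
  for (int i = 0; i < N; i++) idx.push_back(i);
  std::vector<cube> xb = slice_batch(X.begin(), H, W, C, idx);
  mat y = Rcpp::as<mat>(Y);
  net.zero_grads();
  mat logits = net.forward(xb, true);
  mat prob = activate_output(logits, loss);
  double lv = loss_value(prob, y, loss);
  mat dlogits = (prob - y) / (double)N;
  net.backward(xb, dlogits);
  Rcpp::List grads;
  for (auto &L : net.layers) {
    Rcpp::List lg;
    if (L.type == L_CONV || L.type == L_DENSE) {
      lg["W"] = Rcpp::wrap(L.dW); lg["b"] = Rcpp::wrap(L.db);
    } else if (L.type == L_BN) {
      lg["gamma"] = Rcpp::wrap(L.dgamma); lg["beta"] = Rcpp::wrap(L.dbeta);
    }
    grads.push_back(lg);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = lv,
                            Rcpp::Named("grads") = grads);
}

// Training-mode loss only (batch statistics), for finite differences.
// [[Rcpp::export]]
double cnn_loss_cpp(Rcpp::List layers, Rcpp::List weights,
                    Rcpp::NumericVector X, Rcpp::NumericMatrix Y,
                    std::string loss, double bn_eps) {
  Rcpp::IntegerVector xd = X.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Net net = make_net(layers, Rcpp::IntegerVector::create(H, W, C), loss,
                     0.99, bn_eps);
  net.init_params(1);
  import_weights(net, weights);
  std::vector<int> idx;
  for (int i = 0; i < N; i++) idx.push_back(i);
  std::vector<cube> xb = slice_batch(X.begin(), H, W, C, idx);
  mat y = Rcpp::as<mat>(Y);
  mat logits = net.forward(xb, true);
  mat prob = activate_output(logits, loss);
  net.clear_caches();
  return loss_value(prob, y, loss);
}
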