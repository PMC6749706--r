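// 3D convolutional block classifier: im2col + GEMM convolutions in single
// precision, trained with Adam on binary cross-entropy.  The architecture is
// the fixed 14-layer stack used throughout the package (two 8^3 convolutions,
// pool, two 4^3 convolutions, pool, two 2^3 convolutions, dense 128, sigmoid).
// All randomness (shuffling, dropout) is drawn from R's RNG so that set.seed()
// on the R side makes training reproducible.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

// "same" padding for even kernels pads (k-1)/2 in front, rest behind
static inline int pad_before(int k) { return (k - 1) / 2; }

// in: (D^3) x Cin, voxel v = x + D*y + D*D*z.  out: (D^3) x (Cin*k^3),
// column index c*k^3 + dz*k^2 + dy*k + dx.
static void im2col(const fmat &in, int D, int k, fmat &out) {
  const int Cin = in.n_cols, nvox = D * D * D, p = pad_before(k);
  out.zeros(nvox, Cin * k * k * k);
  for (int c = 0; c < Cin; ++c) {
    const float *src = in.colptr(c);
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          float *dst = out.colptr(c * k * k * k + dz * k * k + dy * k + dx);
          const int x0 = std::max(0, p - dx), x1 = std::min(D, D + p - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < D; ++z) {
            const int iz = z + dz - p;
            if (iz < 0 || iz >= D) continue;
            for (int y = 0; y < D; ++y) {
              const int iy = y + dy - p;
              if (iy < 0 || iy >= D) continue;
              std::memcpy(dst + x0 + D * (y + D * z),
                          src + (x0 + dx - p) + D * (iy + D * iz),
                          sizeof(float) * (x1 - x0));
            }
          }
        }
  }
}

// scatter-add transpose of im2col (for gradients w.r.t. a conv input)
static void col2im(const fmat &colmat, int D, int k, int Cin, fmat &dinput) {
  const int p = pad_before(k);
  dinput.zeros(D * D * D, Cin);
  for (int c = 0; c < Cin; ++c) {
    float *dst = dinput.colptr(c);
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const float *src = colmat.colptr(c * k * k * k + dz * k * k + dy * k + dx);
          const int x0 = std::max(0, p - dx), x1 = std::min(D, D + p - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < D; ++z) {
            const int iz = z + dz - p;
            if (iz < 0 || iz >= D) continue;
            for (int y = 0; y < D; ++y) {
              const int iy = y + dy - p;
              if (iy < 0 || iy >= D) continue;
              float *d = dst + (x0 + dx - p) + D * (iy + D * iz);
              const float *s = src + x0 + D * (y + D * z);
              for (int x = 0; x < x1 - x0; ++x) d[x] += s[x];
            }
          }
        }
  }
}

// 2x2x2 max pooling, stride 2; records the winning input row per output cell
static void maxpool(const fmat &in, int D, fmat &out, arma::umat &argmax) {
  const int Do = D / 2, C = in.n_cols;
  out.set_size(Do * Do * Do, C);
  argmax.set_size(Do * Do * Do, C);
  for (int c = 0; c < C; ++c) {
    const float *src = in.colptr(c);
    for (int oz = 0; oz < Do; ++oz)
      for (int oy = 0; oy < Do; ++oy)
        for (int ox = 0; ox < Do; ++ox) {
          float best = -std::numeric_limits<float>::infinity();
          int bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int idx = (2 * ox + dx) + D * ((2 * oy + dy) + D * (2 * oz + dz));
                if (src[idx] > best) { best = src[idx]; bidx = idx; }
              }
          const int o = ox + Do * (oy + Do * oz);
          out(o, c) = best;
          argmax(o, c) = bidx;
        }
  }
}

struct Net {
  // conv layers 1..6 then dense 1..2
  std::vector<fmat> W;
  std::vector<fvec> b;
  static const int kk[6], Din[6];
  static List to_list(const Net &n) {
    List out;
    for (int i = 0; i < 6; ++i) {
      out["W" + std::to_string(i + 1)] = wrap(arma::conv_to<arma::mat>::from(n.W[i]));
      out["b" + std::to_string(i + 1)] = wrap(arma::conv_to<arma::vec>::from(n.b[i]));
    }
    out["Wd1"] = wrap(arma::conv_to<arma::mat>::from(n.W[6]));
    out["bd1"] = wrap(arma::conv_to<arma::vec>::from(n.b[6]));
    out["Wd2"] = wrap(arma::conv_to<arma::mat>::from(n.W[7]));
    out["bd2"] = wrap(arma::conv_to<arma::vec>::from(n.b[7]));
    return out;
  }
  static Net from_list(List l) {
    Net n;
    n.W.resize(8); n.b.resize(8);
    const char *wn[8] = {"W1","W2","W3","W4","W5","W6","Wd1","Wd2"};
    const char *bn[8] = {"b1","b2","b3","b4","b5","b6","bd1","bd2"};
    for (int i = 0; i < 8; ++i) {
      n.W[i] = arma::conv_to<fmat>::from(as<arma::mat>(l[wn[i]]));
      n.b[i] = arma::conv_to<fvec>::from(as<arma::vec>(l[bn[i]]));
    }
    return n;
  }
};
const int Net::kk[6]  = {8, 8, 4, 4, 2, 2};
const int Net::Din[6] = {16, 16, 8, 8, 4, 4};

struct Cache {
  fmat a0, c1, a1, c2, a2, p3, d4, c5, a5, c6, a6, p7, c8, a8, c9, a9, d10;
  arma::umat i3, i7;
  fmat m4, m10;      // dropout masks (conv stages)
  fvec m12;          // dropout mask (dense stage)
  arma::frowvec f, h, hd;
  float z_out, prob;
};

static fmat drop_mask(int nr, int nc, double rate) {
  fmat m(nr, nc);
  const float scale = 1.0f / (1.0f - (float)rate);
  for (arma::uword i = 0; i < m.n_elem; ++i)
    m(i) = (R::unif_rand() < rate) ? 0.0f : scale;
  return m;
}

// forward one sample; x is (4096 x 4)
static float forward(const Net &net, const fmat &x, bool train,
                     const NumericVector &dropout, Cache &cc) {
  cc.a0 = x;
  im2col(cc.a0, 16, 8, cc.c1);
  cc.a1 = cc.c1 * net.W[0];
  cc.a1.each_row() += net.b[0].t();
  cc.a1.transform([](float v) { return v > 0 ? v : 0; });
  im2col(cc.a1, 16, 8, cc.c2);
  cc.a2 = cc.c2 * net.W[1];
  cc.a2.each_row() += net.b[1].t();
  cc.a2.transform([](float v) { return v > 0 ? v : 0; });
  maxpool(cc.a2, 16, cc.p3, cc.i3);
  if (train) { cc.m4 = drop_mask(cc.p3.n_rows, cc.p3.n_cols, dropout[0]); cc.d4 = cc.p3 % cc.m4; }
  else cc.d4 = cc.p3;
  im2col(cc.d4, 8, 4, cc.c5);
  cc.a5 = cc.c5 * net.W[2];
  cc.a5.each_row() += net.b[2].t();
  cc.a5.transform([](float v) { return v > 0 ? v : 0; });
  im2col(cc.a5, 8, 4, cc.c6);
  cc.a6 = cc.c6 * net.W[3];
  cc.a6.each_row() += net.b[3].t();
  cc.a6.transform([](float v) { return v > 0 ? v : 0; });
  maxpool(cc.a6, 8, cc.p7, cc.i7);
  im2col(cc.p7, 4, 2, cc.c8);
  cc.a8 = cc.c8 * net.W[4];
  cc.a8.each_row() += net.b[4].t();
  cc.a8.transform([](float v) { return v > 0 ? v : 0; });
  im2col(cc.a8, 4, 2, cc.c9);
  cc.a9 = cc.c9 * net.W[5];
  cc.a9.each_row() += net.b[5].t();
  cc.a9.transform([](float v) { return v > 0 ? v : 0; });
  if (train) { cc.m10 = drop_mask(cc.a9.n_rows, cc.a9.n_cols, dropout[1]); cc.d10 = cc.a9 % cc.m10; }
  else cc.d10 = cc.a9;
  cc.f = arma::vectorise(cc.d10).t();          // 4096 flattened features
  cc.h = cc.f * net.W[6] + net.b[6].t();
  cc.h.transform([](float v) { return v > 0 ? v : 0; });
  if (train) {
    cc.m12 = drop_mask(cc.h.n_elem, 1, dropout[2]).col(0);
    cc.hd = cc.h % cc.m12.t();
  } else cc.hd = cc.h;
  cc.z_out = arma::as_scalar(cc.hd * net.W[7]) + net.b[7](0);
  cc.prob = 1.0f / (1.0f + std::exp(-cc.z_out));
  return cc.prob;
}

struct Grads {
  std::vector<fmat> W;
  std::vector<fvec> b;
  void zero_like(const Net &n) {
    W.resize(8); b.resize(8);
    for (int i = 0; i < 8; ++i) {
      W[i].zeros(n.W[i].n_rows, n.W[i].n_cols);
      b[i].zeros(n.b[i].n_elem);
    }
  }
};

// unpool: route output-cell gradients back to argmax input rows
static void unpool(const fmat &dout, const arma::umat &argmax, int nvox_in, fmat &din) {
  din.zeros(nvox_in, dout.n_cols);
  for (arma::uword c = 0; c < dout.n_cols; ++c)
    for (arma::uword r = 0; r < dout.n_rows; ++r)
      din(argmax(r, c), c) += dout(r, c);
}

static void backward(const Net &net, const Cache &cc, float y, Grads &g) {
  const float dz = cc.prob - y;  // BCE + sigmoid
  g.W[7] += cc.hd.t() * dz;
  g.b[7](0) += dz;
  arma::frowvec dhd = dz * net.W[7].col(0).t();
  arma::frowvec dh = dhd;
  if (cc.m12.n_elem) dh %= cc.m12.t();
  for (arma::uword i = 0; i < dh.n_elem; ++i) if (cc.h(i) <= 0) dh(i) = 0;
  g.W[6] += cc.f.t() * dh;
  g.b[6] += dh.t();
  arma::frowvec df = dh * net.W[6].t();
  fmat d10 = fmat(df.t());
  d10.reshape(64, 64);                       // back to (voxels x channels)
  if (cc.m10.n_elem) d10 %= cc.m10;
  // conv6 (a9)
  fmat dz9 = d10;
  dz9.elem(arma::find(cc.a9 <= 0)).zeros();
  g.W[5] += cc.c9.t() * dz9;
  g.b[5] += arma::sum(dz9, 0).t();
  fmat dcol = dz9 * net.W[5].t(), din;
  col2im(dcol, 4, 2, 32, din);
  // conv5 (a8)
  fmat dz8 = din;
  dz8.elem(arma::find(cc.a8 <= 0)).zeros();
  g.W[4] += cc.c8.t() * dz8;
  g.b[4] += arma::sum(dz8, 0).t();
  dcol = dz8 * net.W[4].t();
  col2im(dcol, 4, 2, 16, din);
  // pool7
  fmat dp;
  unpool(din, cc.i7, 512, dp);
  // conv4 (a6)
  fmat dz6 = dp;
  dz6.elem(arma::find(cc.a6 <= 0)).zeros();
  g.W[3] += cc.c6.t() * dz6;
  g.b[3] += arma::sum(dz6, 0).t();
  dcol = dz6 * net.W[3].t();
  col2im(dcol, 8, 4, 8, din);
  // conv3 (a5)
  fmat dz5 = din;
  dz5.elem(arma::find(cc.a5 <= 0)).zeros();
  g.W[2] += cc.c5.t() * dz5;
  g.b[2] += arma::sum(dz5, 0).t();
  dcol = dz5 * net.W[2].t();
  col2im(dcol, 8, 4, 4, din);
  if (cc.m4.n_elem) din %= cc.m4;
  // pool3
  unpool(din, cc.i3, 4096, dp);
  // conv2 (a2)
  fmat dz2 = dp;
  dz2.elem(arma::find(cc.a2 <= 0)).zeros();
  g.W[1] += cc.c2.t() * dz2;
  g.b[1] += arma::sum(dz2, 0).t();
  dcol = dz2 * net.W[1].t();
  col2im(dcol, 16, 8, 2, din);
  // conv1 (a1); no input gradient needed
  fmat dz1 = din;
  dz1.elem(arma::find(cc.a1 <= 0)).zeros();
  g.W[0] += cc.c1.t() * dz1;
  g.b[0] += arma::sum(dz1, 0).t();
}

static fmat sample_mat(const double *X, int s) {
  fmat x(4096, 4);
  const double *p = X + (size_t)s * 16384;
  for (int i = 0; i < 16384; ++i) x(i) = (float)p[i];
  return x;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  long t = 0;
  void init(const Net &n) {
    mW.resize(8); vW.resize(8); mb.resize(8); vb.resize(8);
    for (int i = 0; i < 8; ++i) {
      mW[i].zeros(n.W[i].n_rows, n.W[i].n_cols);
      vW[i].zeros(n.W[i].n_rows, n.W[i].n_cols);
      mb[i].zeros(n.b[i].n_elem);
      vb[i].zeros(n.b[i].n_elem);
    }
  }
  void step(Net &n, const Grads &g, double lr, double b1, double b2, double eps) {
    ++t;
    const float c1 = 1.0f - std::pow((float)b1, (float)t);
    const float c2 = 1.0f - std::pow((float)b2, (float)t);
    for (int i = 0; i < 8; ++i) {
      mW[i] = (float)b1 * mW[i] + (1.0f - (float)b1) * g.W[i];
      vW[i] = (float)b2 * vW[i] + (1.0f - (float)b2) * arma::square(g.W[i]);
      n.W[i] -= (float)lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + (float)eps);
      mb[i] = (float)b1 * mb[i] + (1.0f - (float)b1) * g.b[i];
      vb[i] = (float)b2 * vb[i] + (1.0f - (float)b2) * arma::square(g.b[i]);
      n.b[i] -= (float)lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + (float)eps);
    }
  }
};

static double bce(double p, double y) {
  const double e = 1e-7;
  p = std::min(1.0 - e, std::max(e, p));
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List weights, NumericVector X, int n) {
  Net net = Net::from_list(weights);
  NumericVector out(n);
  Cache cc;
  NumericVector dr(3);
  for (int s = 0; s < n; ++s)
    out[s] = forward(net, sample_mat(X.begin(), s), false, dr, cc);
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, NumericVector X, NumericVector y,
                   NumericVector Xval, NumericVector yval,
                   int epochs, int batch, double lr, double beta1, double beta2,
                   double adam_eps, NumericVector dropout, int patience,
                   double stop_train_acc, bool verbose) {
  Net net = Net::from_list(weights);
  const int n = y.size(), nval = yval.size();
  Adam opt;
  opt.init(net);
  Grads g;
  Cache cc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  double best_vloss = R_PosInf;
  int best_epoch = 0, wait = 0;
  Net best = net;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double loss = 0; int correct = 0;
    for (int start = 0; start < n; start += batch) {
      const int bn = std::min(batch, n - start);
      g.zero_like(net);
      for (int k = 0; k < bn; ++k) {
        const int s = order[start + k];
        const float p = forward(net, sample_mat(X.begin(), s), true, dropout, cc);
        loss += bce(p, y[s]);
        if ((p >= 0.5) == (y[s] >= 0.5)) ++correct;
        backward(net, cc, (float)y[s], g);
      }
      for (int i = 0; i < 8; ++i) { g.W[i] /= (float)bn; g.b[i] /= (float)bn; }
      opt.step(net, g, lr, beta1, beta2, adam_eps);
    }
    loss /= n;
    const double acc = (double)correct / n;
    h_loss.push_back(loss);
    h_acc.push_back(acc);
    double vloss = NA_REAL, vacc = NA_REAL;
    bool stop_early = false;
    if (nval > 0) {
      vloss = 0; int vc = 0;
      for (int s = 0; s < nval; ++s) {
        const float p = forward(net, sample_mat(Xval.begin(), s), false, dropout, cc);
        vloss += bce(p, yval[s]);
        if ((p >= 0.5) == (yval[s] >= 0.5)) ++vc;
      }
      vloss /= nval;
      vacc = (double)vc / nval;
      if (vloss < best_vloss - 1e-6) {
        best_vloss = vloss; best = net; best_epoch = ep + 1; wait = 0;
      } else if (++wait >= patience) {
        if (verbose) Rcout << "early stop at epoch " << ep + 1 << "\n";
        stop_early = true;
      }
    }
    h_vloss.push_back(vloss);
    h_vacc.push_back(vacc);
    if (stop_early) break;
    if (verbose)
      Rcout << "epoch " << ep + 1 << " loss " << loss << " acc " << acc
            << (nval > 0 ? " val_loss " : "") << (nval > 0 ? std::to_string(vloss) : "")
            << "\n";
    if (acc >= stop_train_acc) break;
    Rcpp::checkUserInterrupt();
  }
  if (nval > 0 && best_epoch > 0) net = best;
  return List::create(
      _["weights"] = Net::to_list(net),
      _["history"] = List::create(_["loss"] = h_loss, _["acc"] = h_acc,
                                  _["val_loss"] = h_vloss, _["val_acc"] = h_vacc),
      _["best_epoch"] = best_epoch > 0 ? best_epoch : (int)h_loss.size());
}
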