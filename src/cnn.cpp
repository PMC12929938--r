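#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

// LeNet-style network: conv(F1,k)->ReLU->pool2 -> conv(F2,k)->ReLU->pool2
// -> FC(fc)->ReLU -> FC(nClasses), softmax cross-entropy, Adam.
// Convolutions are valid (no padding), stride 1, via im2col + GEMM.
// All parameter initialization and batch ordering comes from R so that
// training is reproducible under R's seed alone.

struct Dims {
  int res, k, F1, F2, fc, nc;
  int c1, p1, c2, p2, flat;  // spatial sides
  Dims(int res_, int k_, int F1_, int F2_, int fc_, int nc_)
      : res(res_), k(k_), F1(F1_), F2(F2_), fc(fc_), nc(nc_) {
    c1 = res - k + 1;
    p1 = c1 / 2;
    c2 = p1 - k + 1;
    p2 = c2 / 2;
    flat = p2 * p2 * F2;
    if (c1 < 1 || c2 < 1 || p2 < 1)
      stop("input resolution too small for the architecture");
  }
};

// im2col for a single-channel image stored col-major (h x w).
// out: (k*k) x (oh*ow); column p = ox*oh + oy; row r = kx*k + ky.
static void im2col1(const double *img, int h, int k, mat &out, int colOff) {
  int oh = h - k + 1;
  for (int ox = 0; ox < oh; ++ox)
    for (int oy = 0; oy < oh; ++oy) {
      double *dst = out.colptr(colOff + ox * oh + oy);
      for (int kx = 0; kx < k; ++kx) {
        const double *src = img + (ox + kx) * h + oy;
        for (int ky = 0; ky < k; ++ky) dst[kx * k + ky] = src[ky];
      }
    }
}

// im2col for a multi-channel cube (h x h x C).
// row r = c*k*k + kx*k + ky.
static void im2colC(const cube &in, int k, mat &out, int colOff) {
  int h = in.n_rows, C = in.n_slices, oh = h - k + 1;
  for (int ox = 0; ox < oh; ++ox)
    for (int oy = 0; oy < oh; ++oy) {
      double *dst = out.colptr(colOff + ox * oh + oy);
      for (int c = 0; c < C; ++c) {
        const double *sl = in.slice_memptr(c);
        for (int kx = 0; kx < k; ++kx) {
          const double *src = sl + (ox + kx) * h + oy;
          for (int ky = 0; ky < k; ++ky)
            dst[c * k * k + kx * k + ky] = src[ky];
        }
      }
    }
}

// col2im accumulation (gradient of im2colC).
static void col2imC(const mat &cols, int colOff, int k, cube &out) {
  int h = out.n_rows, C = out.n_slices, oh = h - k + 1;
  out.zeros();
  for (int ox = 0; ox < oh; ++ox)
    for (int oy = 0; oy < oh; ++oy) {
      const double *src = cols.colptr(colOff + ox * oh + oy);
      for (int c = 0; c < C; ++c) {
        double *sl = out.slice_memptr(c);
        for (int kx = 0; kx < k; ++kx) {
          double *dst = sl + (ox + kx) * h + oy;
          for (int ky = 0; ky < k; ++ky)
            dst[ky] += src[c * k * k + kx * k + ky];
        }
      }
    }
}

// 2x2 max pooling with stride 2 (floor semantics: trailing row/col of odd
// inputs is dropped). Input: activation matrix block (F x oh*oh) for one
// image; output cube (ph x ph x F) and argmax positions (same shape).
static void maxpool(const mat &act, int b, int oh, int F, cube &out,
                    arma::ucube &argmax) {
  int P = oh * oh, ph = oh / 2;
  for (int f = 0; f < F; ++f)
    for (int px = 0; px < ph; ++px)
      for (int py = 0; py < ph; ++py) {
        int x0 = 2 * px, y0 = 2 * py;
        double best = -1e300;
        int bestp = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            int p = (x0 + dx) * oh + (y0 + dy);
            double v = act(f, b * P + p);
            if (v > best) { best = v; bestp = p; }
          }
        out(py, px, f) = best;
        argmax(py, px, f) = bestp;
      }
}

static void unpool(const cube &dout, const arma::ucube &argmax, int b,
                   int oh, int F, mat &dact) {
  int P = oh * oh, ph = dout.n_rows;
  for (int f = 0; f < F; ++f)
    for (int px = 0; px < ph; ++px)
      for (int py = 0; py < ph; ++py)
        dact(f, b * P + argmax(py, px, f)) += dout(py, px, f);
}

struct Net {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4;
};

static Net netFromList(const List &w) {
  Net n;
  n.W1 = as<mat>(w["W1"]); n.b1 = as<vec>(w["b1"]);
  n.W2 = as<mat>(w["W2"]); n.b2 = as<vec>(w["b2"]);
  n.W3 = as<mat>(w["W3"]); n.b3 = as<vec>(w["b3"]);
  n.W4 = as<mat>(w["W4"]); n.b4 = as<vec>(w["b4"]);
  return n;
}

static List netToList(const Net &n) {
  return List::create(_["W1"] = n.W1, _["b1"] = n.b1, _["W2"] = n.W2,
                      _["b2"] = n.b2, _["W3"] = n.W3, _["b3"] = n.b3,
                      _["W4"] = n.W4, _["b4"] = n.b4);
}

// Forward pass for a batch of images (columns of X). Returns class
// probabilities (nc x B); optionally fills caches for backprop.
struct Cache {
  mat C1, Z1, C2, Z2, Fl, A3, probs;
  std::vector<arma::ucube> am1, am2;
};

static mat forward(const Net &net, const Dims &d, const mat &X, Cache *cc) {
  int B = X.n_cols;
  int P1 = d.c1 * d.c1, P2 = d.c2 * d.c2;
  mat C1(d.k * d.k, P1 * B);
  for (int b = 0; b < B; ++b)
    im2col1(X.colptr(b), d.res, d.k, C1, b * P1);
  mat Z1 = net.W1 * C1;
  Z1.each_col() += net.b1;
  mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);

  mat C2(d.k * d.k * d.F1, P2 * B);
  std::vector<arma::ucube> am1(B);
  cube pool1(d.p1, d.p1, d.F1);
  for (int b = 0; b < B; ++b) {
    am1[b].set_size(d.p1, d.p1, d.F1);
    maxpool(A1, b, d.c1, d.F1, pool1, am1[b]);
    im2colC(pool1, d.k, C2, b * P2);
  }
  mat Z2 = net.W2 * C2;
  Z2.each_col() += net.b2;
  mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);

  mat Fl(d.flat, B);
  std::vector<arma::ucube> am2(B);
  cube pool2(d.p2, d.p2, d.F2);
  for (int b = 0; b < B; ++b) {
    am2[b].set_size(d.p2, d.p2, d.F2);
    maxpool(A2, b, d.c2, d.F2, pool2, am2[b]);
    std::memcpy(Fl.colptr(b), pool2.memptr(), sizeof(double) * d.flat);
  }
  mat Z3 = net.W3 * Fl;
  Z3.each_col() += net.b3;
  mat A3 = arma::clamp(Z3, 0.0, arma::datum::inf);
  mat Z4 = net.W4 * A3;
  Z4.each_col() += net.b4;

  mat probs(d.nc, B);
  for (int b = 0; b < B; ++b) {
    vec z = Z4.col(b);
    z -= z.max();
    vec e = arma::exp(z);
    probs.col(b) = e / arma::accu(e);
  }
  if (cc) {
    cc->C1 = std::move(C1); cc->Z1 = std::move(Z1);
    cc->C2 = std::move(C2); cc->Z2 = std::move(Z2);
    cc->Fl = std::move(Fl); cc->A3 = std::move(A3);
    cc->probs = probs; cc->am1 = std::move(am1); cc->am2 = std::move(am2);
  }
  return probs;
}

static void backward(const Net &net, const Dims &d, const mat &X,
                     const arma::ivec &y, Cache &cc, Net &g) {
  int B = X.n_cols;
  int P1 = d.c1 * d.c1, P2 = d.c2 * d.c2;
  mat dZ4 = cc.probs;
  for (int b = 0; b < B; ++b) dZ4(y(b), b) -= 1.0;
  dZ4 /= (double)B;

  g.W4 = dZ4 * cc.A3.t();
  g.b4 = arma::sum(dZ4, 1);
  mat dA3 = net.W4.t() * dZ4;
  mat dZ3 = dA3 % arma::conv_to<mat>::from(cc.A3 > 0);
  g.W3 = dZ3 * cc.Fl.t();
  g.b3 = arma::sum(dZ3, 1);
  mat dFl = net.W3.t() * dZ3;

  mat dA2(d.F2, P2 * B, arma::fill::zeros);
  cube dpool2(d.p2, d.p2, d.F2);
  for (int b = 0; b < B; ++b) {
    std::memcpy(dpool2.memptr(), dFl.colptr(b), sizeof(double) * d.flat);
    unpool(dpool2, cc.am2[b], b, d.c2, d.F2, dA2);
  }
  mat dZ2 = dA2 % arma::conv_to<mat>::from(cc.Z2 > 0);
  g.W2 = dZ2 * cc.C2.t();
  g.b2 = arma::sum(dZ2, 1);
  mat dC2 = net.W2.t() * dZ2;

  mat dA1(d.F1, P1 * B, arma::fill::zeros);
  cube dpool1(d.p1, d.p1, d.F1);
  for (int b = 0; b < B; ++b) {
    col2imC(dC2, b * P2, d.k, dpool1);
    unpool(dpool1, cc.am1[b], b, d.c1, d.F1, dA1);
  }
  mat dZ1 = dA1 % arma::conv_to<mat>::from(cc.Z1 > 0);
  g.W1 = dZ1 * cc.C1.t();
  g.b1 = arma::sum(dZ1, 1);
}

static double ceLoss(const mat &probs, const arma::ivec &y) {
  double s = 0;
  for (arma::uword b = 0; b < probs.n_cols; ++b)
    s += -std::log(std::max(probs(y(b), b), 1e-15));
  return s / probs.n_cols;
}

static double accuracy(const mat &probs, const arma::ivec &y) {
  int ok = 0;
  for (arma::uword b = 0; b < probs.n_cols; ++b)
    ok += (probs.col(b).index_max() == (arma::uword)y(b));
  return (double)ok / probs.n_cols;
}

static mat predictAll(const Net &net, const Dims &d, const mat &X,
                      int chunk = 64) {
  int n = X.n_cols;
  mat probs(d.nc, n);
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    probs.cols(s, e - 1) = forward(net, d, X.cols(s, e - 1), nullptr);
  }
  return probs;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat &X, const arma::ivec &y,
                   const arma::mat &Xval, const arma::ivec &yval,
                   const List &init, int res, int k, int F1, int F2,
                   int fc, int nClasses, const arma::imat &order,
                   int batchSize, double lr, int patience) {
  Dims d(res, k, F1, F2, fc, nClasses);
  Net net = netFromList(init);
  Net m, v;  // Adam moments
  m.W1.zeros(arma::size(net.W1)); v.W1.zeros(arma::size(net.W1));
  m.W2.zeros(arma::size(net.W2)); v.W2.zeros(arma::size(net.W2));
  m.W3.zeros(arma::size(net.W3)); v.W3.zeros(arma::size(net.W3));
  m.W4.zeros(arma::size(net.W4)); v.W4.zeros(arma::size(net.W4));
  m.b1.zeros(net.b1.n_elem); v.b1.zeros(net.b1.n_elem);
  m.b2.zeros(net.b2.n_elem); v.b2.zeros(net.b2.n_elem);
  m.b3.zeros(net.b3.n_elem); v.b3.zeros(net.b3.n_elem);
  m.b4.zeros(net.b4.n_elem); v.b4.zeros(net.b4.n_elem);

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  int n = X.n_cols, epochs = order.n_cols;
  double bestVal = arma::datum::inf;
  int bad = 0;
  Net best = net;
  std::vector<double> trLoss, trAcc, vaLoss, vaAcc;

  auto adam = [&](mat &w, mat &mw, mat &vw, const mat &gw) {
    mw = beta1 * mw + (1 - beta1) * gw;
    vw = beta2 * vw + (1 - beta2) * (gw % gw);
    mat mh = mw / (1 - std::pow(beta1, (double)step));
    mat vh = vw / (1 - std::pow(beta2, (double)step));
    w -= lr * mh / (arma::sqrt(vh) + eps);
  };
  auto adamv = [&](vec &w, vec &mw, vec &vw, const vec &gw) {
    mw = beta1 * mw + (1 - beta1) * gw;
    vw = beta2 * vw + (1 - beta2) * (gw % gw);
    vec mh = mw / (1 - std::pow(beta1, (double)step));
    vec vh = vw / (1 - std::pow(beta2, (double)step));
    w -= lr * mh / (arma::sqrt(vh) + eps);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    double lsum = 0, asum = 0;
    int nb = 0;
    for (int s = 0; s < n; s += batchSize) {
      int e = std::min(n, s + batchSize);
      int B = e - s;
      mat Xb(X.n_rows, B);
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) {
        int idx = order(s + b, ep) - 1;  // 1-based from R
        Xb.col(b) = X.col(idx);
        yb(b) = y(idx);
      }
      Cache cc;
      forward(net, d, Xb, &cc);
      lsum += ceLoss(cc.probs, yb);
      asum += accuracy(cc.probs, yb);
      ++nb;
      Net g;
      backward(net, d, Xb, yb, cc, g);
      ++step;
      adam(net.W1, m.W1, v.W1, g.W1); adamv(net.b1, m.b1, v.b1, g.b1);
      adam(net.W2, m.W2, v.W2, g.W2); adamv(net.b2, m.b2, v.b2, g.b2);
      adam(net.W3, m.W3, v.W3, g.W3); adamv(net.b3, m.b3, v.b3, g.b3);
      adam(net.W4, m.W4, v.W4, g.W4); adamv(net.b4, m.b4, v.b4, g.b4);
    }
    mat pv = predictAll(net, d, Xval);
    double vl = ceLoss(pv, yval), va = accuracy(pv, yval);
    trLoss.push_back(lsum / nb); trAcc.push_back(asum / nb);
    vaLoss.push_back(vl); vaAcc.push_back(va);
    if (vl < bestVal - 1e-6) {
      bestVal = vl;
      best = net;
      bad = 0;
    } else if (++bad >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["weights"] = netToList(best),
    _["history"] = DataFrame::create(
        _["epoch"] = seq_len(trLoss.size()),
        _["train_loss"] = trLoss, _["train_accuracy"] = trAcc,
        _["val_loss"] = vaLoss, _["val_accuracy"] = vaAcc));
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(const List &weights, const arma::mat &X, int res,
                          int k, int F1, int F2, int fc, int nClasses) {
  Dims d(res, k, F1, F2, fc, nClasses);
  Net net = netFromList(weights);
  return predictAll(net, d, X);
}

// [[Rcpp::export(name = ".cnn_logits_cpp")]]
arma::vec cnn_logits_cpp(const List &weights, const arma::vec &x, int res,
                         int k, int F1, int F2, int fc, int nClasses) {
  Dims d(res, k, F1, F2, fc, nClasses);
  Net net = netFromList(weights);
  mat X(x);
  Cache cc;
  forward(net, d, X, &cc);
  // recompute logits from cached pieces
  mat Z4 = net.W4 * cc.A3;
  Z4.each_col() += net.b4;
  return Z4.col(0);
}

// Activations of the last convolutional layer (post-ReLU, pre-pool) and
// the gradient of the target-class logit with respect to them.
// [[Rcpp::export(name = ".cnn_gradcam_cpp")]]
List cnn_gradcam_cpp(const List &weights, const arma::vec &x, int res,
                     int k, int F1, int F2, int fc, int nClasses,
                     int targetClass) {
  Dims d(res, k, F1, F2, fc, nClasses);
  if (targetClass < 0 || targetClass >= nClasses)
    stop("invalid target class");
  Net net = netFromList(weights);
  mat X(x);
  Cache cc;
  forward(net, d, X, &cc);

  int P2 = d.c2 * d.c2;
  // gradient of logit targetClass wrt A3, Fl, pooled2, then A2
  vec e(d.nc, arma::fill::zeros);
  e(targetClass) = 1.0;
  vec dA3 = net.W4.t() * e;
  vec dZ3 = dA3 % arma::conv_to<vec>::from(cc.A3.col(0) > 0);
  vec dFl = net.W3.t() * dZ3;
  mat dA2(d.F2, P2, arma::fill::zeros);
  cube dpool2(d.p2, d.p2, d.F2);
  std::memcpy(dpool2.memptr(), dFl.memptr(), sizeof(double) * d.flat);
  unpool(dpool2, cc.am2[0], 0, d.c2, d.F2, dA2);

  // reshape activations and gradients to (c2 x c2 x F2) cubes
  mat A2 = arma::clamp(cc.Z2, 0.0, arma::datum::inf);
  cube act(d.c2, d.c2, d.F2), grad(d.c2, d.c2, d.F2);
  for (int f = 0; f < d.F2; ++f)
    for (int px = 0; px < d.c2; ++px)
      for (int py = 0; py < d.c2; ++py) {
        act(py, px, f) = A2(f, px * d.c2 + py);
        grad(py, px, f) = dA2(f, px * d.c2 + py);
      }
  return List::create(_["activations"] = act, _["gradients"] = grad);
}
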