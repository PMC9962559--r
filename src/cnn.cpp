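// Training / inference core for the 1D dilated convolutional network.
//
// Layout conventions:
//   * Activations for a batch of B curves of length L with C channels are
//     stored as an arma::fmat of size (B*L) x C, rows ordered sample-major
//     (row s*L + t holds position t of sample s).
//   * A convolution with kernel k and dilation d uses symmetric zero
//     padding ("same"), so the length L is preserved through every layer.
//   * Conv weights are (k*Cin) x Cout matrices acting on im2col blocks;
//     tap j (0-based) reads input position t + d*(j - k/2).
//
// Arithmetic is single precision: gradients of a small softmax classifier
// trained with the adaptive-moment method do not need more, and it halves
// the memory traffic of the im2col matrices that dominate the cost.
// All randomness (weight init, batch order) is generated on the R side and
// passed in, so training is reproducible from R's RNG alone.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ConvSpec {
  int k, dil, cin, cout;
};

inline void relu_inplace(fmat& Z) {
  Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// im2col for one layer over a whole batch, into a preallocated target.
void im2col(const fmat& A, int B, int L, const ConvSpec& cs, fmat& M) {
  M.zeros(static_cast<uword>(B) * L, static_cast<uword>(cs.k) * cs.cin);
  const int half = cs.k / 2;
  for (int s = 0; s < B; ++s) {
    const int base = s * L;
    for (int j = 0; j < cs.k; ++j) {
      const int shift = cs.dil * (j - half);
      const int t0 = std::max(0, -shift);
      const int t1 = std::min(L, L - shift);
      if (t0 >= t1) continue;
      M.submat(base + t0, j * cs.cin, base + t1 - 1, (j + 1) * cs.cin - 1) =
          A.rows(base + t0 + shift, base + t1 - 1 + shift);
    }
  }
}

// Scatter-add the im2col gradient back onto the input activations.
void col2im(const fmat& dM, int B, int L, const ConvSpec& cs, fmat& dA) {
  dA.zeros(static_cast<uword>(B) * L, cs.cin);
  const int half = cs.k / 2;
  for (int s = 0; s < B; ++s) {
    const int base = s * L;
    for (int j = 0; j < cs.k; ++j) {
      const int shift = cs.dil * (j - half);
      const int t0 = std::max(0, -shift);
      const int t1 = std::min(L, L - shift);
      if (t0 >= t1) continue;
      dA.rows(base + t0 + shift, base + t1 - 1 + shift) +=
          dM.submat(base + t0, j * cs.cin, base + t1 - 1,
                    (j + 1) * cs.cin - 1);
    }
  }
}

struct Net {
  std::vector<ConvSpec> conv;
  std::vector<fmat> Wc;   // (k*cin) x cout
  std::vector<frowvec> bc;
  fmat W1, W2;            // dense layers
  frowvec b1, b2;
  int L, dense, nclass;
};

fmat as_f(SEXP x) { return conv_to<fmat>::from(Rcpp::as<mat>(x)); }

Net unpack(const Rcpp::List& weights, const Rcpp::List& cfg) {
  Net net;
  net.L = Rcpp::as<int>(cfg["target_len"]);
  net.dense = Rcpp::as<int>(cfg["dense_units"]);
  net.nclass = Rcpp::as<int>(cfg["n_classes"]);
  const int k = Rcpp::as<int>(cfg["kernel_size"]);
  Rcpp::IntegerVector filt = cfg["filters"], dil = cfg["dilations"];
  Rcpp::List Wc = weights["Wc"], bc = weights["bc"];
  int cin = 1;
  for (int l = 0; l < filt.size(); ++l) {
    net.conv.push_back(ConvSpec{k, dil[l], cin, filt[l]});
    net.Wc.push_back(as_f(Wc[l]));
    net.bc.push_back(as_f(bc[l]).row(0));
    cin = filt[l];
  }
  net.W1 = as_f(weights["W1"]);
  net.b1 = as_f(weights["b1"]).row(0);
  net.W2 = as_f(weights["W2"]);
  net.b2 = as_f(weights["b2"]).row(0);
  return net;
}

// Preallocated scratch for forward/backward at one fixed batch size.
struct Workspace {
  std::vector<fmat> M;     // im2col inputs per conv layer
  std::vector<fmat> Z;     // post-ReLU conv outputs
  fmat A0;                 // raw input as (B*L) x 1
  umat argmax;             // B x C row indices chosen by the max pool
  fmat P, H, probs;        // pooled features, dense hidden, softmax
  fmat dM, dA;             // backward scratch
  explicit Workspace(size_t nconv) : M(nconv), Z(nconv) {}
};

void forward(const Net& net, const fmat& X, Workspace& ws) {
  const int B = X.n_rows, L = net.L;
  ws.A0 = vectorise(X.t());  // sample-major (B*L) x 1
  const fmat* A = &ws.A0;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    im2col(*A, B, L, net.conv[l], ws.M[l]);
    ws.Z[l] = ws.M[l] * net.Wc[l];
    ws.Z[l].each_row() += net.bc[l];
    relu_inplace(ws.Z[l]);
    A = &ws.Z[l];
  }
  const int C = A->n_cols;
  ws.P.set_size(B, C);
  ws.argmax.set_size(B, C);
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      uword idx;
      ws.P(s, c) = A->col(c).subvec(s * L, (s + 1) * L - 1).max(idx);
      ws.argmax(s, c) = s * L + idx;
    }
  }
  ws.H = ws.P * net.W1;
  ws.H.each_row() += net.b1;
  relu_inplace(ws.H);
  ws.probs = ws.H * net.W2;
  ws.probs.each_row() += net.b2;
  ws.probs.each_col() -= max(ws.probs, 1);
  ws.probs = exp(ws.probs);
  ws.probs.each_col() /= sum(ws.probs, 1);
}

double xent(const fmat& probs, const uvec& y) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    s -= std::log(std::max(static_cast<double>(probs(i, y[i])), 1e-12));
  return s / y.n_elem;
}

double acc(const fmat& probs, const uvec& y) {
  uword hit = 0;
  for (uword i = 0; i < y.n_elem; ++i) {
    uword idx;
    probs.row(i).max(idx);
    hit += (idx == y[i]);
  }
  return static_cast<double>(hit) / y.n_elem;
}

struct Adam {
  std::vector<fmat> m, v;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f, lr;
  long t = 0;
  void init(const std::vector<fmat*>& params, float lr_) {
    lr = lr_;
    for (fmat* p : params) {
      m.emplace_back(size(*p), fill::zeros);
      v.emplace_back(size(*p), fill::zeros);
    }
  }
  void step(const std::vector<fmat*>& params, const std::vector<fmat>& g) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, static_cast<float>(t));
    const float c2 = 1.0f - std::pow(b2, static_cast<float>(t));
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * square(g[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward(Rcpp::List weights, Rcpp::List cfg, arma::mat X) {
  Net net = unpack(weights, cfg);
  Workspace ws(net.conv.size());
  forward(net, conv_to<fmat>::from(X), ws);
  return conv_to<mat>::from(ws.probs);
}

// Full training loop. `order` is an epochs x n_train matrix of 1-based
// permutations drawn in R; `ytrain`/`yval` are 0-based class indices.
// Reported per-epoch training loss/accuracy are running averages over the
// minibatches (pre-update forward passes); validation metrics come from a
// full forward pass at the end of each epoch.
// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::List weights, Rcpp::List cfg, arma::mat Xtrain,
                     arma::uvec ytrain, arma::mat Xval, arma::uvec yval,
                     arma::umat order, arma::vec class_weights) {
  Net net = unpack(weights, cfg);
  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = Rcpp::as<int>(cfg["batch_size"]);
  const float lr = static_cast<float>(Rcpp::as<double>(cfg["learning_rate"]));
  const int n = Xtrain.n_rows, L = net.L;
  const size_t nconv = net.conv.size();

  const fmat Xt = conv_to<fmat>::from(Xtrain);
  const fmat Xv = conv_to<fmat>::from(Xval);
  const fvec cw = conv_to<fvec>::from(class_weights);

  std::vector<fmat> bias(nconv + 2);  // biases as 1 x n mats for Adam
  for (size_t l = 0; l < nconv; ++l) bias[l] = net.bc[l];
  bias[nconv] = net.b1;
  bias[nconv + 1] = net.b2;
  auto sync_bias = [&]() {
    for (size_t l = 0; l < nconv; ++l) net.bc[l] = bias[l].row(0);
    net.b1 = bias[nconv].row(0);
    net.b2 = bias[nconv + 1].row(0);
  };

  std::vector<fmat*> params;
  for (size_t l = 0; l < nconv; ++l) params.push_back(&net.Wc[l]);
  params.push_back(&net.W1);
  params.push_back(&net.W2);
  for (auto& b : bias) params.push_back(&b);
  const size_t gb0 = nconv + 2;  // index of the first bias slot

  Adam opt;
  opt.init(params, lr);
  std::vector<fmat> grads(params.size());

  Workspace ws(nconv), wsv(nconv);
  fmat Xb(batch, L);
  mat history(epochs, 4);  // train_loss, train_acc, val_loss, val_acc

  for (int e = 0; e < epochs; ++e) {
    double run_loss = 0.0, run_hits = 0.0;
    for (int start = 0; start < n; start += batch) {
      const int stop = std::min(start + batch, n);
      const int B = stop - start;
      Xb.set_size(B, L);
      uvec yb(B);
      fvec wb(B);
      for (int i = 0; i < B; ++i) {
        const uword idx = order(e, start + i) - 1;
        Xb.row(i) = Xt.row(idx);
        yb[i] = ytrain[idx];
        wb[i] = cw[ytrain[idx]];
      }
      sync_bias();
      forward(net, Xb, ws);
      run_loss += xent(ws.probs, yb) * B;
      run_hits += acc(ws.probs, yb) * B;

      fmat dO = ws.probs;  // weighted softmax cross-entropy gradient
      for (int i = 0; i < B; ++i) dO(i, yb[i]) -= 1.0f;
      dO.each_col() %= wb;
      dO /= accu(wb);

      grads[nconv + 1] = ws.H.t() * dO;            // W2
      grads[gb0 + nconv + 1] = sum(dO, 0);         // b2
      fmat dH = dO * net.W2.t();
      dH.elem(find(ws.H == 0)).zeros();
      grads[nconv] = ws.P.t() * dH;                // W1
      grads[gb0 + nconv] = sum(dH, 0);             // b1
      fmat dP = dH * net.W1.t();
      ws.dA.zeros(static_cast<uword>(B) * L, net.conv.back().cout);
      for (int s = 0; s < B; ++s)                  // un-pool
        for (uword c = 0; c < dP.n_cols; ++c)
          ws.dA(ws.argmax(s, c), c) += dP(s, c);
      for (int l = static_cast<int>(nconv) - 1; l >= 0; --l) {
        ws.dA.elem(find(ws.Z[l] == 0)).zeros();
        grads[l] = ws.M[l].t() * ws.dA;            // Wc[l]
        grads[gb0 + l] = sum(ws.dA, 0);            // bc[l]
        if (l > 0) {
          ws.dM = ws.dA * net.Wc[l].t();
          col2im(ws.dM, B, L, net.conv[l], ws.dA);
        }
      }
      opt.step(params, grads);
    }
    history(e, 0) = run_loss / n;
    history(e, 1) = run_hits / n;
    if (Xv.n_rows > 0) {
      sync_bias();
      forward(net, Xv, wsv);
      history(e, 2) = xent(wsv.probs, yval);
      history(e, 3) = acc(wsv.probs, yval);
    } else {
      history(e, 2) = datum::nan;
      history(e, 3) = datum::nan;
    }
    Rcpp::checkUserInterrupt();
  }

  sync_bias();
  Rcpp::List Wc(nconv), bc(nconv);
  for (size_t l = 0; l < nconv; ++l) {
    Wc[l] = conv_to<mat>::from(net.Wc[l]);
    bc[l] = conv_to<mat>::from(fmat(net.bc[l]));
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::List::create(
          Rcpp::Named("Wc") = Wc, Rcpp::Named("bc") = bc,
          Rcpp::Named("W1") = conv_to<mat>::from(net.W1),
          Rcpp::Named("b1") = conv_to<mat>::from(fmat(net.b1)),
          Rcpp::Named("W2") = conv_to<mat>::from(net.W2),
          Rcpp::Named("b2") = conv_to<mat>::from(fmat(net.b2))),
      Rcpp::Named("history") = history);
}
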