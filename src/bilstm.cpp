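// Bidirectional LSTM sequence-to-sequence regression engine.
//
// Architecture: n_layers (Bi)LSTM layers (hidden units per direction H),
// a per-timestep fully connected layer (D*H -> H, ReLU), dropout before the
// final layer, and a linear output layer (H -> n_out). Trained with Adam on
// a masked mean-squared-error loss so zero-padded timesteps contribute no
// gradient.
//
// Data layout: R passes X as an (N, C, T) cube (slice t = samples x
// channels), Y as (N, n_out, T), M as an N x T validity mask. Internally a
// batch is held time-flattened as a (T*B, C) matrix whose row block t is
// the batch at time t; all non-recurrent projections then run as single
// large GEMMs, only the h * R recurrence and the backward dh chain are
// per-timestep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct LstmLayer {
  mat W, R;   // input and recurrent weights (in x 4H, H x 4H)
  rowvec b;   // 4H
};

struct Net {
  int n_layers, hidden, n_dir, n_in, n_out;
  std::vector<std::vector<LstmLayer>> lstm; // [layer][dir]
  mat W1, W2;
  rowvec b1, b2;
};

Net unpack(const Rcpp::List& params, int n_layers, int hidden, int n_dir) {
  Net net;
  net.n_layers = n_layers; net.hidden = hidden; net.n_dir = n_dir;
  int k = 0;
  net.lstm.resize(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    net.lstm[l].resize(n_dir);
    for (int d = 0; d < n_dir; ++d) {
      net.lstm[l][d].W = Rcpp::as<mat>(params[k++]);
      net.lstm[l][d].R = Rcpp::as<mat>(params[k++]);
      net.lstm[l][d].b = Rcpp::as<rowvec>(params[k++]);
    }
  }
  net.W1 = Rcpp::as<mat>(params[k++]);
  net.b1 = Rcpp::as<rowvec>(params[k++]);
  net.W2 = Rcpp::as<mat>(params[k++]);
  net.b2 = Rcpp::as<rowvec>(params[k++]);
  net.n_in = net.lstm[0][0].W.n_rows;
  net.n_out = net.W2.n_cols;
  return net;
}

Rcpp::List pack(const Net& net) {
  Rcpp::List out;
  auto as_vec = [](const rowvec& v) {           // plain R vector, no dim
    return Rcpp::NumericVector(v.begin(), v.end());
  };
  for (int l = 0; l < net.n_layers; ++l)
    for (int d = 0; d < net.n_dir; ++d) {
      out.push_back(net.lstm[l][d].W);
      out.push_back(net.lstm[l][d].R);
      out.push_back(as_vec(net.lstm[l][d].b));
    }
  out.push_back(net.W1);
  out.push_back(as_vec(net.b1));
  out.push_back(net.W2);
  out.push_back(as_vec(net.b2));
  return out;
}

struct LayerCache {
  mat I, F, G, O, C, H;       // (T*B, H), row block t = batch at time t
};

struct ForwardCache {
  int B, T;
  std::vector<std::vector<LayerCache>> layers; // [layer][dir]
  std::vector<mat> inputs;    // input to each layer, (T*B, in_l)
  mat hcat;                   // (T*B, D*H)
  mat Z1, A1d, drop;          // head intermediates, (T*B, H)
  mat Yhat;                   // (T*B, n_out)
};

// time-flattened batch matrix from an (N, C, T) cube
mat flatten_batch(const cube& X, const uvec& idx) {
  const int B = idx.n_elem, T = X.n_slices, C = X.n_cols;
  mat out(T * B, C);
  for (int t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = X.slice(t).rows(idx);
  return out;
}

void forward_batch(const Net& net, const mat& Xflat, int B, int T,
                   ForwardCache& fc) {
  const int H = net.hidden, D = net.n_dir;
  fc.B = B; fc.T = T;
  fc.layers.assign(net.n_layers, std::vector<LayerCache>(D));
  fc.inputs.resize(net.n_layers);
  mat cur = Xflat;
  for (int l = 0; l < net.n_layers; ++l) {
    fc.inputs[l] = cur;
    mat out(T * B, D * H);
    for (int d = 0; d < D; ++d) {
      LayerCache& lc = fc.layers[l][d];
      lc.I.set_size(T * B, H); lc.F.set_size(T * B, H); lc.G.set_size(T * B, H);
      lc.O.set_size(T * B, H); lc.C.set_size(T * B, H); lc.H.set_size(T * B, H);
      const LstmLayer& ly = net.lstm[l][d];
      mat pre = cur * ly.W;        // one large GEMM for the input term
      pre.each_row() += ly.b;
      mat h(B, H, fill::zeros), c(B, H, fill::zeros);
      for (int s = 0; s < T; ++s) {
        int t = (d == 0) ? s : (T - 1 - s);
        int r0 = t * B, r1 = t * B + B - 1;
        mat z = pre.rows(r0, r1) + h * ly.R;
        mat i = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
        mat f = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
        mat g = tanh(z.cols(2 * H, 3 * H - 1));
        mat o = 1.0 / (1.0 + exp(-z.cols(3 * H, 4 * H - 1)));
        c = f % c + i % g;
        h = o % tanh(c);
        lc.I.rows(r0, r1) = i; lc.F.rows(r0, r1) = f; lc.G.rows(r0, r1) = g;
        lc.O.rows(r0, r1) = o; lc.C.rows(r0, r1) = c; lc.H.rows(r0, r1) = h;
        out.submat(r0, d * H, r1, (d + 1) * H - 1) = h;
      }
    }
    cur = out;
  }
  fc.hcat = cur;
  fc.Z1 = cur * net.W1;
  fc.Z1.each_row() += net.b1;
  mat a1 = clamp(fc.Z1, 0.0, datum::inf);     // ReLU
  fc.A1d = a1 % fc.drop;
  fc.Yhat = fc.A1d * net.W2;
  fc.Yhat.each_row() += net.b2;
}

// masked MSE loss and full gradients for one batch
double backward_batch(const Net& net, const mat& Yflat, const mat& Mflat,
                      const ForwardCache& fc, Net& grad) {
  const int B = fc.B, T = fc.T, H = net.hidden, D = net.n_dir;
  double denom = accu(Mflat) * net.n_out;
  if (denom < 1.0) denom = 1.0;

  mat diff = fc.Yhat - Yflat;
  diff.each_col() %= Mflat;
  double loss = accu(square(diff)) / denom;
  mat dY = 2.0 * diff / denom;

  grad = net;
  grad.W2 = fc.A1d.t() * dY;
  grad.b2 = sum(dY, 0);
  mat dA1 = (dY * net.W2.t()) % fc.drop;
  mat dZ1 = dA1 % conv_to<mat>::from(fc.Z1 > 0.0);
  grad.W1 = fc.hcat.t() * dZ1;
  grad.b1 = sum(dZ1, 0);
  mat dHcat = dZ1 * net.W1.t();

  for (int l = net.n_layers - 1; l >= 0; --l) {
    const mat& Xl = fc.inputs[l];
    mat dXl(Xl.n_rows, Xl.n_cols, fill::zeros);
    for (int d = 0; d < D; ++d) {
      const LayerCache& lc = fc.layers[l][d];
      const LstmLayer& ly = net.lstm[l][d];
      LstmLayer& gl = grad.lstm[l][d];
      mat dZ(T * B, 4 * H);
      mat Hprev(T * B, H, fill::zeros);
      mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
      for (int s = T - 1; s >= 0; --s) {
        int t = (d == 0) ? s : (T - 1 - s);
        int r0 = t * B, r1 = t * B + B - 1;
        mat dh = dHcat.submat(r0, d * H, r1, (d + 1) * H - 1) + dh_next;
        mat tc = tanh(lc.C.rows(r0, r1));
        mat o = lc.O.rows(r0, r1), i = lc.I.rows(r0, r1);
        mat f = lc.F.rows(r0, r1), g = lc.G.rows(r0, r1);
        mat dc = dc_next + dh % o % (1.0 - square(tc));
        mat c_prev(B, H, fill::zeros), h_prev(B, H, fill::zeros);
        if (s > 0) {
          int tp = (d == 0) ? (t - 1) : (t + 1);
          c_prev = lc.C.rows(tp * B, tp * B + B - 1);
          h_prev = lc.H.rows(tp * B, tp * B + B - 1);
        }
        mat di = dc % g % i % (1.0 - i);
        mat df = dc % c_prev % f % (1.0 - f);
        mat dg = dc % i % (1.0 - square(g));
        mat do_ = dh % tc % o % (1.0 - o);
        dZ.submat(r0, 0, r1, H - 1) = di;
        dZ.submat(r0, H, r1, 2 * H - 1) = df;
        dZ.submat(r0, 2 * H, r1, 3 * H - 1) = dg;
        dZ.submat(r0, 3 * H, r1, 4 * H - 1) = do_;
        Hprev.rows(r0, r1) = h_prev;
        dh_next = dZ.rows(r0, r1) * ly.R.t();
        dc_next = dc % f;
      }
      gl.W = Xl.t() * dZ;         // single large GEMMs for the weight grads
      gl.R = Hprev.t() * dZ;
      gl.b = sum(dZ, 0);
      dXl += dZ * ly.W.t();
    }
    if (l > 0) dHcat = dXl;
  }
  return loss;
}

struct AdamState {
  std::vector<mat> m, v;
  long step = 0;
};

void adam_init(AdamState& st, const Net& net) {
  auto add = [&](const mat& p) {
    st.m.push_back(zeros<mat>(p.n_rows, p.n_cols));
    st.v.push_back(zeros<mat>(p.n_rows, p.n_cols));
  };
  for (int l = 0; l < net.n_layers; ++l)
    for (int d = 0; d < net.n_dir; ++d) {
      add(net.lstm[l][d].W); add(net.lstm[l][d].R);
      add(conv_to<mat>::from(net.lstm[l][d].b));
    }
  add(net.W1); add(conv_to<mat>::from(net.b1));
  add(net.W2); add(conv_to<mat>::from(net.b2));
}

void adam_step(Net& net, const Net& grad, AdamState& st,
               double lr, double b1, double b2, double eps = 1e-8) {
  st.step += 1;
  double bc1 = 1.0 - std::pow(b1, (double)st.step);
  double bc2 = 1.0 - std::pow(b2, (double)st.step);
  int k = 0;
  auto upd = [&](mat& p, const mat& g) {
    st.m[k] = b1 * st.m[k] + (1.0 - b1) * g;
    st.v[k] = b2 * st.v[k] + (1.0 - b2) * square(g);
    p -= lr * (st.m[k] / bc1) / (sqrt(st.v[k] / bc2) + eps);
    ++k;
  };
  auto updr = [&](rowvec& p, const rowvec& g) {
    mat pm = conv_to<mat>::from(p);
    upd(pm, conv_to<mat>::from(g));
    p = conv_to<rowvec>::from(pm);
  };
  for (int l = 0; l < net.n_layers; ++l)
    for (int d = 0; d < net.n_dir; ++d) {
      upd(net.lstm[l][d].W, grad.lstm[l][d].W);
      upd(net.lstm[l][d].R, grad.lstm[l][d].R);
      updr(net.lstm[l][d].b, grad.lstm[l][d].b);
    }
  upd(net.W1, grad.W1);
  updr(net.b1, grad.b1);
  upd(net.W2, grad.W2);
  updr(net.b2, grad.b2);
}

mat flat_mask(const mat& M, const uvec& idx) {
  const int B = idx.n_elem, T = M.n_cols;
  mat sub = M.rows(idx);              // B x T
  mat out(T * B, 1);
  for (int t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = sub.col(t);
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_train(Rcpp::List params, arma::cube X, arma::cube Y,
                            arma::mat M, int n_layers, int hidden, int n_dir,
                            int epochs, int batch_size, double lr,
                            double beta1, double beta2, double dropout,
                            int seed) {
  Net net = unpack(params, n_layers, hidden, n_dir);
  const int N = X.n_rows, T = X.n_slices, H = hidden;
  AdamState adam;
  adam_init(adam, net);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double keep = 1.0 - dropout;
  std::vector<double> history;
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  Net grad;
  ForwardCache fc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(N, start + batch_size);
      uvec idx(end - start);
      for (int i = start; i < end; ++i) idx[i - start] = order[i];
      int B = idx.n_elem;
      mat Xb = flatten_batch(X, idx), Yb = flatten_batch(Y, idx);
      mat Mb = flat_mask(M, idx);
      fc.drop.set_size(T * B, H);
      if (dropout > 0.0) {
        for (auto& v : fc.drop) v = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      } else {
        fc.drop.ones();
      }
      forward_batch(net, Xb, B, T, fc);
      ep_loss += backward_batch(net, Yb, Mb.col(0), fc, grad);
      adam_step(net, grad, adam, lr, beta1, beta2);
      ++n_batches;
    }
    history.push_back(ep_loss / std::max(1, n_batches));
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(net),
                            Rcpp::Named("loss_history") = history);
}

// [[Rcpp::export]]
arma::cube cpp_bilstm_predict(Rcpp::List params, arma::cube X, int n_layers,
                              int hidden, int n_dir) {
  Net net = unpack(params, n_layers, hidden, n_dir);
  const int N = X.n_rows, T = X.n_slices;
  cube out(N, net.n_out, T);
  const int chunk = 256;
  ForwardCache fc;
  for (int start = 0; start < N; start += chunk) {
    int end = std::min(N, start + chunk);
    uvec idx(end - start);
    for (int i = start; i < end; ++i) idx[i - start] = i;
    int B = idx.n_elem;
    mat Xb = flatten_batch(X, idx);
    fc.drop.ones(T * B, hidden);
    forward_batch(net, Xb, B, T, fc);
    for (int t = 0; t < T; ++t)
      out.slice(t).rows(idx) = fc.Yhat.rows(t * B, t * B + B - 1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_loss_grad(Rcpp::List params, arma::cube X, arma::cube Y,
                                arma::mat M, int n_layers, int hidden,
                                int n_dir) {
  Net net = unpack(params, n_layers, hidden, n_dir);
  const int N = X.n_rows, T = X.n_slices;
  uvec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  mat Xb = flatten_batch(X, idx), Yb = flatten_batch(Y, idx);
  mat Mb = flat_mask(M, idx);
  ForwardCache fc;
  fc.drop.ones(T * N, hidden);
  forward_batch(net, Xb, N, T, fc);
  Net grad;
  double loss = backward_batch(net, Yb, Mb.col(0), fc, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(grad));
}
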