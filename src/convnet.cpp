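// Coordinate-regression convolutional network: four Conv(3x3, valid)+MaxPool(2x2)
// blocks (32/64/128/256 filters), Dense(512, ReLU), Dropout(0.5), Dense(out,
// sigmoid). Trained with Adam on mean-squared error over normalized coordinates.
//
// Layout conventions (all single precision internally):
//  - an activation is an fmat of size C x (H*W*B); spatial column s = y + H*x,
//    image b occupying columns [b*H*W, (b+1)*H*W)
//  - an input column from R is channel-fastest: index c + C*(y + H*x)
//  - im2col row index r = c + Cin*dy + 3*Cin*dx, and conv weights follow the
//    same ordering (opaque to the R side, which only fixes fan-in/fan-out)
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

namespace {

struct LayerDims {
  int Cin, Cout, H, W;      // input channels / filters / input spatial size
  int Ho() const { return H - 2; }
  int Wo() const { return W - 2; }
  int Hp() const { return Ho() / 2; }
  int Wp() const { return Wo() / 2; }
};

// Fixed geometry for 128x128x3 input: 128->126->63->61->30->28->14->12->6
const LayerDims kConv[4] = {
  {3, 32, 128, 128}, {32, 64, 63, 63}, {64, 128, 30, 30}, {128, 256, 14, 14}
};
const int kFlat = 6 * 6 * 256;  // 9216
const int kDense = 512;

void im2col(const fmat& A, const LayerDims& d, int B, fmat& K) {
  const int H = d.H, Ho = d.Ho(), Wo = d.Wo(), Cin = d.Cin;
  K.set_size(Cin * 9, (size_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b) {
    const float* Ab = A.colptr((size_t)b * H * d.W);
    float* Kb = K.colptr((size_t)b * Ho * Wo);
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        float* kcol = Kb + ((size_t)x * Ho + y) * Cin * 9;
        for (int dx = 0; dx < 3; ++dx) {
          const float* src = Ab + ((size_t)(x + dx) * H + y) * Cin;
          std::memcpy(kcol + (size_t)dx * 3 * Cin, src,
                      sizeof(float) * 3 * Cin);
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
void col2im(const fmat& K, const LayerDims& d, int B, fmat& dA) {
  const int H = d.H, Ho = d.Ho(), Wo = d.Wo(), Cin = d.Cin;
  dA.zeros(Cin, (size_t)H * d.W * B);
  for (int b = 0; b < B; ++b) {
    float* Ab = dA.colptr((size_t)b * H * d.W);
    const float* Kb = K.colptr((size_t)b * Ho * Wo);
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        const float* kcol = Kb + ((size_t)x * Ho + y) * Cin * 9;
        for (int dx = 0; dx < 3; ++dx) {
          float* dst = Ab + ((size_t)(x + dx) * H + y) * Cin;
          const float* src = kcol + (size_t)dx * 3 * Cin;
          for (int i = 0; i < 3 * Cin; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// 2x2 max pooling with stride 2; odd trailing row/column dropped.
// IDX records, per (channel, pooled column), the source column of the max.
void maxpool(const fmat& Z, const LayerDims& d, int B, fmat& P, umat& IDX) {
  const int C = d.Cout, Ho = d.Ho(), Hp = d.Hp(), Wp = d.Wp();
  P.set_size(C, (size_t)Hp * Wp * B);
  IDX.set_size(C, (size_t)Hp * Wp * B);
  for (int b = 0; b < B; ++b) {
    const size_t in0 = (size_t)b * Ho * d.Wo(), out0 = (size_t)b * Hp * Wp;
    for (int xp = 0; xp < Wp; ++xp) {
      for (int yp = 0; yp < Hp; ++yp) {
        const size_t j = out0 + (size_t)xp * Hp + yp;
        const size_t s[4] = {in0 + (size_t)(2 * xp) * Ho + 2 * yp,
                             in0 + (size_t)(2 * xp) * Ho + 2 * yp + 1,
                             in0 + (size_t)(2 * xp + 1) * Ho + 2 * yp,
                             in0 + (size_t)(2 * xp + 1) * Ho + 2 * yp + 1};
        for (int c = 0; c < C; ++c) {
          float best = Z(c, s[0]);
          size_t bi = s[0];
          for (int q = 1; q < 4; ++q) {
            const float v = Z(c, s[q]);
            if (v > best) { best = v; bi = s[q]; }
          }
          P(c, j) = best;
          IDX(c, j) = bi;
        }
      }
    }
  }
}

void unpool(const fmat& dP, const umat& IDX, const LayerDims& d, int B,
            fmat& dZ) {
  dZ.zeros(d.Cout, (size_t)d.Ho() * d.Wo() * B);
  for (size_t j = 0; j < dP.n_cols; ++j)
    for (int c = 0; c < d.Cout; ++c) dZ(c, IDX(c, j)) += dP(c, j);
}

struct Weights {
  fmat Wc[4]; fvec bc[4];   // conv blocks
  fmat W5; fvec b5;         // dense 9216 -> 512
  fmat W6; fvec b6;         // dense 512 -> out
};

Weights from_list(const List& w) {
  Weights out;
  for (int l = 0; l < 4; ++l) {
    out.Wc[l] = conv_to<fmat>::from(Rcpp::as<mat>(w[2 * l]));
    out.bc[l] = conv_to<fvec>::from(Rcpp::as<vec>(w[2 * l + 1]));
  }
  out.W5 = conv_to<fmat>::from(Rcpp::as<mat>(w[8]));
  out.b5 = conv_to<fvec>::from(Rcpp::as<vec>(w[9]));
  out.W6 = conv_to<fmat>::from(Rcpp::as<mat>(w[10]));
  out.b6 = conv_to<fvec>::from(Rcpp::as<vec>(w[11]));
  return out;
}

List to_list(const Weights& w) {
  List out(12);
  for (int l = 0; l < 4; ++l) {
    out[2 * l] = Rcpp::wrap(conv_to<mat>::from(w.Wc[l]));
    out[2 * l + 1] = Rcpp::wrap(conv_to<vec>::from(w.bc[l]));
  }
  out[8] = Rcpp::wrap(conv_to<mat>::from(w.W5));
  out[9] = Rcpp::wrap(conv_to<vec>::from(w.b5));
  out[10] = Rcpp::wrap(conv_to<mat>::from(w.W6));
  out[11] = Rcpp::wrap(conv_to<vec>::from(w.b6));
  return out;
}

// Gather selected input columns into the first activation.
fmat gather(const fmat& X, const uvec& idx) {
  fmat A(3, (size_t)128 * 128 * idx.n_elem);
  for (size_t b = 0; b < idx.n_elem; ++b)
    std::memcpy(A.colptr((size_t)b * 128 * 128), X.colptr(idx[b]),
                sizeof(float) * X.n_rows);
  return A;
}

struct ForwardState {
  fmat K[4], Z[4], P[4];  // im2col, post-ReLU conv, pooled
  umat IDX[4];
  fmat F, Z5, H5, H5d, D, Pout;
};

// Forward pass on a gathered batch; dropout applied when rng != nullptr.
void forward(const Weights& w, const fmat& A1, int B, ForwardState& st,
             double drop_rate, std::mt19937* rng) {
  const fmat* in = &A1;
  for (int l = 0; l < 4; ++l) {
    im2col(*in, kConv[l], B, st.K[l]);
    st.Z[l] = w.Wc[l] * st.K[l];
    st.Z[l].each_col() += w.bc[l];
    st.Z[l].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    maxpool(st.Z[l], kConv[l], B, st.P[l], st.IDX[l]);
    in = &st.P[l];
  }
  st.F = fmat(const_cast<float*>(st.P[3].memptr()), kFlat, B, true, false);
  st.Z5 = w.W5 * st.F;
  st.Z5.each_col() += w.b5;
  st.H5 = st.Z5;
  st.H5.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (rng != nullptr && drop_rate > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    st.D.set_size(kDense, B);
    const float scale = 1.0f / (float)(1.0 - drop_rate);
    for (size_t j = 0; j < st.D.n_cols; ++j)
      for (int i = 0; i < kDense; ++i)
        st.D(i, j) = unif(*rng) < drop_rate ? 0.0f : scale;
    st.H5d = st.H5 % st.D;
  } else {
    st.H5d = st.H5;
  }
  st.Pout = w.W6 * st.H5d;
  st.Pout.each_col() += w.b6;
  st.Pout.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
}

struct Grads {
  fmat Wc[4]; fvec bc[4];
  fmat W5; fvec b5; fmat W6; fvec b6;
};

double backward(const Weights& w, const ForwardState& st, const fmat& Y,
                int B, double drop_rate, bool dropped, Grads& g) {
  const int out_dim = Y.n_rows;
  fmat diff = st.Pout - Y;
  const double loss = accu(conv_to<mat>::from(square(diff))) /
                      ((double)out_dim * B);
  fmat dZ6 = (2.0f / (float)(out_dim * B)) * diff % st.Pout %
             (1.0f - st.Pout);
  g.W6 = dZ6 * st.H5d.t();
  g.b6 = sum(dZ6, 1);
  fmat dH5 = w.W6.t() * dZ6;
  if (dropped && drop_rate > 0) dH5 %= st.D;
  fmat dZ5 = dH5;
  {
    const float* z = st.Z5.memptr();
    float* dd = dZ5.memptr();
    for (uword i = 0; i < dZ5.n_elem; ++i)
      if (z[i] <= 0.0f) dd[i] = 0.0f;
  }
  g.W5 = dZ5 * st.F.t();
  g.b5 = sum(dZ5, 1);
  fmat dF = w.W5.t() * dZ5;
  fmat dP = fmat(dF.memptr(), 256, (size_t)36 * B);  // reshape view
  for (int l = 3; l >= 0; --l) {
    fmat dZ;
    unpool(dP, st.IDX[l], kConv[l], B, dZ);
    {
      const float* z = st.Z[l].memptr();
      float* dd = dZ.memptr();
      for (uword i = 0; i < dZ.n_elem; ++i)
        if (z[i] <= 0.0f) dd[i] = 0.0f;
    }
    g.Wc[l] = dZ * st.K[l].t();
    g.bc[l] = sum(dZ, 1);
    if (l > 0) {
      fmat dK = w.Wc[l].t() * dZ;
      col2im(dK, kConv[l], B, dP);
    }
  }
  return loss;
}

struct AdamState {
  fmat mW[6], vW[6];
  fvec mb[6], vb[6];
  long t = 0;
  void init(const Weights& w) {
    const fmat* Ws[6] = {&w.Wc[0], &w.Wc[1], &w.Wc[2], &w.Wc[3], &w.W5, &w.W6};
    const fvec* bs[6] = {&w.bc[0], &w.bc[1], &w.bc[2], &w.bc[3], &w.b5, &w.b6};
    for (int i = 0; i < 6; ++i) {
      mW[i].zeros(size(*Ws[i])); vW[i].zeros(size(*Ws[i]));
      mb[i].zeros(size(*bs[i])); vb[i].zeros(size(*bs[i]));
    }
  }
};

void adam_step(Weights& w, const Grads& g, AdamState& a, double lr) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  a.t += 1;
  const float corr = (float)(lr * std::sqrt(1.0 - std::pow((double)b2, a.t)) /
                             (1.0 - std::pow((double)b1, a.t)));
  fmat* Ws[6] = {&w.Wc[0], &w.Wc[1], &w.Wc[2], &w.Wc[3], &w.W5, &w.W6};
  const fmat* gW[6] = {&g.Wc[0], &g.Wc[1], &g.Wc[2], &g.Wc[3], &g.W5, &g.W6};
  fvec* bs[6] = {&w.bc[0], &w.bc[1], &w.bc[2], &w.bc[3], &w.b5, &w.b6};
  const fvec* gb[6] = {&g.bc[0], &g.bc[1], &g.bc[2], &g.bc[3], &g.b5, &g.b6};
  for (int i = 0; i < 6; ++i) {
    a.mW[i] = b1 * a.mW[i] + (1 - b1) * (*gW[i]);
    a.vW[i] = b2 * a.vW[i] + (1 - b2) * square(*gW[i]);
    *Ws[i] -= corr * a.mW[i] / (sqrt(a.vW[i]) + eps);
    a.mb[i] = b1 * a.mb[i] + (1 - b1) * (*gb[i]);
    a.vb[i] = b2 * a.vb[i] + (1 - b2) * square(*gb[i]);
    *bs[i] -= corr * a.mb[i] / (sqrt(a.vb[i]) + eps);
  }
}

double eval_loss(const Weights& w, const fmat& X, const fmat& Y,
                 int batch) {
  const int N = X.n_cols;
  double sse = 0.0;
  ForwardState st;
  for (int start = 0; start < N; start += batch) {
    const int B = std::min(batch, N - start);
    uvec idx = regspace<uvec>(start, start + B - 1);
    fmat A1 = gather(X, idx);
    forward(w, A1, B, st, 0.0, nullptr);
    fmat diff = st.Pout - Y.cols(start, start + B - 1);
    sse += accu(conv_to<mat>::from(square(diff)));
  }
  return sse / ((double)Y.n_rows * N);
}

}  // namespace

// Analytic gradients of the mean-squared-error loss on a batch (no dropout);
// used by tests to validate the backward pass against finite differences.
// [[Rcpp::export(name = ".cnn_grad_cpp")]]
Rcpp::List cnn_grad_cpp(Rcpp::List weights, const arma::mat& X,
                        const arma::mat& Y) {
  const Weights w = from_list(weights);
  const fmat Xf = conv_to<fmat>::from(X);
  const fmat Yf = conv_to<fmat>::from(Y);
  const int B = Xf.n_cols;
  uvec idx = regspace<uvec>(0, B - 1);
  fmat A1 = gather(Xf, idx);
  ForwardState st;
  forward(w, A1, B, st, 0.0, nullptr);
  Grads g;
  const double loss = backward(w, st, Yf, B, 0.0, false, g);
  Weights gw;
  for (int l = 0; l < 4; ++l) { gw.Wc[l] = g.Wc[l]; gw.bc[l] = g.bc[l]; }
  gw.W5 = g.W5; gw.b5 = g.b5; gw.W6 = g.W6; gw.b6 = g.b6;
  Rcpp::List out = to_list(gw);
  out.attr("loss") = loss;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(Rcpp::List weights, const arma::mat& X) {
  const Weights w = from_list(weights);
  const fmat Xf = conv_to<fmat>::from(X);
  const int N = Xf.n_cols, out_dim = w.W6.n_rows, batch = 16;
  mat P(out_dim, N);
  ForwardState st;
  for (int start = 0; start < N; start += batch) {
    const int B = std::min(batch, N - start);
    uvec idx = regspace<uvec>(start, start + B - 1);
    fmat A1 = gather(Xf, idx);
    forward(w, A1, B, st, 0.0, nullptr);
    P.cols(start, start + B - 1) = conv_to<mat>::from(st.Pout);
  }
  return P;
}

// orders: N x max_epochs matrix of 1-based sample orderings (one column per
// epoch), generated on the R side from the data seed so that batch composition
// is reproducible under R's RNG contract.
// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, const arma::mat& Xtr,
                         const arma::mat& Ytr, const arma::mat& Xval,
                         const arma::mat& Yval, const arma::imat& orders,
                         double lr, int batch_size, int max_epochs,
                         int patience, double drop_rate, int drop_seed,
                         bool early_stop, bool verbose) {
  Weights w = from_list(weights);
  const fmat Xtrf = conv_to<fmat>::from(Xtr);
  const fmat Ytrf = conv_to<fmat>::from(Ytr);
  const fmat Xvalf = conv_to<fmat>::from(Xval);
  const fmat Yvalf = conv_to<fmat>::from(Yval);
  const int N = Xtrf.n_cols;
  const bool has_val = Xvalf.n_cols > 0;

  AdamState adam;
  adam.init(w);
  std::mt19937 rng((unsigned)drop_seed);
  std::vector<double> tr_hist, val_hist;
  double best_val = datum::inf;
  int best_epoch = -1, wait = 0;
  Weights best = w;

  ForwardState st;
  Grads g;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double ep_loss = 0.0;
    long n_seen = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      uvec idx(B);
      for (int i = 0; i < B; ++i)
        idx[i] = (uword)(orders(start + i, epoch) - 1);
      fmat A1 = gather(Xtrf, idx);
      fmat Yb(Ytrf.n_rows, B);
      for (int i = 0; i < B; ++i) Yb.col(i) = Ytrf.col(idx[i]);
      forward(w, A1, B, st, drop_rate, &rng);
      const double loss = backward(w, st, Yb, B, drop_rate, true, g);
      adam_step(w, g, adam, lr);
      ep_loss += loss * B;
      n_seen += B;
    }
    tr_hist.push_back(ep_loss / n_seen);
    double vl = NA_REAL;
    if (has_val) {
      vl = eval_loss(w, Xvalf, Yvalf, 32);
      val_hist.push_back(vl);
      if (vl < best_val) {
        best_val = vl;
        best = w;
        best_epoch = epoch;
        wait = 0;
      } else {
        ++wait;
      }
    } else {
      best = w;
      best_epoch = epoch;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch + 1 << " train " << tr_hist.back()
                  << " val " << (has_val ? vl : NA_REAL) << std::endl;
    Rcpp::checkUserInterrupt();
    if (early_stop && has_val && wait >= patience) break;
  }
  if (has_val) w = best;  // restore best-validation weights

  return Rcpp::List::create(
      Rcpp::Named("weights") = to_list(w),
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("best_val_loss") = has_val ? best_val : NA_REAL);
}
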