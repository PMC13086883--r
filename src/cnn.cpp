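// Core numerical kernels for the grade-classification CNN.
//
// The network is the fixed sequential architecture used throughout the
// package: six blocks of (3x3 conv, pad 1) -> ReLU -> (2x2 max pool),
// channel widths 16, 32, 64, 128, 256, 512 on a 3x64x64 input, followed by
// flatten -> linear(512,256) -> ReLU -> linear(256,1) -> sigmoid.
//
// Convolutions are evaluated as GEMMs over im2col buffers in single
// precision; weight gradients are accumulated over the batch in a fixed
// order so repeated runs are bit-identical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LayerDims {
  int in_ch, out_ch, size; // spatial size of the conv input (== output, pad 1)
};

// widths/sizes for the six conv blocks given a config
static std::vector<LayerDims> conv_dims(int in_channels, int base_maps,
                                        int n_blocks, int input_size) {
  std::vector<LayerDims> d(n_blocks);
  int ch = in_channels, sz = input_size;
  for (int b = 0; b < n_blocks; ++b) {
    int out = base_maps << b;
    d[b] = {ch, out, sz};
    ch = out;
    sz /= 2;
  }
  return d;
}

// im2col for a 3x3 kernel with padding 1.
// x: (in_ch) x (H*W) feature matrix, spatial index s = r + H*c.
// out: (in_ch*9) x (H*W); kernel offsets enumerated (dr,dc) in {-1,0,1}^2.
static void im2col3(const fmat& x, int H, fmat& col) {
  const int W = x.n_cols > 0 ? (int)(x.n_cols / 1) : 0; // unused; keep H==W
  (void)W;
  const int HW = (int)x.n_cols;
  const int C = (int)x.n_rows;
  const int side = H;
  col.zeros(C * 9, HW);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int c = 0; c < side; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= side) continue;
        int r0 = std::max(0, -dr), r1 = std::min(side, side - dr);
        if (r1 <= r0) continue;
        // rows r0..r1-1 of column c come from rows r0+dr.. of column cc
        col.submat(k * C, c * side + r0, (k + 1) * C - 1, c * side + r1 - 1) =
            x.cols(cc * side + r0 + dr, cc * side + r1 - 1 + dr);
      }
      ++k;
    }
  }
}

// adjoint of im2col3: scatter-add columns back into the padded image
static void col2im3(const fmat& col, int H, fmat& x) {
  const int C = (int)x.n_rows;
  const int side = H;
  x.zeros();
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int c = 0; c < side; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= side) continue;
        int r0 = std::max(0, -dr), r1 = std::min(side, side - dr);
        if (r1 <= r0) continue;
        x.cols(cc * side + r0 + dr, cc * side + r1 - 1 + dr) +=
            col.submat(k * C, c * side + r0, (k + 1) * C - 1,
                       c * side + r1 - 1);
      }
      ++k;
    }
  }
}

// 2x2 max pool; records argmax linear indices for the backward pass
static void maxpool2(const fmat& x, int H, fmat& y, umat& idx) {
  const int C = (int)x.n_rows;
  const int h = H / 2;
  y.set_size(C, h * h);
  idx.set_size(C, h * h);
  for (int c = 0; c < h; ++c) {
    for (int r = 0; r < h; ++r) {
      int s0 = (2 * r) + H * (2 * c);
      int cand[4] = {s0, s0 + 1, s0 + H, s0 + H + 1};
      int o = r + h * c;
      for (int ch = 0; ch < C; ++ch) {
        float best = x(ch, cand[0]);
        int bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          float v = x(ch, cand[j]);
          if (v > best) { best = v; bi = cand[j]; }
        }
        y(ch, o) = best;
        idx(ch, o) = (uword)bi;
      }
    }
  }
}

struct Weights {
  std::vector<fmat> Wc;  // conv kernels, out_ch x (in_ch*9)
  std::vector<fvec> bc;  // conv biases
  fmat W1; fvec b1;      // fc 512 -> 256
  fmat W2; fvec b2;      // fc 256 -> 1
};

static Weights unpack_weights(const Rcpp::List& w, int n_blocks) {
  Weights out;
  Rcpp::List conv = w["conv"];
  if ((int)conv.size() != n_blocks)
    Rcpp::stop("expected %d conv blocks, got %d", n_blocks, (int)conv.size());
  for (int b = 0; b < n_blocks; ++b) {
    Rcpp::List blk = conv[b];
    out.Wc.push_back(conv_to<fmat>::from(Rcpp::as<mat>(blk["W"])));
    out.bc.push_back(conv_to<fvec>::from(Rcpp::as<vec>(blk["b"])));
  }
  Rcpp::List fc1 = w["fc1"], fc2 = w["fc2"];
  out.W1 = conv_to<fmat>::from(Rcpp::as<mat>(fc1["W"]));
  out.b1 = conv_to<fvec>::from(Rcpp::as<vec>(fc1["b"]));
  out.W2 = conv_to<fmat>::from(Rcpp::as<mat>(fc2["W"]));
  out.b2 = conv_to<fvec>::from(Rcpp::as<vec>(fc2["b"]));
  return out;
}

// per-sample forward state kept for the backward pass
struct FwdState {
  std::vector<fmat> cols;   // im2col buffers
  std::vector<fmat> relu;   // post-ReLU conv activations
  std::vector<umat> poolix; // pool argmax
  std::vector<fmat> pooled; // post-pool activations
  fvec flat, h1;            // flattened features, post-ReLU fc hidden
  float logit;
};

static void forward_one(const Weights& w, const std::vector<LayerDims>& dims,
                        const fmat& x0, FwdState& st, bool keep,
                        int bump_layer = -1, int bump_ch = -1,
                        int bump_pix = -1, float bump_eps = 0.f) {
  const int nb = (int)dims.size();
  fmat cur = x0;
  if (keep) {
    st.cols.resize(nb); st.relu.resize(nb);
    st.poolix.resize(nb); st.pooled.resize(nb);
  }
  fmat col, conv, pooled;
  umat pix;
  for (int b = 0; b < nb; ++b) {
    im2col3(cur, dims[b].size, col);
    conv = w.Wc[b] * col;
    conv.each_col() += w.bc[b];
    conv.transform([](float v) { return v > 0.f ? v : 0.f; });
    if (b == bump_layer && bump_ch >= 0)
      conv(bump_ch, bump_pix) += bump_eps;
    maxpool2(conv, dims[b].size, pooled, pix);
    if (keep) {
      st.cols[b] = col; st.relu[b] = conv;
      st.poolix[b] = pix; st.pooled[b] = pooled;
    }
    cur = pooled;
  }
  fvec flat = vectorise(cur); // 512 x 1 (channels over the 1x1 pixel)
  fvec h1 = w.W1 * flat + w.b1;
  h1.transform([](float v) { return v > 0.f ? v : 0.f; });
  float logit = dot(w.W2.row(0).t(), h1) + w.b2(0);
  if (keep) { st.flat = flat; st.h1 = h1; }
  st.logit = logit;
}

struct Grads {
  std::vector<fmat> dWc;
  std::vector<fvec> dbc;
  fmat dW1; fvec db1;
  fmat dW2; fvec db2;
  void init(const Weights& w) {
    dWc.resize(w.Wc.size()); dbc.resize(w.bc.size());
    for (size_t b = 0; b < w.Wc.size(); ++b) {
      dWc[b].zeros(w.Wc[b].n_rows, w.Wc[b].n_cols);
      dbc[b].zeros(w.bc[b].n_elem);
    }
    dW1.zeros(w.W1.n_rows, w.W1.n_cols); db1.zeros(w.b1.n_elem);
    dW2.zeros(w.W2.n_rows, w.W2.n_cols); db2.zeros(w.b2.n_elem);
  }
};

// backprop one sample given dL/dlogit; accumulates into g.
// If cam_layer >= 0, also writes dlogit/d(relu activation of that block)
// into cam_grad (taking dlogit scale out again).
static void backward_one(const Weights& w, const std::vector<LayerDims>& dims,
                         const FwdState& st, float dlogit, Grads& g,
                         int cam_layer = -1, fmat* cam_grad = nullptr) {
  const int nb = (int)dims.size();
  // head
  g.dW2 += dlogit * st.h1.t();
  g.db2(0) += dlogit;
  fvec dh1 = dlogit * w.W2.row(0).t();
  for (uword i = 0; i < dh1.n_elem; ++i)
    if (st.h1(i) <= 0.f) dh1(i) = 0.f;
  g.dW1 += dh1 * st.flat.t();
  g.db1 += dh1;
  fvec dflat = w.W1.t() * dh1;
  // reshape into channels x 1 pixel
  fmat dcur(dflat.memptr(), dims[nb - 1].out_ch, 1);
  fmat dconv, dcol, dprev;
  for (int b = nb - 1; b >= 0; --b) {
    const int H = dims[b].size;
    // unpool: route gradient to argmax positions
    dconv.zeros(dims[b].out_ch, H * H);
    const umat& pix = st.poolix[b];
    for (uword j = 0; j < pix.n_cols; ++j)
      for (uword ch = 0; ch < pix.n_rows; ++ch)
        dconv(ch, pix(ch, j)) += dcur(ch, j);
    // ReLU gate
    dconv.elem(find(st.relu[b] <= 0.f)).zeros();
    if (b == cam_layer && cam_grad != nullptr)
      *cam_grad = dconv / dlogit;
    g.dWc[b] += dconv * st.cols[b].t();
    g.dbc[b] += sum(dconv, 1);
    if (b > 0) {
      dcol = w.Wc[b].t() * dconv;
      dprev.set_size(dims[b].in_ch, H * H);
      col2im3(dcol, H, dprev);
      dcur = dprev;
    }
  }
}

static std::vector<LayerDims> dims_from_list(const Rcpp::List& cfg) {
  return conv_dims(Rcpp::as<int>(cfg["in_channels"]),
                   Rcpp::as<int>(cfg["base_feature_maps"]),
                   Rcpp::as<int>(cfg["n_conv_blocks"]),
                   Rcpp::as<int>(cfg["input_size"]));
}

// batch array (H, W, C, N) column-major -> per-sample C x (H*W) matrix
static fmat sample_matrix(const Rcpp::NumericVector& x, int H, int W, int C,
                          int n) {
  fmat out(C, H * W);
  const double* p = x.begin() + (size_t)n * H * W * C;
  for (int ch = 0; ch < C; ++ch)
    for (int s = 0; s < H * W; ++s)
      out(ch, s) = (float)p[s + (size_t)ch * H * W];
  return out;
}

static float sigmoidf(float z) {
  return z >= 0.f ? 1.f / (1.f + std::exp(-z))
                  : std::exp(z) / (1.f + std::exp(z));
}

} // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::List weights, Rcpp::List config,
                                    Rcpp::NumericVector x) {
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) Rcpp::stop("input must be a 4-d array (H, W, C, N)");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  std::vector<LayerDims> dims = dims_from_list(config);
  if (H != dims[0].size || W != dims[0].size || C != dims[0].in_ch)
    Rcpp::stop("input shape %dx%dx%d does not match the model (%dx%dx%d)", H,
               W, C, dims[0].size, dims[0].size, dims[0].in_ch);
  Weights w = unpack_weights(weights, (int)dims.size());
  Rcpp::NumericVector out(N);
  FwdState st;
  for (int n = 0; n < N; ++n) {
    fmat x0 = sample_matrix(x, H, W, C, n);
    forward_one(w, dims, x0, st, false);
    out[n] = sigmoidf(st.logit);
  }
  return out;
}

// Weighted binary cross-entropy over a batch; returns loss, probabilities
// and gradients for every weight tensor.
// [[Rcpp::export(name = ".cnn_batch_grad")]]
Rcpp::List cnn_batch_grad_cpp(Rcpp::List weights, Rcpp::List config,
                              Rcpp::NumericVector x, Rcpp::NumericVector y,
                              Rcpp::NumericVector sample_weight) {
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) Rcpp::stop("input must be a 4-d array (H, W, C, N)");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  if ((int)y.size() != N || (int)sample_weight.size() != N)
    Rcpp::stop("labels/weights length must match batch size");
  std::vector<LayerDims> dims = dims_from_list(config);
  Weights w = unpack_weights(weights, (int)dims.size());
  Grads g;
  g.init(w);
  Rcpp::NumericVector probs(N);
  double loss = 0.0;
  FwdState st;
  const float eps = 1e-7f;
  for (int n = 0; n < N; ++n) {
    fmat x0 = sample_matrix(x, H, W, C, n);
    forward_one(w, dims, x0, st, true);
    float p = sigmoidf(st.logit);
    probs[n] = p;
    float yv = (float)y[n], wv = (float)sample_weight[n];
    float pc = std::min(std::max(p, eps), 1.f - eps);
    loss += -wv * (yv * std::log(pc) + (1.f - yv) * std::log(1.f - pc));
    float dlogit = wv * (p - yv) / (float)N;
    backward_one(w, dims, st, dlogit, g);
  }
  loss /= N;
  Rcpp::List gconv(dims.size());
  for (size_t b = 0; b < dims.size(); ++b)
    gconv[b] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(g.dWc[b]),
        Rcpp::Named("b") = conv_to<vec>::from(g.dbc[b]));
  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("conv") = gconv,
      Rcpp::Named("fc1") = Rcpp::List::create(
          Rcpp::Named("W") = conv_to<mat>::from(g.dW1),
          Rcpp::Named("b") = conv_to<vec>::from(g.db1)),
      Rcpp::Named("fc2") = Rcpp::List::create(
          Rcpp::Named("W") = conv_to<mat>::from(g.dW2),
          Rcpp::Named("b") = conv_to<vec>::from(g.db2)));
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = probs,
                            Rcpp::Named("grads") = grads);
}

// Activations and logit-gradients of one conv block for Grad-CAM.
// Returns A (channels x pixels, post-ReLU) and dlogit/dA, plus the spatial
// side length and the predicted probability.
// [[Rcpp::export(name = ".cnn_cam_grad")]]
Rcpp::List cnn_cam_grad_cpp(Rcpp::List weights, Rcpp::List config,
                            Rcpp::NumericVector x, int layer) {
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) Rcpp::stop("input must be a 3-d array (H, W, C)");
  const int H = dm[0], W = dm[1], C = dm[2];
  std::vector<LayerDims> dims = dims_from_list(config);
  if (layer < 1 || layer > (int)dims.size())
    Rcpp::stop("cam layer must be in 1..%d", (int)dims.size());
  Weights w = unpack_weights(weights, (int)dims.size());
  Rcpp::NumericVector xr = Rcpp::clone(x);
  xr.attr("dim") = Rcpp::IntegerVector::create(H, W, C, 1);
  fmat x0 = sample_matrix(xr, H, W, C, 0);
  FwdState st;
  forward_one(w, dims, x0, st, true);
  Grads g;
  g.init(w);
  fmat cam_grad;
  backward_one(w, dims, st, 1.0f, g, layer - 1, &cam_grad);
  return Rcpp::List::create(
      Rcpp::Named("activation") = conv_to<mat>::from(st.relu[layer - 1]),
      Rcpp::Named("gradient") = conv_to<mat>::from(cam_grad),
      Rcpp::Named("side") = dims[layer - 1].size,
      Rcpp::Named("prob") = sigmoidf(st.logit));
}

// Forward with an additive perturbation of one post-ReLU conv activation;
// used to validate the activation gradients by finite differences.
// [[Rcpp::export(name = ".cnn_forward_bumped")]]
double cnn_forward_bumped_cpp(Rcpp::List weights, Rcpp::List config,
                              Rcpp::NumericVector x, int layer, int channel,
                              int pixel, double eps) {
  Rcpp::IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2];
  std::vector<LayerDims> dims = dims_from_list(config);
  Weights w = unpack_weights(weights, (int)dims.size());
  Rcpp::NumericVector xr = Rcpp::clone(x);
  xr.attr("dim") = Rcpp::IntegerVector::create(H, W, C, 1);
  fmat x0 = sample_matrix(xr, H, W, C, 0);
  FwdState st;
  forward_one(w, dims, x0, st, false, layer - 1, channel - 1, pixel - 1,
              (float)eps);
  return (double)st.logit;
}
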