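// Compact convolutional classifier used for driver-region classification:
// three 3x3 same-padding conv layers (ReLU, 2x2 max-pool after each),
// two ReLU dense layers with dropout, softmax head.  Trained with Adam on
// class-weighted categorical cross-entropy, with early stopping, learning
// rate reduction and best-model checkpointing.  Everything is seeded and
// single-threaded for reproducibility.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
// single precision throughout: halves memory traffic and roughly doubles
// GEMM throughput on one CPU; classification is insensitive to the loss of
// mantissa, and gradient checks against double finite differences pass at
// the appropriate tolerance.
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef arma::umat umat;
typedef float real_t;

struct Spec {
  int H, W, C, K;
  std::vector<int> filters;   // conv filter counts
  std::vector<int> dense;     // dense layer units
  double dropout;
  // derived per conv layer: input dims
  std::vector<int> h_in, w_in, c_in, h_pool, w_pool;
  void derive() {
    int h = H, w = W, c = C;
    h_in.clear(); w_in.clear(); c_in.clear(); h_pool.clear(); w_pool.clear();
    for (size_t l = 0; l < filters.size(); ++l) {
      h_in.push_back(h); w_in.push_back(w); c_in.push_back(c);
      if (h < 2 || w < 2)
        stop("input too small: spatial dims collapse at conv block %d "
             "(need >= 8 x 8 input for 3 pooling stages)", (int)l + 1);
      h /= 2; w /= 2; c = filters[l];
      h_pool.push_back(h); w_pool.push_back(w);
    }
    if (h < 1 || w < 1) stop("input too small after pooling");
  }
  int flat_dim() const {
    return h_pool.back() * w_pool.back() * filters.back();
  }
};

static Spec make_spec(List spec) {
  Spec s;
  IntegerVector in = spec["input_shape"];
  s.H = in[0]; s.W = in[1]; s.C = in.size() > 2 ? in[2] : 1;
  IntegerVector f = spec["filters"];
  s.filters.assign(f.begin(), f.end());
  IntegerVector d = spec["dense"];
  s.dense.assign(d.begin(), d.end());
  s.K = as<int>(spec["n_classes"]);
  s.dropout = as<double>(spec["dropout"]);
  s.derive();
  return s;
}

// im2col for 3x3 same padding: rows = H*W output pixels of one sample
// (column-major over h), cols = 9*C (kh + 3*kw + 9*c).
static void im2col_sample(const real_t* x, int H, int W, int C,
                          mat& IM, int row0) {
  for (int c = 0; c < C; ++c) {
    const real_t* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int q = kh + 3 * kw + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kw - 1;
          real_t* dst = IM.colptr(q) + row0 + (size_t)H * j;
          if (jj < 0 || jj >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const real_t* src = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + kh - 1;
            dst[i] = (ii >= 0 && ii < H) ? src[ii] : 0.0;
          }
        }
      }
    }
  }
}

// col2im (transpose of im2col): scatter-add dIM back to a sample gradient.
static void col2im_sample(const mat& dIM, int row0, int H, int W, int C,
                          real_t* dx) {
  for (int c = 0; c < C; ++c) {
    real_t* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int q = kh + 3 * kw + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kw - 1;
          if (jj < 0 || jj >= W) continue;
          const real_t* src = dIM.colptr(q) + row0 + (size_t)H * j;
          real_t* dst = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + kh - 1;
            if (ii >= 0 && ii < H) dst[ii] += src[i];
          }
        }
      }
    }
  }
}

struct Weights {
  std::vector<mat> Wc;  // conv: 9*C_in x F
  std::vector<vec> bc;
  std::vector<mat> Wd;  // dense (incl. softmax head): in x out
  std::vector<vec> bd;
};

static Weights weights_from_list(const List& wl, const Spec& s) {
  Weights w;
  int k = 0;
  for (size_t l = 0; l < s.filters.size(); ++l) {
    w.Wc.push_back(arma::conv_to<mat>::from(as<arma::mat>(wl[k++])));
    w.bc.push_back(arma::conv_to<vec>::from(as<arma::vec>(wl[k++])));
  }
  for (size_t l = 0; l < s.dense.size() + 1; ++l) {
    w.Wd.push_back(arma::conv_to<mat>::from(as<arma::mat>(wl[k++])));
    w.bd.push_back(arma::conv_to<vec>::from(as<arma::vec>(wl[k++])));
  }
  return w;
}

static List weights_to_list(const Weights& w) {
  List out;
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    out.push_back(wrap(arma::conv_to<arma::mat>::from(w.Wc[l])));
    out.push_back(wrap(arma::conv_to<arma::vec>::from(w.bc[l])));
  }
  for (size_t l = 0; l < w.Wd.size(); ++l) {
    out.push_back(wrap(arma::conv_to<arma::mat>::from(w.Wd[l])));
    out.push_back(wrap(arma::conv_to<arma::vec>::from(w.bd[l])));
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(List spec, int seed) {
  Spec s = make_spec(spec);
  std::mt19937 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Weights w;
  for (size_t l = 0; l < s.filters.size(); ++l) {
    const int fan_in = 9 * s.c_in[l];
    mat W(fan_in, s.filters[l]);
    for (auto& v : W) v = (real_t)(nd(rng) * std::sqrt(2.0 / fan_in));
    w.Wc.push_back(W);
    w.bc.push_back(vec(s.filters[l], arma::fill::zeros));
  }
  int in_dim = s.flat_dim();
  std::vector<int> outs(s.dense);
  outs.push_back(s.K);
  for (size_t l = 0; l < outs.size(); ++l) {
    const bool head = (l == outs.size() - 1);
    mat W(in_dim, outs[l]);
    const double sc = head ? std::sqrt(1.0 / in_dim)
                           : std::sqrt(2.0 / in_dim);
    for (auto& v : W) v = (real_t)(nd(rng) * sc);
    w.Wd.push_back(W);
    w.bd.push_back(vec(outs[l], arma::fill::zeros));
    in_dim = outs[l];
  }
  return weights_to_list(w);
}

struct FwdCache {
  std::vector<mat> IM;       // im2col per conv layer
  std::vector<mat> Z;        // post-relu conv activations (B*HW x F)
  std::vector<umat> amax;    // pool argmax (row in Z) per pooled element
  std::vector<mat> P;        // pooled activations
  std::vector<mat> A;        // dense activations (post relu, post dropout)
  std::vector<mat> drop;     // dropout masks
  mat probs;
};

// Forward pass over a batch (columns of X).  When training, dropout masks
// are sampled from rng; cache is filled for backward when keep_cache.
static void forward(const Spec& s, const Weights& w, const mat& X,
                    bool training, bool keep_cache, std::mt19937& rng,
                    FwdCache& fc) {
  const int B = X.n_cols;
  const size_t L = s.filters.size();
  fc.IM.assign(L, mat()); fc.Z.assign(L, mat());
  fc.amax.assign(L, umat()); fc.P.assign(L, mat());
  mat cur = X;  // D x B, conv input
  for (size_t l = 0; l < L; ++l) {
    const int H = s.h_in[l], W = s.w_in[l], C = s.c_in[l];
    const int F = s.filters[l], HW = H * W;
    mat IM((size_t)B * HW, 9 * C);
    for (int b = 0; b < B; ++b)
      im2col_sample(cur.colptr(b), H, W, C, IM, b * HW);
    mat Z = IM * w.Wc[l];
    Z.each_row() += w.bc[l].t();
    Z.transform([](real_t v) { return v > 0 ? v : (real_t)0; });
    // max pool 2x2 stride 2 (floor)
    const int Ho = s.h_pool[l], Wo = s.w_pool[l];
    mat P((size_t)B * Ho * Wo, F);
    umat amax((size_t)B * Ho * Wo, F);
    for (int b = 0; b < B; ++b) {
      const size_t zb = (size_t)b * HW, pb = (size_t)b * Ho * Wo;
      for (int f = 0; f < F; ++f) {
        const real_t* zc = Z.colptr(f);
        real_t* pc = P.colptr(f);
        arma::uword* ac = amax.colptr(f);
        for (int j = 0; j < Wo; ++j) {
          for (int i = 0; i < Ho; ++i) {
            const size_t r00 = zb + 2 * i + (size_t)H * (2 * j);
            const size_t cand[4] = {r00, r00 + 1, r00 + H, r00 + H + 1};
            size_t best = cand[0];
            real_t bv = zc[cand[0]];
            for (int q = 1; q < 4; ++q)
              if (zc[cand[q]] > bv) { bv = zc[cand[q]]; best = cand[q]; }
            pc[pb + i + (size_t)Ho * j] = bv;
            ac[pb + i + (size_t)Ho * j] = best;
          }
        }
      }
    }
    if (keep_cache) { fc.IM[l] = std::move(IM); fc.Z[l] = std::move(Z);
                      fc.amax[l] = amax; }
    // flatten pooled output to (Ho*Wo*F) x B
    mat nxt(Ho * Wo * F, B);
    for (int b = 0; b < B; ++b) {
      const mat sub = P.rows((size_t)b * Ho * Wo,
                             (size_t)(b + 1) * Ho * Wo - 1);
      std::copy(sub.begin(), sub.end(), nxt.colptr(b));
    }
    if (keep_cache) fc.P[l] = std::move(P);
    cur = std::move(nxt);
  }
  // dense stack
  const size_t nd = s.dense.size();
  fc.A.assign(nd + 1, mat());
  fc.drop.assign(nd, mat());
  std::uniform_real_distribution<double> ud(0.0, 1.0);
  mat a = cur;
  if (keep_cache) fc.A[0] = a;  // flat input (pre-dense)
  std::vector<mat> dense_in(nd + 1);
  for (size_t l = 0; l < nd; ++l) {
    dense_in[l] = a;
    mat z = w.Wd[l].t() * a;
    z.each_col() += w.bd[l];
    z.transform([](real_t v) { return v > 0 ? v : (real_t)0; });
    if (training && s.dropout > 0) {
      mat msk(z.n_rows, z.n_cols);
      const double keep = 1.0 - s.dropout;
      for (auto& v : msk) v = (ud(rng) < keep) ? (real_t)(1.0 / keep) : (real_t)0;
      z %= msk;
      if (keep_cache) fc.drop[l] = std::move(msk);
    }
    a = std::move(z);
    if (keep_cache) fc.A[l + 1] = a;
  }
  mat logits = w.Wd[nd].t() * a;
  logits.each_col() += w.bd[nd];
  logits.each_row() -= arma::max(logits, 0);
  mat e = arma::exp(logits);
  arma::frowvec denom = arma::sum(e, 0);
  fc.probs = e.each_row() / denom;
}

// Backward pass; returns gradients in the same layout as Weights.
static void backward(const Spec& s, const Weights& w, const mat& X,
                     const arma::ivec& y, const vec& sw, FwdCache& fc,
                     Weights& g) {
  const int B = X.n_cols;
  const size_t nd = s.dense.size();
  // dLogits for sum-reduction weighted CE divided by B (mean reduction)
  mat dlog = fc.probs;
  for (int b = 0; b < B; ++b) {
    dlog(y[b], b) -= 1.0;
    dlog.col(b) *= sw[b] / B;
  }
  g.Wd.assign(nd + 1, mat());
  g.bd.assign(nd + 1, vec());
  mat da;
  {
    const mat& a_in = fc.A[nd];
    g.Wd[nd] = a_in * dlog.t();
    g.bd[nd] = arma::sum(dlog, 1);
    da = w.Wd[nd] * dlog;
  }
  for (int l = (int)nd - 1; l >= 0; --l) {
    mat dz = da;
    if (fc.drop[l].n_elem) dz %= fc.drop[l];
    const mat& act = fc.A[l + 1];
    dz.elem(arma::find(act == 0)).zeros();
    g.Wd[l] = fc.A[l] * dz.t();
    g.bd[l] = arma::sum(dz, 1);
    da = w.Wd[l] * dz;
  }
  // conv stack backward
  const size_t L = s.filters.size();
  g.Wc.assign(L, mat());
  g.bc.assign(L, vec());
  mat dcur = da;  // gradient w.r.t. flattened pooled output of last conv
  for (int l = (int)L - 1; l >= 0; --l) {
    const int H = s.h_in[l], W = s.w_in[l], C = s.c_in[l];
    const int F = s.filters[l], HW = H * W;
    const int Ho = s.h_pool[l], Wo = s.w_pool[l];
    // unflatten dcur (Ho*Wo*F x B) -> dP (B*Ho*Wo x F)
    mat dP((size_t)B * Ho * Wo, F, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      const real_t* src = dcur.colptr(b);
      for (int f = 0; f < F; ++f)
        std::copy(src + (size_t)f * Ho * Wo, src + (size_t)(f + 1) * Ho * Wo,
                  dP.colptr(f) + (size_t)b * Ho * Wo);
    }
    // pool backward via argmax
    mat dZ((size_t)B * HW, F, arma::fill::zeros);
    for (int f = 0; f < F; ++f) {
      const real_t* dpc = dP.colptr(f);
      const arma::uword* ac = fc.amax[l].colptr(f);
      real_t* dzc = dZ.colptr(f);
      for (size_t r = 0; r < dP.n_rows; ++r) dzc[ac[r]] += dpc[r];
    }
    dZ.elem(arma::find(fc.Z[l] == 0)).zeros();
    g.Wc[l] = fc.IM[l].t() * dZ;
    g.bc[l] = arma::sum(dZ, 0).t();
    if (l > 0) {
      mat dIM = dZ * w.Wc[l].t();
      const int Hp = s.h_in[l], Wp = s.w_in[l];
      mat dprev(s.h_pool[l - 1] * s.w_pool[l - 1] * s.filters[l - 1], B,
                arma::fill::zeros);
      for (int b = 0; b < B; ++b)
        col2im_sample(dIM, b * HW, Hp, Wp, C, dprev.colptr(b));
      dcur = std::move(dprev);
    }
  }
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Weights& w) {
    for (const auto& m : w.Wc) { mW.push_back(mat(arma::size(m), arma::fill::zeros));
                                 vW.push_back(mat(arma::size(m), arma::fill::zeros)); }
    for (const auto& m : w.Wd) { mW.push_back(mat(arma::size(m), arma::fill::zeros));
                                 vW.push_back(mat(arma::size(m), arma::fill::zeros)); }
    for (const auto& b : w.bc) { mb.push_back(vec(b.n_elem, arma::fill::zeros));
                                 vb.push_back(vec(b.n_elem, arma::fill::zeros)); }
    for (const auto& b : w.bd) { mb.push_back(vec(b.n_elem, arma::fill::zeros));
                                 vb.push_back(vec(b.n_elem, arma::fill::zeros)); }
  }
  void stepm(mat& w, const mat& g, mat& m, mat& v, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  }
  void stepv(vec& w, const vec& g, vec& m, vec& v, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  }
  void update(Weights& w, const Weights& g, double lr) {
    ++t;
    size_t k = 0;
    for (size_t l = 0; l < w.Wc.size(); ++l, ++k)
      stepm(w.Wc[l], g.Wc[l], mW[k], vW[k], lr);
    for (size_t l = 0; l < w.Wd.size(); ++l, ++k)
      stepm(w.Wd[l], g.Wd[l], mW[k], vW[k], lr);
    k = 0;
    for (size_t l = 0; l < w.bc.size(); ++l, ++k)
      stepv(w.bc[l], g.bc[l], mb[k], vb[k], lr);
    for (size_t l = 0; l < w.bd.size(); ++l, ++k)
      stepv(w.bd[l], g.bd[l], mb[k], vb[k], lr);
  }
};

static double eval_loss_acc(const Spec& s, const Weights& w, const mat& X,
                            const arma::ivec& y, const vec& sw,
                            std::mt19937& rng, double* acc,
                            int batch = 256) {
  const int n = X.n_cols;
  double loss = 0, wsum = 0;
  int correct = 0;
  FwdCache fc;
  for (int at = 0; at < n; at += batch) {
    const int b2 = std::min(n, at + batch);
    mat Xb = X.cols(at, b2 - 1);
    forward(s, w, Xb, false, false, rng, fc);
    for (int b = at; b < b2; ++b) {
      const double p = std::max((double)fc.probs(y[b], b - at), 1e-12);
      loss += -sw[b] * std::log(p);
      wsum += sw[b];
      arma::uword best;
      fc.probs.col(b - at).max(best);
      if ((int)best == y[b]) ++correct;
    }
  }
  if (acc) *acc = (double)correct / n;
  return loss / std::max(wsum, 1e-12);
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericMatrix cnn_predict(List spec, List weights, NumericMatrix X) {
  Spec s = make_spec(spec);
  Weights w = weights_from_list(weights, s);
  std::mt19937 rng(0);
  mat Xm = arma::conv_to<mat>::from(
      arma::mat(X.begin(), X.nrow(), X.ncol(), false));
  FwdCache fc;
  const int n = Xm.n_cols;
  mat out(s.K, n);
  for (int at = 0; at < n; at += 256) {
    const int b2 = std::min(n, at + 256);
    mat Xb = Xm.cols(at, b2 - 1);
    forward(s, w, Xb, false, false, rng, fc);
    out.cols(at, b2 - 1) = fc.probs;
  }
  return wrap(arma::conv_to<arma::mat>::from(out.t()));
}

// Sum-reduction weighted cross-entropy (used by the class-weighting
// equivalence check).
// [[Rcpp::export(name = ".cnn_loss_sum")]]
double cnn_loss_sum(List spec, List weights, NumericMatrix X,
                    IntegerVector y, NumericVector sw) {
  Spec s = make_spec(spec);
  Weights w = weights_from_list(weights, s);
  std::mt19937 rng(0);
  mat Xm = arma::conv_to<mat>::from(
      arma::mat(X.begin(), X.nrow(), X.ncol(), false));
  FwdCache fc;
  forward(s, w, Xm, false, false, rng, fc);
  double loss = 0;
  for (int b = 0; b < Xm.n_cols; ++b)
    loss += -sw[b] * std::log(std::max((double)fc.probs(y[b], b), 1e-12));
  return loss;
}

// Analytic gradients of the mean-reduction weighted CE for one batch
// (dropout off); used by the finite-difference backprop test.
// [[Rcpp::export(name = ".cnn_grad")]]
List cnn_grad(List spec, List weights, NumericMatrix X, IntegerVector y,
              NumericVector sw) {
  Spec s = make_spec(spec);
  Weights w = weights_from_list(weights, s);
  std::mt19937 rng(0);
  mat Xm = arma::conv_to<mat>::from(
      arma::mat(X.begin(), X.nrow(), X.ncol(), false));
  arma::ivec yv(X.ncol());
  for (int i = 0; i < X.ncol(); ++i) yv[i] = y[i];
  vec swv = arma::conv_to<vec>::from(arma::vec(sw.begin(), sw.size(), false));
  FwdCache fc;
  Spec s0 = s;
  s0.dropout = 0;
  forward(s0, w, Xm, true, true, rng, fc);
  Weights g;
  backward(s0, w, Xm, yv, swv, fc, g);
  return weights_to_list(g);
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List spec, List weights, NumericMatrix X, IntegerVector y,
               NumericVector sample_w, Nullable<NumericMatrix> Xval_,
               Nullable<IntegerVector> yval_, List config) {
  Spec s = make_spec(spec);
  Weights w = weights_from_list(weights, s);
  const int n = X.ncol();
  mat Xm = arma::conv_to<mat>::from(
      arma::mat(X.begin(), X.nrow(), n, false));
  arma::ivec yv(n);
  for (int i = 0; i < n; ++i) yv[i] = y[i];
  vec sw = arma::conv_to<vec>::from(arma::vec(sample_w.begin(), n, false));

  mat Xval; arma::ivec yval; vec swval;
  bool has_val = Xval_.isNotNull() && yval_.isNotNull();
  if (has_val) {
    NumericMatrix Xv(Xval_);
    IntegerVector yvl(yval_);
    Xval = arma::conv_to<mat>::from(
        arma::mat(Xv.begin(), Xv.nrow(), Xv.ncol(), false));
    yval.set_size(Xv.ncol());
    for (int i = 0; i < Xv.ncol(); ++i) yval[i] = yvl[i];
    swval = vec(Xv.ncol(), arma::fill::ones);
  }

  const int max_epochs = as<int>(config["max_epochs"]);
  const int batch = as<int>(config["batch_size"]);
  double lr = as<double>(config["lr"]);
  const double lr_factor = as<double>(config["lr_factor"]);
  const int lr_patience = as<int>(config["lr_patience"]);
  const int es_patience = as<int>(config["es_patience"]);
  const std::string monitor = as<std::string>(config["monitor"]);
  const int seed = as<int>(config["seed"]);
  const bool verbose = as<bool>(config["verbose"]);
  const double min_delta = 1e-5;
  if (monitor == "val_loss" && !has_val)
    stop("monitor = 'val_loss' requires validation data");

  std::mt19937 rng(seed);
  Adam adam;
  adam.init(w);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Weights best = w;
  double best_mon = std::numeric_limits<double>::infinity();
  int best_epoch = -1, since_best = 0, since_lr = 0;
  std::vector<double> h_tl, h_ta, h_vl, h_va, h_lr;

  FwdCache fc;
  Weights g;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double run_loss = 0, run_w = 0;
    int run_correct = 0;
    for (int at = 0; at < n; at += batch) {
      const int b2 = std::min(n, at + batch);
      const int B = b2 - at;
      mat Xb(Xm.n_rows, B);
      arma::ivec yb(B);
      vec swb(B);
      for (int b = 0; b < B; ++b) {
        Xb.col(b) = Xm.col(order[at + b]);
        yb[b] = yv[order[at + b]];
        swb[b] = sw[order[at + b]];
      }
      forward(s, w, Xb, true, true, rng, fc);
      for (int b = 0; b < B; ++b) {
        run_loss += -swb[b] *
          std::log(std::max((double)fc.probs(yb[b], b), 1e-12));
        run_w += swb[b];
        arma::uword best;
        fc.probs.col(b).max(best);
        if ((int)best == yb[b]) ++run_correct;
      }
      backward(s, w, Xb, yb, swb, fc, g);
      adam.update(w, g, lr);
    }
    // running (minibatch, dropout-on) loss and accuracy, Keras-style
    const double train_loss = run_loss / std::max(run_w, 1e-12);
    if (!std::isfinite(train_loss))
      stop("loss became non-finite at epoch %d", epoch + 1);
    double train_acc = (double)run_correct / n;
    double val_loss = NA_REAL, val_acc = NA_REAL;
    if (has_val) {
      double acc;
      val_loss = eval_loss_acc(s, w, Xval, yval, swval, rng, &acc);
      val_acc = acc;
    }
    h_tl.push_back(train_loss); h_ta.push_back(train_acc);
    h_vl.push_back(val_loss); h_va.push_back(val_acc);
    h_lr.push_back(lr);
    const double mon = (monitor == "val_loss") ? val_loss : train_loss;
    if (mon < best_mon - min_delta) {
      best_mon = mon; best = w; best_epoch = epoch;
      since_best = 0; since_lr = 0;
    } else {
      ++since_best; ++since_lr;
    }
    if (verbose)
      Rcout << "epoch " << epoch + 1 << " loss " << train_loss
            << " acc " << train_acc
            << (has_val ? " val_loss " + std::to_string(val_loss) : "")
            << " lr " << lr << "\n";
    if (since_lr >= lr_patience) { lr *= lr_factor; since_lr = 0; }
    if (since_best >= es_patience) break;
    Rcpp::checkUserInterrupt();
  }
  List hist = List::create(_["train_loss"] = h_tl, _["train_acc"] = h_ta,
                           _["val_loss"] = h_vl, _["val_acc"] = h_va,
                           _["lr"] = h_lr);
  return List::create(_["weights"] = weights_to_list(best),
                      _["history"] = hist,
                      _["best_epoch"] = best_epoch + 1,
                      _["best_monitor"] = best_mon);
}
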