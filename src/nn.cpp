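// Core forward/backward passes for the squiggle classifier:
// strided 1-D conv blocks (conv -> batch norm -> ReLU), a bidirectional GRU
// over the conv feature sequence, [max-pool; mean-pool; last fwd hidden;
// last bwd hidden] concatenation, and a two-layer dense head with sigmoid
// output.  Batch size is one sequence; batch-norm statistics in training
// mode are taken over the time axis (per channel), eval mode uses running
// statistics.  Gate layout in all 3H-row GRU matrices is [r; z; n]
// (two-bias convention).  No RNG anywhere in this file: initialization and
// sampling live on the R side so runs are reproducible from R's seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double BN_EPS = 1e-5;

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
static inline vec sigmoid_v(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// im2col for stride-s valid 1-D convolution: X is C x L, result (C*k) x T
// with rows kk*C + c holding X(c, t*s + kk).
static mat im2col(const mat& X, int k, int s) {
  const int C = X.n_rows, L = X.n_cols;
  const int T = (L - k) / s + 1;
  mat Xc(C * k, T);
  for (int kk = 0; kk < k; ++kk) {
    double* dst = Xc.memptr() + kk * C;  // row offset within each column
    const double* src = X.memptr();
    for (int t = 0; t < T; ++t)
      std::memcpy(dst + (size_t)t * C * k, src + (size_t)(t * s + kk) * C,
                  C * sizeof(double));
  }
  return Xc;
}

// scatter-add of im2col gradient back onto the input
static mat col2im(const mat& dXc, int C, int L, int k, int s) {
  const int T = dXc.n_cols;
  mat dX(C, L, fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    const double* src = dXc.memptr() + kk * C;
    double* dst = dX.memptr();
    for (int t = 0; t < T; ++t) {
      double* d = dst + (size_t)(t * s + kk) * C;
      const double* s2 = src + (size_t)t * C * k;
      for (int c = 0; c < C; ++c) d[c] += s2[c];
    }
  }
  return dX;
}

struct ConvCache {
  mat Xc;        // im2col of the layer input
  mat pre_bn;    // conv output (pre-normalization)
  mat xhat;      // normalized activations (training mode)
  vec mu, invstd;
  mat post;      // after BN + ReLU (layer output)
  int L_in;      // input length (for col2im)
};

struct GruCache {
  mat X;                 // input sequence C x T (in processing order)
  mat R, Z, N, H, GHN;   // per-timestep gates, hidden states, W_hn h + b_hn
};

// One GRU direction over X (C x T, already in processing order).
static GruCache gru_forward(const mat& X, const mat& Wi, const mat& Wh,
                            const vec& bi, const vec& bh) {
  const int H = Wh.n_cols, T = X.n_cols;
  GruCache c;
  c.X = X;
  c.R.set_size(H, T); c.Z.set_size(H, T); c.N.set_size(H, T);
  c.H.set_size(H, T); c.GHN.set_size(H, T);
  mat Gi = Wi * X;       // batched input projections
  Gi.each_col() += bi;
  vec h(H, fill::zeros), gh(3 * H);
  for (int t = 0; t < T; ++t) {
    gh = Wh * h;
    gh += bh;
    const double* gi = Gi.colptr(t);
    const double* g = gh.memptr();
    double* hp = h.memptr();
    double* Rc = c.R.colptr(t); double* Zc = c.Z.colptr(t);
    double* Nc = c.N.colptr(t); double* Hc = c.H.colptr(t);
    double* Gc = c.GHN.colptr(t);
    for (int i = 0; i < H; ++i) {
      double r = 1.0 / (1.0 + std::exp(-(gi[i] + g[i])));
      double z = 1.0 / (1.0 + std::exp(-(gi[H + i] + g[H + i])));
      double ghn = g[2 * H + i];
      double n = std::tanh(gi[2 * H + i] + r * ghn);
      hp[i] = (1.0 - z) * n + z * hp[i];
      Rc[i] = r; Zc[i] = z; Nc[i] = n; Gc[i] = ghn; Hc[i] = hp[i];
    }
  }
  return c;
}

// BPTT for one direction.  dH holds dL/dh_t per timestep (processing order).
// Returns dX and accumulates parameter gradients.  Weight gradients are
// assembled from the per-step preactivation gradients with two GEMMs.
static mat gru_backward(const GruCache& c, const mat& Wi, const mat& Wh,
                        const mat& dH,
                        mat& dWi, mat& dWh, vec& dbi, vec& dbh) {
  const int H = Wh.n_cols, T = c.X.n_cols;
  mat dGi(3 * H, T);   // input-side preactivation grads [r; z; n]
  mat dGh(3 * H, T);   // hidden-side preactivation grads [r; z; n % r]
  vec dh_next(H, fill::zeros), dgh(3 * H), wtd(H);
  const mat WhT = Wh.t();
  for (int t = T - 1; t >= 0; --t) {
    const double* r = c.R.colptr(t);
    const double* z = c.Z.colptr(t);
    const double* n = c.N.colptr(t);
    const double* ghn = c.GHN.colptr(t);
    const double* hprev = (t > 0) ? c.H.colptr(t - 1) : nullptr;
    const double* dHt = dH.colptr(t);
    double* dgi = dGi.colptr(t);
    double* dghp = dgh.memptr();
    double* dhn = dh_next.memptr();
    for (int i = 0; i < H; ++i) {
      double hp = hprev ? hprev[i] : 0.0;
      double dh = dHt[i] + dhn[i];
      double dz = dh * (hp - n[i]);
      double dn_pre = dh * (1.0 - z[i]) * (1.0 - n[i] * n[i]);
      double dr_pre = dn_pre * ghn[i] * r[i] * (1.0 - r[i]);
      double dz_pre = dz * z[i] * (1.0 - z[i]);
      dgi[i] = dr_pre;
      dgi[H + i] = dz_pre;
      dgi[2 * H + i] = dn_pre;
      dghp[i] = dr_pre;
      dghp[H + i] = dz_pre;
      dghp[2 * H + i] = dn_pre * r[i];
      dhn[i] = dh * z[i];  // completed below by WhT * dgh
    }
    dGh.col(t) = dgh;
    wtd = WhT * dgh;
    dh_next += wtd;
  }
  dWi = dGi * c.X.t();
  dbi = sum(dGi, 1);
  // h_prev sequence: zeros at t=0, then H columns 0..T-2
  mat Hprev(H, T, fill::zeros);
  if (T > 1) Hprev.cols(1, T - 1) = c.H.cols(0, T - 2);
  dWh = dGh * Hprev.t();
  dbh = sum(dGh, 1);
  return Wi.t() * dGi;  // dX
}

struct ForwardState {
  std::vector<ConvCache> conv;
  GruCache gf, gb;       // forward / backward direction caches
  mat O;                 // pooled-over sequence: (dirs*H) x T, original order
  vec v, a1, z1;
  double logit, prob;
  int n_conv;
  bool bidir, use_bn, training;
};

// Full forward pass.  x: normalized signal.  On training=true, batch-norm
// uses time-axis statistics and (if momentum > 0) updates bn_run in place
// semantics via the returned values; eval uses running statistics.
static ForwardState forward_pass(const vec& x, const List& params,
                                 const List& cfg, List& bn_run,
                                 bool training, double momentum) {
  ForwardState st;
  const ivec channels = Rcpp::as<ivec>(cfg["conv_channels"]);
  const int k = Rcpp::as<int>(cfg["kernel_size"]);
  const int s = Rcpp::as<int>(cfg["stride"]);
  st.use_bn = Rcpp::as<bool>(cfg["use_batch_norm"]);
  st.bidir = Rcpp::as<bool>(cfg["gru_bidirectional"]);
  st.training = training;
  st.n_conv = channels.n_elem;

  // minimum input length so every conv layer emits >= 1 feature
  int lmin = 1;
  for (int i = 0; i < st.n_conv; ++i) lmin = (lmin - 1) * s + k;
  if ((int)x.n_elem < lmin)
    Rcpp::stop("input signal has %d samples; the configured network needs at least %d",
               (int)x.n_elem, lmin);

  mat X = conv_to<mat>::from(x.t());  // 1 x L
  for (int i = 0; i < st.n_conv; ++i) {
    ConvCache cc;
    cc.L_in = X.n_cols;
    std::string tag = "conv" + std::to_string(i + 1);
    mat W = Rcpp::as<mat>(params[tag + "_W"]);
    vec b = Rcpp::as<vec>(params[tag + "_b"]);
    cc.Xc = im2col(X, k, s);
    mat Y = W * cc.Xc;
    Y.each_col() += b;
    cc.pre_bn = Y;
    if (st.use_bn) {
      std::string bt = "bn" + std::to_string(i + 1);
      vec gamma = Rcpp::as<vec>(params[bt + "_gamma"]);
      vec beta = Rcpp::as<vec>(params[bt + "_beta"]);
      const int T = Y.n_cols;
      if (training) {
        cc.mu = mean(Y, 1);
        mat Yc = Y;
        Yc.each_col() -= cc.mu;
        vec var_b = mean(square(Yc), 1);
        cc.invstd = 1.0 / sqrt(var_b + BN_EPS);
        Yc.each_col() %= cc.invstd;
        cc.xhat = Yc;
        if (momentum > 0) {
          vec rm = Rcpp::as<vec>(bn_run[bt + "_mean"]);
          vec rv = Rcpp::as<vec>(bn_run[bt + "_var"]);
          vec var_u = (T > 1) ? vec(var_b * ((double)T / (T - 1))) : var_b;
          bn_run[bt + "_mean"] = Rcpp::wrap((1.0 - momentum) * rm + momentum * cc.mu);
          bn_run[bt + "_var"] = Rcpp::wrap((1.0 - momentum) * rv + momentum * var_u);
        }
      } else {
        vec rm = Rcpp::as<vec>(bn_run[bt + "_mean"]);
        vec rv = Rcpp::as<vec>(bn_run[bt + "_var"]);
        cc.mu = rm;
        cc.invstd = 1.0 / sqrt(rv + BN_EPS);
        mat Yc = Y;
        Yc.each_col() -= rm;
        Yc.each_col() %= cc.invstd;
        cc.xhat = Yc;
      }
      Y = cc.xhat;
      Y.each_col() %= gamma;
      Y.each_col() += beta;
    }
    cc.post = clamp(Y, 0.0, datum::inf);  // ReLU
    X = cc.post;
    st.conv.push_back(std::move(cc));
  }

  const int T = X.n_cols;
  const mat Wi_f = Rcpp::as<mat>(params["gru_fwd_Wi"]);
  const mat Wh_f = Rcpp::as<mat>(params["gru_fwd_Wh"]);
  st.gf = gru_forward(X, Wi_f, Wh_f,
                      Rcpp::as<vec>(params["gru_fwd_bi"]),
                      Rcpp::as<vec>(params["gru_fwd_bh"]));
  const int H = Wh_f.n_cols;
  if (st.bidir) {
    mat Xr = fliplr(X);
    st.gb = gru_forward(Xr, Rcpp::as<mat>(params["gru_bwd_Wi"]),
                        Rcpp::as<mat>(params["gru_bwd_Wh"]),
                        Rcpp::as<vec>(params["gru_bwd_bi"]),
                        Rcpp::as<vec>(params["gru_bwd_bh"]));
    st.O = join_cols(st.gf.H, fliplr(st.gb.H));  // bwd states back in original order
  } else {
    st.O = st.gf.H;
  }

  vec maxv = max(st.O, 1);
  vec meanv = mean(st.O, 1);
  vec h_last_f = st.gf.H.col(T - 1);
  if (st.bidir) {
    vec h_last_b = st.gb.H.col(T - 1);  // = original position 1
    st.v = join_cols(join_cols(maxv, meanv), join_cols(h_last_f, h_last_b));
  } else {
    st.v = join_cols(join_cols(maxv, meanv), h_last_f);
  }
  (void)H;

  st.a1 = Rcpp::as<mat>(params["fc1_W"]) * st.v + Rcpp::as<vec>(params["fc1_b"]);
  st.z1 = clamp(st.a1, 0.0, datum::inf);
  st.logit = dot(Rcpp::as<mat>(params["fc2_W"]).row(0), st.z1) +
             Rcpp::as<vec>(params["fc2_b"])(0);
  st.prob = 1.0 / (1.0 + std::exp(-st.logit));
  return st;
}

// numerically stable BCE from the logit
static double bce_loss(double logit, double y) {
  double sp = (logit > 0) ? logit + std::log1p(std::exp(-logit))
                          : std::log1p(std::exp(logit));
  return sp - y * logit;
}

// [[Rcpp::export(name = ".nn_predict_cpp")]]
double nn_predict_cpp(const arma::vec& x, const List& params, const List& cfg,
                      List bn_run) {
  ForwardState st = forward_pass(x, params, cfg, bn_run, false, 0.0);
  return st.prob;
}

// [[Rcpp::export(name = ".nn_loss_cpp")]]
double nn_loss_cpp(const arma::vec& x, double y, const List& params,
                   const List& cfg, List bn_run, bool training) {
  ForwardState st = forward_pass(x, params, cfg, bn_run, training, 0.0);
  return bce_loss(st.logit, y);
}

// Forward + full backward in training mode.  Returns the probability, the
// BCE loss, the gradient of the loss w.r.t. every trainable parameter
// (named as in `params`), and updated batch-norm running statistics.
// [[Rcpp::export(name = ".nn_grad_cpp")]]
List nn_grad_cpp(const arma::vec& x, double y, const List& params,
                 const List& cfg, List bn_run, double bn_momentum) {
  List run = Rcpp::clone(bn_run);
  ForwardState st = forward_pass(x, params, cfg, run, true, bn_momentum);
  const int k = Rcpp::as<int>(cfg["kernel_size"]);
  const int s = Rcpp::as<int>(cfg["stride"]);
  const int T = st.O.n_cols;
  const int H = st.gf.H.n_rows;
  const int D = st.O.n_rows;  // dirs * H

  List g;

  // head
  double dlogit = st.prob - y;
  const mat fc2_W = Rcpp::as<mat>(params["fc2_W"]);
  g["fc2_W"] = Rcpp::wrap(mat(dlogit * st.z1.t()));
  g["fc2_b"] = Rcpp::wrap(vec{dlogit});
  vec dz1 = fc2_W.t() * dlogit;
  vec da1 = dz1 % conv_to<vec>::from(st.a1 > 0);
  const mat fc1_W = Rcpp::as<mat>(params["fc1_W"]);
  g["fc1_W"] = Rcpp::wrap(mat(da1 * st.v.t()));
  g["fc1_b"] = Rcpp::wrap(da1);
  vec dv = fc1_W.t() * da1;

  // un-concatenate: [max(D); mean(D); h_last_f(H); (h_last_b(H))]
  mat dO(D, T, fill::zeros);
  ucolvec amax = index_max(st.O, 1);
  for (int i = 0; i < D; ++i) dO(i, amax(i)) += dv(i);
  dO.each_col() += dv.subvec(D, 2 * D - 1) / (double)T;
  mat dH_f = dO.rows(0, H - 1);
  dH_f.col(T - 1) += dv.subvec(2 * D, 2 * D + H - 1);

  const mat Wi_f = Rcpp::as<mat>(params["gru_fwd_Wi"]);
  const mat Wh_f = Rcpp::as<mat>(params["gru_fwd_Wh"]);
  mat dWi_f(size(Wi_f)), dWh_f(size(Wh_f));
  vec dbi_f(3 * H), dbh_f(3 * H);
  mat dX = gru_backward(st.gf, Wi_f, Wh_f, dH_f, dWi_f, dWh_f, dbi_f, dbh_f);
  g["gru_fwd_Wi"] = Rcpp::wrap(dWi_f); g["gru_fwd_Wh"] = Rcpp::wrap(dWh_f);
  g["gru_fwd_bi"] = Rcpp::wrap(dbi_f); g["gru_fwd_bh"] = Rcpp::wrap(dbh_f);

  if (st.bidir) {
    mat dH_b = fliplr(mat(dO.rows(H, 2 * H - 1)));  // to processing order
    dH_b.col(T - 1) += dv.subvec(2 * D + H, 2 * D + 2 * H - 1);
    const mat Wi_b = Rcpp::as<mat>(params["gru_bwd_Wi"]);
    const mat Wh_b = Rcpp::as<mat>(params["gru_bwd_Wh"]);
    mat dWi_b(size(Wi_b)), dWh_b(size(Wh_b));
    vec dbi_b(3 * H), dbh_b(3 * H);
    mat dXb = gru_backward(st.gb, Wi_b, Wh_b, dH_b, dWi_b, dWh_b, dbi_b, dbh_b);
    g["gru_bwd_Wi"] = Rcpp::wrap(dWi_b); g["gru_bwd_Wh"] = Rcpp::wrap(dWh_b);
    g["gru_bwd_bi"] = Rcpp::wrap(dbi_b); g["gru_bwd_bh"] = Rcpp::wrap(dbh_b);
    dX += fliplr(dXb);
  }

  // conv stack, last to first
  for (int i = st.n_conv - 1; i >= 0; --i) {
    const ConvCache& cc = st.conv[i];
    std::string tag = "conv" + std::to_string(i + 1);
    mat dOut = dX % conv_to<mat>::from(cc.post > 0);  // ReLU
    if (st.use_bn) {
      std::string bt = "bn" + std::to_string(i + 1);
      vec gamma = Rcpp::as<vec>(params[bt + "_gamma"]);
      g[bt + "_gamma"] = Rcpp::wrap(vec(sum(dOut % cc.xhat, 1)));
      g[bt + "_beta"] = Rcpp::wrap(vec(sum(dOut, 1)));
      const double Tn = (double)dOut.n_cols;
      // dL/dY for per-channel statistics over the time axis
      vec m1 = mean(dOut, 1);
      vec m2 = mean(dOut % cc.xhat, 1);
      mat dY = dOut;
      dY.each_col() -= m1;
      mat xm = cc.xhat;
      xm.each_col() %= m2;
      dY -= xm;
      dY.each_col() %= (gamma % cc.invstd);
      (void)Tn;
      dOut = dY;
    }
    const mat W = Rcpp::as<mat>(params[tag + "_W"]);
    g[tag + "_W"] = Rcpp::wrap(mat(dOut * cc.Xc.t()));
    g[tag + "_b"] = Rcpp::wrap(vec(sum(dOut, 1)));
    mat dXc = W.t() * dOut;
    int C_in = (i == 0) ? 1 : (int)st.conv[i - 1].post.n_rows;
    dX = col2im(dXc, C_in, cc.L_in, k, s);
  }

  return List::create(Named("prob") = st.prob,
                      Named("loss") = bce_loss(st.logit, y),
                      Named("grads") = g,
                      Named("bn_run") = run);
}
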