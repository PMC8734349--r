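// Fully connected network for per-pixel T1 regression.
// Single precision throughout: training at 32-bit float matches the
// checkpoint format and halves the memory traffic of the dense layers.
// The batch loop preallocates all activations and fuses the Adam update
// into one pass per parameter block to keep the loop GEMM-bound.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

// Layer weights are held as (d_out x d_in) so a forward step is one GEMM.
struct Net {
  std::vector<arma::fmat> W;
  std::vector<arma::fvec> b;
  float slope;  // leaky rectifier negative slope
};

static Net net_from_r(List weights, List biases, double slope) {
  Net net;
  net.slope = (float)slope;
  for (int i = 0; i < weights.size(); ++i) {
    arma::mat Wd = as<arma::mat>(weights[i]);     // d_in x d_out (R layout)
    arma::vec bd = as<arma::vec>(biases[i]);
    net.W.push_back(arma::conv_to<arma::fmat>::from(Wd.t()));
    net.b.push_back(arma::conv_to<arma::fvec>::from(bd));
  }
  return net;
}

static List net_to_r(const Net& net) {
  List W(net.W.size()), b(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    arma::mat Wd = arma::conv_to<arma::mat>::from(net.W[i].t());
    arma::vec bd = arma::conv_to<arma::vec>::from(net.b[i]);
    W[i] = Wd; b[i] = bd;
  }
  return List::create(_["weights"] = W, _["biases"] = b);
}

static inline void leaky_fwd(arma::fmat& A, float slope) {
  float* p = A.memptr();
  const arma::uword n = A.n_elem;
  for (arma::uword k = 0; k < n; ++k)
    if (p[k] < 0.0f) p[k] *= slope;
}

// plain forward pass for evaluation (chunked by the caller)
static arma::frowvec forward_eval(const Net& net, const arma::fmat& X) {
  arma::fmat A = X;
  const size_t L = net.W.size();
  for (size_t i = 0; i < L; ++i) {
    arma::fmat Z = net.W[i] * A;
    Z.each_col() += net.b[i];
    if (i + 1 < L) leaky_fwd(Z, net.slope);
    A = std::move(Z);
  }
  return A.row(0);
}

// [[Rcpp::export(name = ".mlp_forward")]]
NumericVector mlp_forward_cpp(List weights, List biases, NumericMatrix X,
                              double slope) {
  Net net = net_from_r(weights, biases, slope);
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);  // n x d
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(Xd.t());
  const arma::uword n = Xf.n_cols, chunk = 8192;
  NumericVector res(n);
  for (arma::uword s = 0; s < n; s += chunk) {
    arma::uword e = std::min(n, s + chunk) - 1;
    arma::frowvec out = forward_eval(net, Xf.cols(s, e));
    for (arma::uword i = 0; i <= e - s; ++i) res[s + i] = out[i];
  }
  return res;
}

static double range_mae(const arma::frowvec& pred, const arma::frowvec& y,
                        float lo, float hi) {
  double s = 0; arma::uword n = 0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    if (y[i] >= lo && y[i] <= hi) { s += std::fabs((double)pred[i] - y[i]); ++n; }
  return n ? s / n : NA_REAL;
}

// fused Adam step on one parameter block (in place, no temporaries)
static inline void adam_update(float* w, const float* g, float* m, float* v,
                               arma::uword n, float wd, float lr,
                               float c1, float c2) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  for (arma::uword k = 0; k < n; ++k) {
    float gk = g[k] + wd * w[k];
    m[k] = b1 * m[k] + (1.0f - b1) * gk;
    v[k] = b2 * v[k] + (1.0f - b2) * gk * gk;
    w[k] -= lr * (m[k] / c1) / (std::sqrt(v[k] / c2) + eps);
  }
}

// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train_cpp(NumericMatrix X, NumericVector y,
                   NumericMatrix Xval, NumericVector yval,
                   List weights, List biases, double slope,
                   double lr, double weight_decay, int batch_size,
                   int max_epochs, int patience, int seed,
                   double lr_decay, int lr_decay_every,
                   NumericMatrix monitor_ranges, bool verbose) {
  Net net = net_from_r(weights, biases, slope);
  const size_t L = net.W.size();
  const float slp = net.slope;

  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::fmat Xtr = arma::conv_to<arma::fmat>::from(Xd.t());  // d x n
  arma::frowvec ytr = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(y));
  arma::mat Xvd(Xval.begin(), Xval.nrow(), Xval.ncol(), false);
  arma::fmat Xv = arma::conv_to<arma::fmat>::from(Xvd.t());
  arma::frowvec yv = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(yval));

  const arma::uword n = Xtr.n_cols;
  const arma::uword B = (arma::uword)batch_size;

  // Adam state
  std::vector<arma::fmat> mW(L), vW(L), gW(L);
  std::vector<arma::fvec> mb(L), vb(L), gb(L);
  for (size_t i = 0; i < L; ++i) {
    mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols); vW[i] = mW[i]; gW[i] = mW[i];
    mb[i].zeros(net.b[i].n_elem); vb[i] = mb[i]; gb[i] = mb[i];
  }
  long step = 0;

  // preallocated batch workspace: A[i] holds the input of layer i,
  // Z[i] its output; delta[i] the gradient w.r.t. layer i's pre-activation
  std::vector<arma::fmat> A(L + 1), delta(L);
  arma::fmat Xb(Xtr.n_rows, B);
  arma::frowvec yb(B);

  std::mt19937 rng((unsigned)seed);
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  int nranges = monitor_ranges.nrow();
  arma::mat history(max_epochs, 4 + nranges);
  double best_val = R_PosInf;
  int best_epoch = -1, epochs_run = 0;
  Net best = net;

  for (int ep = 0; ep < max_epochs; ++ep) {
    float cur_lr = (float)(lr * std::pow(lr_decay,
                    lr_decay_every > 0 ? ep / lr_decay_every : 0));
    std::shuffle(idx.begin(), idx.end(), rng);
    double train_abs = 0; arma::uword train_n = 0;
    for (arma::uword s = 0; s < n; s += B) {
      const arma::uword bn = std::min<arma::uword>(B, n - s);
      Xb.set_size(Xtr.n_rows, bn); yb.set_size(bn);
      for (arma::uword j = 0; j < bn; ++j) {
        Xb.col(j) = Xtr.col(idx[s + j]);
        yb[j] = ytr[idx[s + j]];
      }
      // forward
      A[0] = Xb;
      for (size_t i = 0; i < L; ++i) {
        A[i + 1] = net.W[i] * A[i];
        A[i + 1].each_col() += net.b[i];
        if (i + 1 < L) leaky_fwd(A[i + 1], slp);
      }
      // MAE subgradient at the linear output
      delta[L - 1].set_size(1, bn);
      {
        const float* pr = A[L].memptr();
        float* dl = delta[L - 1].memptr();
        const float inv = 1.0f / (float)bn;
        for (arma::uword j = 0; j < bn; ++j) {
          float e = pr[j] - yb[j];
          train_abs += std::fabs((double)e);
          dl[j] = (e > 0.0f ? inv : (e < 0.0f ? -inv : 0.0f));
        }
        train_n += bn;
      }
      // backward: delta[i] = dL/dZ_i; A[i] is layer i's input
      for (int i = (int)L - 1; i > 0; --i) {
        delta[i - 1] = net.W[i].t() * delta[i];
        // leaky derivative via the post-activation sign (slope > 0)
        const float* zi = A[i].memptr();
        float* dl = delta[i - 1].memptr();
        const arma::uword ne = delta[i - 1].n_elem;
        for (arma::uword k = 0; k < ne; ++k)
          if (zi[k] < 0.0f) dl[k] *= slp;
      }
      ++step;
      const float c1 = 1.0f - std::pow(0.9f, (float)step);
      const float c2 = 1.0f - std::pow(0.999f, (float)step);
      for (size_t i = 0; i < L; ++i) {
        gW[i] = delta[i] * A[i].t();
        gb[i] = arma::sum(delta[i], 1);
        adam_update(net.W[i].memptr(), gW[i].memptr(), mW[i].memptr(),
                    vW[i].memptr(), net.W[i].n_elem, (float)weight_decay,
                    cur_lr, c1, c2);
        adam_update(net.b[i].memptr(), gb[i].memptr(), mb[i].memptr(),
                    vb[i].memptr(), net.b[i].n_elem, 0.0f, cur_lr, c1, c2);
      }
    }
    // validation pass
    arma::frowvec pv(yv.n_elem);
    const arma::uword chunk = 8192;
    for (arma::uword s = 0; s < Xv.n_cols; s += chunk) {
      arma::uword e = std::min(Xv.n_cols, s + chunk) - 1;
      pv.subvec(s, e) = forward_eval(net, Xv.cols(s, e));
    }
    double val_mae = arma::accu(arma::abs(pv - yv)) / yv.n_elem;
    history(ep, 0) = ep + 1;
    history(ep, 1) = train_abs / train_n;
    history(ep, 2) = val_mae;
    for (int r = 0; r < nranges; ++r)
      history(ep, 3 + r) = range_mae(pv, yv, (float)monitor_ranges(r, 0),
                                     (float)monitor_ranges(r, 1));
    history(ep, 3 + nranges) = cur_lr;
    epochs_run = ep + 1;
    if (val_mae < best_val) {
      best_val = val_mae;
      best_epoch = ep;
      best = net;
    }
    if (verbose)
      Rprintf("epoch %d: train MAE %.2f, val MAE %.2f (best %.2f @ %d)\n",
              ep + 1, history(ep, 1), val_mae, best_val, best_epoch + 1);
    Rcpp::checkUserInterrupt();
    if (ep - best_epoch >= patience) break;
  }

  List out = net_to_r(best);
  out["history"] = wrap(history.rows(0, epochs_run - 1));
  out["best_epoch"] = best_epoch + 1;
  out["best_val_mae"] = best_val;
  out["epochs_run"] = epochs_run;
  return out;
}
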