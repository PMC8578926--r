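// Minimal 1-D convolutional regression engine.
//
// Four conv1d stages (kernel 5, stride 2, padding 2), each followed by ReLU,
// then one max-pool (kernel 3, stride 2), flatten, and a single affine output
// unit.  Trained with Adam on the MSE loss; per-epoch validation
// checkpointing returns the weights of the epoch with the lowest validation
// MSE.  Everything is single-threaded and seeded, so runs are reproducible.
//
// Input tensors are passed from R as numeric arrays with dim (L, C, n):
// slice i is sample i with one channel per column.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvSpec {
  int c_in, c_out, l_in, l_out, kernel, stride, pad;
};

int out_len(int l_in, int k, int s, int p) {
  return (l_in + 2 * p - k) / s + 1;
}

// Build im2col matrix for a batch: result (c_in*kernel, l_out*nb).
// F has layout (c_in, l_in*nb), sample s occupying columns [s*l_in, (s+1)*l_in).
arma::mat im2col(const arma::mat& F, const ConvSpec& cs, int nb) {
  arma::mat M(cs.c_in * cs.kernel, cs.l_out * nb, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < cs.l_out; ++j) {
      const int col = s * cs.l_out + j;
      const int start = j * cs.stride - cs.pad;
      for (int t = 0; t < cs.kernel; ++t) {
        const int src = start + t;
        if (src < 0 || src >= cs.l_in) continue;
        for (int c = 0; c < cs.c_in; ++c)
          M(c * cs.kernel + t, col) = F(c, s * cs.l_in + src);
      }
    }
  }
  return M;
}

// Scatter-add of col gradients back onto the input feature map.
void col2im_add(arma::mat& dF, const arma::mat& dM, const ConvSpec& cs, int nb) {
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < cs.l_out; ++j) {
      const int col = s * cs.l_out + j;
      const int start = j * cs.stride - cs.pad;
      for (int t = 0; t < cs.kernel; ++t) {
        const int src = start + t;
        if (src < 0 || src >= cs.l_in) continue;
        for (int c = 0; c < cs.c_in; ++c)
          dF(c, s * cs.l_in + src) += dM(c * cs.kernel + t, col);
      }
    }
  }
}

struct Params {
  std::vector<arma::mat> W;   // conv weights (c_out, c_in*kernel)
  std::vector<arma::vec> b;   // conv biases
  arma::rowvec Wh;            // head weights (1, flat)
  double bh;                  // head bias
};

Params params_from_list(const List& p) {
  Params out;
  List Ws = p["conv_w"], bs = p["conv_b"];
  for (int i = 0; i < Ws.size(); ++i) {
    out.W.push_back(as<arma::mat>(Ws[i]));
    out.b.push_back(as<arma::vec>(bs[i]));
  }
  out.Wh = as<arma::rowvec>(p["head_w"]);
  out.bh = as<double>(p["head_b"]);
  return out;
}

List params_to_list(const Params& p) {
  List Ws(p.W.size()), bs(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    Ws[i] = p.W[i];
    bs[i] = p.b[i];
  }
  return List::create(Named("conv_w") = Ws, Named("conv_b") = bs,
                      Named("head_w") = p.Wh, Named("head_b") = p.bh);
}

std::vector<ConvSpec> make_specs(const Params& p, int l0, int kernel,
                                 int stride, int pad) {
  std::vector<ConvSpec> specs;
  int l = l0;
  for (size_t i = 0; i < p.W.size(); ++i) {
    ConvSpec cs;
    cs.c_in = p.W[i].n_cols / kernel;
    cs.c_out = p.W[i].n_rows;
    cs.kernel = kernel;
    cs.stride = stride;
    cs.pad = pad;
    cs.l_in = l;
    cs.l_out = out_len(l, kernel, stride, pad);
    specs.push_back(cs);
    l = cs.l_out;
  }
  return specs;
}

struct Cache {
  std::vector<arma::mat> F;    // feature maps, F[0] = input
  std::vector<arma::mat> M;    // im2col matrices
  std::vector<arma::mat> Z;    // pre-activations
  arma::mat pooled;            // (c4, lp*nb)
  arma::umat pool_arg;         // argmax positions within [0, l4)
  arma::mat flat;              // (c4*lp, nb)
};

const int POOL_K = 3, POOL_S = 2;

arma::rowvec forward(const Params& p, const std::vector<ConvSpec>& specs,
                     const arma::mat& X0, int nb, Cache* cache) {
  arma::mat F = X0;
  Cache local;
  Cache& cc = cache ? *cache : local;
  cc.F.clear(); cc.M.clear(); cc.Z.clear();
  for (size_t i = 0; i < p.W.size(); ++i) {
    const ConvSpec& cs = specs[i];
    arma::mat M = im2col(F, cs, nb);
    arma::mat Z = p.W[i] * M;
    Z.each_col() += p.b[i];
    if (cache) { cc.F.push_back(F); cc.M.push_back(std::move(M)); cc.Z.push_back(Z); }
    F = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
  }
  if (cache) cc.F.push_back(F);

  const ConvSpec& last = specs.back();
  const int c4 = last.c_out, l4 = last.l_out;
  const int lp = (l4 - POOL_K) / POOL_S + 1;
  arma::mat pooled(c4, lp * nb);
  arma::umat parg(c4, lp * nb);
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < lp; ++j) {
      const int col = s * lp + j;
      const int start = j * POOL_S;
      for (int c = 0; c < c4; ++c) {
        double best = F(c, s * l4 + start);
        int barg = start;
        for (int t = 1; t < POOL_K; ++t) {
          const double val = F(c, s * l4 + start + t);
          if (val > best) { best = val; barg = start + t; }
        }
        pooled(c, col) = best;
        parg(c, col) = barg;
      }
    }
  }
  arma::mat flat(c4 * lp, nb);
  for (int s = 0; s < nb; ++s)
    flat.col(s) = arma::vectorise(pooled.cols(s * lp, (s + 1) * lp - 1));
  arma::rowvec yhat = p.Wh * flat + p.bh;
  if (cache) {
    cc.pooled = std::move(pooled);
    cc.pool_arg = std::move(parg);
    cc.flat = std::move(flat);
  }
  return yhat;
}

void backward(const Params& p, const std::vector<ConvSpec>& specs,
              const Cache& cc, const arma::rowvec& dy, int nb, Params& grad) {
  const ConvSpec& last = specs.back();
  const int c4 = last.c_out, l4 = last.l_out;
  const int lp = (l4 - POOL_K) / POOL_S + 1;

  grad.Wh = dy * cc.flat.t();
  grad.bh = arma::accu(dy);
  arma::mat dflat = p.Wh.t() * dy;  // (c4*lp, nb)

  arma::mat dF(c4, l4 * nb, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < lp; ++j) {
      const int col = s * lp + j;
      for (int c = 0; c < c4; ++c)
        dF(c, s * l4 + cc.pool_arg(c, col)) += dflat(c + c4 * j, s);
    }
  }
  for (int i = static_cast<int>(p.W.size()) - 1; i >= 0; --i) {
    const ConvSpec& cs = specs[i];
    arma::mat dZ = dF % (cc.Z[i] > 0);
    grad.W[i] = dZ * cc.M[i].t();
    grad.b[i] = arma::sum(dZ, 1);
    if (i > 0) {
      arma::mat dM = p.W[i].t() * dZ;
      dF.zeros(cs.c_in, cs.l_in * nb);
      col2im_add(dF, dM, cs, nb);
    }
  }
}

// gather batch columns: X cube (L, C, n) -> F0 (C, L*nb)
arma::mat gather_batch(const arma::cube& X, const std::vector<int>& idx) {
  const int L = X.n_rows, C = X.n_cols, nb = idx.size();
  arma::mat F(C, L * nb);
  for (int s = 0; s < nb; ++s)
    F.cols(s * L, (s + 1) * L - 1) = X.slice(idx[s]).t();
  return F;
}

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::vec> mb, vb;
  arma::rowvec mWh, vWh;
  double mbh = 0.0, vbh = 0.0;
  long t = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;

  explicit Adam(const Params& p, double lr_) : lr(lr_) {
    for (size_t i = 0; i < p.W.size(); ++i) {
      mW.push_back(arma::zeros<arma::mat>(arma::size(p.W[i])));
      vW.push_back(arma::zeros<arma::mat>(arma::size(p.W[i])));
      mb.push_back(arma::zeros<arma::vec>(p.b[i].n_elem));
      vb.push_back(arma::zeros<arma::vec>(p.b[i].n_elem));
    }
    mWh = arma::zeros<arma::rowvec>(p.Wh.n_elem);
    vWh = arma::zeros<arma::rowvec>(p.Wh.n_elem);
  }

  template <typename T>
  void upd(T& w, T& m, T& v, const T& g, double a1, double a2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    w -= lr * (m / a1) / (arma::sqrt(v / a2) + eps);
  }

  void step(Params& p, const Params& g) {
    ++t;
    const double a1 = 1 - std::pow(b1, t), a2 = 1 - std::pow(b2, t);
    for (size_t i = 0; i < p.W.size(); ++i) {
      upd(p.W[i], mW[i], vW[i], g.W[i], a1, a2);
      upd(p.b[i], mb[i], vb[i], g.b[i], a1, a2);
    }
    upd(p.Wh, mWh, vWh, g.Wh, a1, a2);
    double m1 = mbh = b1 * mbh + (1 - b1) * g.bh;
    double v1 = vbh = b2 * vbh + (1 - b2) * g.bh * g.bh;
    p.bh -= lr * (m1 / a1) / (std::sqrt(v1 / a2) + eps);
  }
};

double mse_on(const Params& p, const std::vector<ConvSpec>& specs,
              const arma::cube& X, const arma::vec& y, int chunk = 512) {
  const int n = X.n_slices;
  double sse = 0.0;
  for (int start = 0; start < n; start += chunk) {
    const int nb = std::min(chunk, n - start);
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = start + i;
    arma::mat F0 = gather_batch(X, idx);
    arma::rowvec yh = forward(p, specs, F0, nb, nullptr);
    for (int i = 0; i < nb; ++i) {
      const double d = yh[i] - y[start + i];
      sse += d * d;
    }
  }
  return sse / n;
}

} // namespace

// [[Rcpp::export]]
List cnn_init_cpp(int in_channels, IntegerVector out_channels, int kernel,
                  int input_len, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  Params p;
  int c_in = in_channels, l = input_len;
  for (int i = 0; i < out_channels.size(); ++i) {
    const int c_out = out_channels[i];
    const double bound = 1.0 / std::sqrt(static_cast<double>(c_in * kernel));
    std::uniform_real_distribution<double> U(-bound, bound);
    arma::mat W(c_out, c_in * kernel);
    arma::vec b(c_out);
    for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = U(rng);
    // small positive conv biases keep ReLU units initially active
    // (inputs are min-max normalized and non-negative)
    for (arma::uword j = 0; j < b.n_elem; ++j) b(j) = 0.05 * std::fabs(U(rng)) + 0.01;
    p.W.push_back(W);
    p.b.push_back(b);
    l = out_len(l, kernel, 2, 2);
    c_in = c_out;
  }
  const int lp = (l - POOL_K) / POOL_S + 1;
  if (lp <= 0) stop("input too short: flatten width would be non-positive");
  const int flat = c_in * lp;
  const double bound = 1.0 / std::sqrt(static_cast<double>(flat));
  std::uniform_real_distribution<double> U(-bound, bound);
  p.Wh = arma::rowvec(flat);
  for (int j = 0; j < flat; ++j) p.Wh(j) = U(rng);
  p.bh = U(rng);
  List out = params_to_list(p);
  out["flat_width"] = flat;
  return out;
}

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(List params, NumericVector Xr, int kernel,
                              int stride, int pad) {
  IntegerVector dims = Xr.attr("dim");
  arma::cube X(Xr.begin(), dims[0], dims[1], dims[2], false);
  Params p = params_from_list(params);
  std::vector<ConvSpec> specs = make_specs(p, dims[0], kernel, stride, pad);
  const int n = X.n_slices;
  NumericVector out(n);
  const int chunk = 512;
  for (int start = 0; start < n; start += chunk) {
    const int nb = std::min(chunk, n - start);
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = start + i;
    arma::mat F0 = gather_batch(X, idx);
    arma::rowvec yh = forward(p, specs, F0, nb, nullptr);
    for (int i = 0; i < nb; ++i) out[start + i] = yh[i];
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, NumericVector Xr, NumericVector yr,
                   NumericVector Xvr, NumericVector yvr, int batch_size,
                   int max_epochs, double lr, int seed, int kernel, int stride,
                   int pad) {
  IntegerVector dims = Xr.attr("dim"), dimsv = Xvr.attr("dim");
  arma::cube X(Xr.begin(), dims[0], dims[1], dims[2], false);
  arma::cube Xv(Xvr.begin(), dimsv[0], dimsv[1], dimsv[2], false);
  arma::vec y(yr.begin(), yr.size(), false);
  arma::vec yv(yvr.begin(), yvr.size(), false);

  Params p = params_from_list(params);
  std::vector<ConvSpec> specs = make_specs(p, dims[0], kernel, stride, pad);
  Params grad = p;  // shape template
  Adam adam(p, lr);
  std::mt19937 rng(static_cast<unsigned>(seed));

  const int n = X.n_slices;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector val_hist(max_epochs), train_hist(max_epochs);
  Params best = p;
  double best_val = R_PosInf;
  int best_epoch = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double train_sse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int nb = std::min(batch_size, n - start);
      std::vector<int> idx(order.begin() + start, order.begin() + start + nb);
      arma::mat F0 = gather_batch(X, idx);
      Cache cc;
      arma::rowvec yh = forward(p, specs, F0, nb, &cc);
      arma::rowvec dy(nb);
      for (int i = 0; i < nb; ++i) {
        const double d = yh[i] - y[idx[i]];
        train_sse += d * d;
        dy[i] = 2.0 * d / nb;
      }
      backward(p, specs, cc, dy, nb, grad);
      adam.step(p, grad);
    }
    const double train_mse = train_sse / n;
    const double val_mse = mse_on(p, specs, Xv, yv);
    if (!std::isfinite(train_mse) || !std::isfinite(val_mse))
      stop("training loss became non-finite (seed %d, batch %d, epoch %d)",
           seed, batch_size, epoch + 1);
    train_hist[epoch] = train_mse;
    val_hist[epoch] = val_mse;
    if (val_mse < best_val) {
      best_val = val_mse;
      best = p;
      best_epoch = epoch + 1;
    }
  }
  List out = params_to_list(best);
  return List::create(Named("params") = out, Named("best_epoch") = best_epoch,
                      Named("best_val_mse") = best_val,
                      Named("val_history") = val_hist,
                      Named("train_history") = train_hist);
}
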