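// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Training loop of the two-layer GCN, compiled for speed. The algorithm is
// identical to the R reference engine (gcn_step_grads / adam_step): one
// Adam update per shuffled batch of labeled training nodes, cross-entropy
// on the batch, full-graph forward passes, dropout on the second hidden
// state, early stopping on the monitor loss with patience, and restoring
// the best-monitor-loss parameters. All randomness (batch order, dropout
// masks) is drawn from R's RNG, so a seed set on the R side reproduces the
// run exactly.

static arma::mat softmax_rows(const arma::mat &S) {
  arma::mat E = arma::exp(S.each_col() - arma::max(S, 1));
  E.each_col() /= arma::sum(E, 1);
  return E;
}

static double xent(const arma::mat &Z, const arma::mat &Y,
                   const arma::uvec &idx) {
  arma::mat p = arma::sum(Z.rows(idx) % Y.rows(idx), 1);
  return -arma::mean(arma::mean(arma::log(p + 1e-12)));
}

static double acc(const arma::mat &Z, const arma::ivec &lab,
                  const arma::uvec &idx) {
  arma::uvec pred = arma::index_max(Z.rows(idx), 1);
  arma::ivec l = lab.elem(idx);
  int ok = 0;
  for (arma::uword t = 0; t < idx.n_elem; ++t)
    if ((int)pred[t] == l[t]) ++ok;
  return (double)ok / idx.n_elem;
}

struct AdamVar {
  arma::mat m, v;
  AdamVar(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                          v(r, c, arma::fill::zeros) {}
};

static void adam_update(arma::mat &w, AdamVar &s, const arma::mat &g,
                        double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.m = b1 * s.m + (1 - b1) * g;
  s.v = b2 * s.v + (1 - b2) * (g % g);
  arma::mat mhat = s.m / (1 - std::pow(b1, t));
  arma::mat vhat = s.v / (1 - std::pow(b2, t));
  w -= lr * mhat / (arma::sqrt(vhat) + eps);
}

// [[Rcpp::export]]
List gcn_train_loop(const arma::sp_mat &P, const arma::mat &A1x,
                    const arma::mat &Y, const arma::ivec &labels,
                    const arma::uvec &train_idx0, const arma::uvec &mask_idx0,
                    arma::mat W0, arma::mat W1, arma::mat Wfc,
                    double lr, int batch_size, int max_epochs, int patience,
                    double dropout) {
  arma::uvec train_idx = train_idx0 - 1; // R 1-based -> 0-based
  arma::uvec mask_idx = mask_idx0;
  bool has_mask = mask_idx.n_elem > 0;
  if (has_mask) mask_idx -= 1;
  const arma::uword n = A1x.n_rows;
  const double keep = 1.0 - dropout;

  AdamVar s0(W0.n_rows, W0.n_cols), s1(W1.n_rows, W1.n_cols),
      sf(Wfc.n_rows, Wfc.n_cols);
  int t_adam = 0;

  arma::mat bW0 = W0, bW1 = W1, bWfc = Wfc;
  double best_loss = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0, epoch = 0;
  std::vector<double> h_tl, h_ta, h_ml, h_ma;
  arma::uvec ord = train_idx;
  const int nb = train_idx.n_elem;
  const int bs = batch_size > 0 ? std::min(batch_size, nb) : nb;

  while (epoch < max_epochs) {
    ++epoch;
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = nb - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int start = 0; start < nb; start += bs) {
      int stop = std::min(start + bs, nb) - 1;
      arma::uvec batch = ord.subvec(start, stop);
      // forward
      arma::mat H1 = A1x * W0;
      H1.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat A2 = P * H1;
      arma::mat H2 = A2 * W1;
      H2.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat H2d = H2;
      arma::mat M;
      if (dropout > 0) {
        M.set_size(H2.n_rows, H2.n_cols);
        for (arma::uword c = 0; c < M.n_cols; ++c)
          for (arma::uword r = 0; r < M.n_rows; ++r)
            M(r, c) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        H2d %= M;
      }
      arma::mat Z = softmax_rows(H2d * Wfc);
      // backward (cross-entropy restricted to the batch)
      arma::mat dS(n, Z.n_cols, arma::fill::zeros);
      dS.rows(batch) = (Z.rows(batch) - Y.rows(batch)) / (double)batch.n_elem;
      arma::mat dWfc = H2d.t() * dS;
      arma::mat dH2 = dS * Wfc.t();
      if (dropout > 0) dH2 %= M;
      arma::mat dZ2 = dH2 % (H2 > 0);
      arma::mat dW1 = A2.t() * dZ2;
      arma::mat dH1 = P * (dZ2 * W1.t());
      arma::mat dZ1 = dH1 % (H1 > 0);
      arma::mat dW0 = A1x.t() * dZ1;
      ++t_adam;
      adam_update(W0, s0, dW0, lr, t_adam);
      adam_update(W1, s1, dW1, lr, t_adam);
      adam_update(Wfc, sf, dWfc, lr, t_adam);
    }
    // end-of-epoch evaluation (dropout off)
    arma::mat H1 = A1x * W0;
    H1.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat H2 = (P * H1) * W1;
    H2.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat Z = softmax_rows(H2 * Wfc);
    double tl = xent(Z, Y, train_idx), ta = acc(Z, labels, train_idx);
    double ml = NA_REAL, ma = NA_REAL;
    double monitor = tl;
    if (has_mask) {
      ml = xent(Z, Y, mask_idx);
      ma = acc(Z, labels, mask_idx);
      monitor = ml;
    }
    h_tl.push_back(tl); h_ta.push_back(ta);
    h_ml.push_back(ml); h_ma.push_back(ma);
    if (monitor < best_loss - 1e-6) {
      best_loss = monitor;
      bW0 = W0; bW1 = W1; bWfc = Wfc;
      best_epoch = epoch;
      wait = 0;
    } else if (has_mask) {
      if (++wait >= patience) break;
    }
  }

  bool use_best = has_mask && max_epochs > 0;
  return List::create(
      _["W0"] = use_best ? bW0 : W0, _["W1"] = use_best ? bW1 : W1,
      _["W_fc"] = use_best ? bWfc : Wfc,
      _["train_loss"] = h_tl, _["train_acc"] = h_ta,
      _["mask_loss"] = h_ml, _["mask_acc"] = h_ma,
      _["epoch_stopped"] = epoch,
      _["best_epoch"] = has_mask ? best_epoch : epoch);
}
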