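// Bidirectional LSTM sequence classifier: forward pass, per-timestep
// softmax, and BPTT training with per-sequence SGD + momentum.
//
// Weight layout (list from R):
//   Wf (4H x D), Uf (4H x H), bf (4H)   forward-direction cell
//   Wb (4H x D), Ub (4H x H), bb (4H)   backward-direction cell
//   V  (C x 2H), co (C)                 shared output layer
// Gate row blocks within 4H: [input; forget; cell; output].
//
// Sequences arrive as D x T matrices (one column per timestep).
// The loss is the cross-entropy of the per-timestep softmax against the
// sequence label, summed over timesteps (one term per output, matching a
// per-timestep target replication of the sequence class).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  mat i, f, g, o, c, tc, h; // H x T, indexed by original time
};

struct Weights {
  mat Wf, Uf, Wb, Ub, V;
  vec bf, bb, co;
};

Weights unpack(const Rcpp::List& w) {
  Weights out;
  out.Wf = Rcpp::as<mat>(w["Wf"]); out.Uf = Rcpp::as<mat>(w["Uf"]);
  out.bf = Rcpp::as<vec>(w["bf"]);
  out.Wb = Rcpp::as<mat>(w["Wb"]); out.Ub = Rcpp::as<mat>(w["Ub"]);
  out.bb = Rcpp::as<vec>(w["bb"]);
  out.V  = Rcpp::as<mat>(w["V"]);  out.co = Rcpp::as<vec>(w["co"]);
  return out;
}

Rcpp::List pack(const Weights& w) {
  return Rcpp::List::create(
    Rcpp::Named("Wf") = w.Wf, Rcpp::Named("Uf") = w.Uf,
    Rcpp::Named("bf") = w.bf,
    Rcpp::Named("Wb") = w.Wb, Rcpp::Named("Ub") = w.Ub,
    Rcpp::Named("bb") = w.bb,
    Rcpp::Named("V") = w.V, Rcpp::Named("co") = w.co);
}

// one-direction LSTM pass; reverse = true reads the sequence backwards
// but stores states at their original time index.
void lstm_forward(const mat& X, const mat& W, const mat& U, const vec& b,
                  bool reverse, DirCache& cc) {
  const uword T = X.n_cols, H = U.n_cols;
  cc.i.set_size(H, T); cc.f.set_size(H, T); cc.g.set_size(H, T);
  cc.o.set_size(H, T); cc.c.set_size(H, T); cc.tc.set_size(H, T);
  cc.h.set_size(H, T);
  vec hprev(H, fill::zeros), cprev(H, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    uword t = reverse ? (T - 1 - k) : k;
    vec a = W * X.col(t) + U * hprev + b;
    vec ig = sigmoid(a.rows(0, H - 1));
    vec fg = sigmoid(a.rows(H, 2 * H - 1));
    vec gg = tanh(a.rows(2 * H, 3 * H - 1));
    vec og = sigmoid(a.rows(3 * H, 4 * H - 1));
    vec cell = fg % cprev + ig % gg;
    vec tcell = tanh(cell);
    cc.i.col(t) = ig; cc.f.col(t) = fg; cc.g.col(t) = gg; cc.o.col(t) = og;
    cc.c.col(t) = cell; cc.tc.col(t) = tcell;
    cc.h.col(t) = og % tcell;
    hprev = cc.h.col(t); cprev = cell;
  }
}

// per-timestep softmax probabilities (C x T) for one sequence
mat posteriors(const Weights& w, const mat& X, DirCache& fc, DirCache& bc) {
  lstm_forward(X, w.Wf, w.Uf, w.bf, false, fc);
  lstm_forward(X, w.Wb, w.Ub, w.bb, true, bc);
  const uword T = X.n_cols, H = w.Uf.n_cols;
  mat Z = w.V.cols(0, H - 1) * fc.h + w.V.cols(H, 2 * H - 1) * bc.h;
  Z.each_col() += w.co;
  Z.each_row() -= max(Z, 0);
  mat P = exp(Z);
  P.each_row() /= sum(P, 0);
  return P;
}

// cross-entropy summed over timesteps for label y
double seq_loss(const mat& P, int y) {
  rowvec py = P.row(y);
  return -accu(log(py + 1e-12));
}

// BPTT through one direction given upstream dh (H x T); accumulates into
// dW, dU, db.
void lstm_backward(const mat& X, const mat& U, const DirCache& cc,
                   const mat& dh_ext, bool reverse,
                   mat& dW, mat& dU, vec& db) {
  const uword T = X.n_cols, H = U.n_cols;
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    uword t = reverse ? k : (T - 1 - k);            // reverse of read order
    bool has_prev = reverse ? (t + 1 < T) : (t > 0); // previous in read order
    uword tprev = reverse ? t + 1 : t - 1;
    vec dh = dh_ext.col(t) + dh_next;
    vec o = cc.o.col(t), i = cc.i.col(t), f = cc.f.col(t), g = cc.g.col(t);
    vec tc = cc.tc.col(t);
    vec dc = dh % o % (1.0 - tc % tc) + dc_next;
    vec cprev = has_prev ? vec(cc.c.col(tprev)) : vec(H, fill::zeros);
    vec da(4 * H);
    da.rows(0, H - 1)         = dc % g % i % (1.0 - i);
    da.rows(H, 2 * H - 1)     = dc % cprev % f % (1.0 - f);
    da.rows(2 * H, 3 * H - 1) = dc % i % (1.0 - g % g);
    da.rows(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dW += da * X.col(t).t();
    if (has_prev) dU += da * cc.h.col(tprev).t();
    db += da;
    dh_next = U.t() * da;
    dc_next = dc % f;
  }
}

struct Grads {
  mat Wf, Uf, Wb, Ub, V;
  vec bf, bb, co;
  void zeros_like(const Weights& w) {
    Wf.zeros(size(w.Wf)); Uf.zeros(size(w.Uf)); bf.zeros(w.bf.n_elem);
    Wb.zeros(size(w.Wb)); Ub.zeros(size(w.Ub)); bb.zeros(w.bb.n_elem);
    V.zeros(size(w.V)); co.zeros(w.co.n_elem);
  }
};

void clip_mat(mat& m, double c) { m.clamp(-c, c); }
void clip_vec(vec& v, double c) { v.clamp(-c, c); }

double dataset_loss(const Weights& w, const std::vector<mat>& X,
                    const std::vector<int>& y) {
  if (X.empty()) return NA_REAL;
  double tot = 0.0;
  DirCache fc, bc;
  for (size_t s = 0; s < X.size(); ++s) {
    mat P = posteriors(w, X[s], fc, bc);
    tot += seq_loss(P, y[s]) / P.n_cols; // mean CE per timestep
  }
  return tot / X.size();
}

std::vector<mat> as_mat_list(const Rcpp::List& L) {
  std::vector<mat> out;
  out.reserve(L.size());
  for (R_xlen_t s = 0; s < L.size(); ++s) out.push_back(Rcpp::as<mat>(L[s]));
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_blstm_posterior(Rcpp::List weights,
                                        Rcpp::NumericMatrix X) {
  Weights w = unpack(weights);
  DirCache fc, bc;
  mat P = posteriors(w, Rcpp::as<mat>(X), fc, bc);
  return Rcpp::wrap(mat(P.t())); // T x C
}

// [[Rcpp::export]]
Rcpp::List cpp_blstm_train(Rcpp::List Xs, Rcpp::IntegerVector y,
                           Rcpp::List Xval, Rcpp::IntegerVector yval,
                           Rcpp::List w0, double lr, double momentum,
                           int max_epochs, int patience, double min_delta,
                           double clip, Rcpp::IntegerMatrix orders) {
  Weights w = unpack(w0);
  std::vector<mat> X = as_mat_list(Xs), Xv = as_mat_list(Xval);
  std::vector<int> lab(y.begin(), y.end()), labv(yval.begin(), yval.end());
  const uword C = w.co.n_elem, H = w.Uf.n_cols;

  Grads vel; vel.zeros_like(w); // momentum velocity
  Weights best = w;
  double best_val = datum::inf;
  int wait = 0, best_epoch = 0, epochs_run = 0;
  std::vector<double> hist_train, hist_val;
  DirCache fc, bc;

  for (int e = 0; e < max_epochs; ++e) {
    double train_loss = 0.0;
    for (R_xlen_t pos = 0; pos < (R_xlen_t)X.size(); ++pos) {
      int s = orders(e, pos); // 0-based sequence index
      const mat& Xi = X[s];
      const uword T = Xi.n_cols;
      mat P = posteriors(w, Xi, fc, bc);
      train_loss += seq_loss(P, lab[s]) / T;

      // output-layer gradient: softmax CE summed over timesteps
      mat dZ = P;                 // C x T
      dZ.row(lab[s]) -= 1.0;
      Grads g; g.zeros_like(w);
      g.V = dZ * join_rows(fc.h.t(), bc.h.t()); // C x 2H
      g.co = sum(dZ, 1);
      mat dh_f = w.V.cols(0, H - 1).t() * dZ;       // H x T
      mat dh_b = w.V.cols(H, 2 * H - 1).t() * dZ;
      lstm_backward(Xi, w.Uf, fc, dh_f, false, g.Wf, g.Uf, g.bf);
      lstm_backward(Xi, w.Ub, bc, dh_b, true, g.Wb, g.Ub, g.bb);

      if (clip > 0) {
        clip_mat(g.Wf, clip); clip_mat(g.Uf, clip); clip_vec(g.bf, clip);
        clip_mat(g.Wb, clip); clip_mat(g.Ub, clip); clip_vec(g.bb, clip);
        clip_mat(g.V, clip);  clip_vec(g.co, clip);
      }
      // SGD with momentum, weights updated after each sequence
      vel.Wf = momentum * vel.Wf - lr * g.Wf;  w.Wf += vel.Wf;
      vel.Uf = momentum * vel.Uf - lr * g.Uf;  w.Uf += vel.Uf;
      vel.bf = momentum * vel.bf - lr * g.bf;  w.bf += vel.bf;
      vel.Wb = momentum * vel.Wb - lr * g.Wb;  w.Wb += vel.Wb;
      vel.Ub = momentum * vel.Ub - lr * g.Ub;  w.Ub += vel.Ub;
      vel.bb = momentum * vel.bb - lr * g.bb;  w.bb += vel.bb;
      vel.V  = momentum * vel.V  - lr * g.V;   w.V  += vel.V;
      vel.co = momentum * vel.co - lr * g.co;  w.co += vel.co;
    }
    train_loss /= X.size();
    double val_loss = Xv.empty() ? train_loss : dataset_loss(w, Xv, labv);
    if (!std::isfinite(train_loss) || !std::isfinite(val_loss)) {
      Rcpp::stop("divergence error: non-finite loss at epoch %d", e + 1);
    }
    hist_train.push_back(train_loss);
    hist_val.push_back(val_loss);
    epochs_run = e + 1;
    if (val_loss < best_val - min_delta) {
      best_val = val_loss; best = w; best_epoch = e + 1; wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  (void)C;
  return Rcpp::List::create(
    Rcpp::Named("weights") = pack(best),
    Rcpp::Named("train_error") = hist_train,
    Rcpp::Named("val_error") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = epochs_run);
}
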