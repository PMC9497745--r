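// Sequence-to-sequence LSTM / BiLSTM with full backpropagation through time
// and Adam, written against Armadillo. Training is full-batch and
// single-threaded, so results are exactly reproducible given the initial
// parameters. Gate preactivations are stacked [input; forget; output; cell]
// along the first dimension.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;
using arma::umat;

struct DirParams { mat W, U; vec b; };

struct DirCache {
  cube I, F, O, G, C, H; // H x B x T each, indexed by original time
};

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// Run one direction over a batch; reverse = true processes time backwards.
static void lstm_forward_dir(const cube& X, const DirParams& p, bool reverse,
                             DirCache& cc) {
  const int T = X.n_slices, B = X.n_cols;
  const int H = p.U.n_cols;
  cc.I.set_size(H, B, T); cc.F.set_size(H, B, T); cc.O.set_size(H, B, T);
  cc.G.set_size(H, B, T); cc.C.set_size(H, B, T); cc.H.set_size(H, B, T);
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    const int t = reverse ? (T - 1 - s) : s;
    mat z = p.W * X.slice(t) + p.U * h;
    z.each_col() += p.b;
    mat i = sigm(z.rows(0, H - 1));
    mat f = sigm(z.rows(H, 2 * H - 1));
    mat o = sigm(z.rows(2 * H, 3 * H - 1));
    mat g = arma::tanh(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.O.slice(t) = o;
    cc.G.slice(t) = g; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
}

// Backward pass of one direction. dH holds dLoss/dh_t (external, from the
// output layer). Accumulates gradients into gW,gU,gb.
static void lstm_backward_dir(const cube& X, const DirParams& p, bool reverse,
                              const DirCache& cc, const cube& dH,
                              mat& gW, mat& gU, vec& gb) {
  const int T = X.n_slices, B = X.n_cols;
  const int H = p.U.n_cols;
  mat dh_carry(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = reverse ? (T - 1 - s) : s;
    const int tprev = reverse ? (t + 1) : (t - 1);
    const mat& i = cc.I.slice(t);
    const mat& f = cc.F.slice(t);
    const mat& o = cc.O.slice(t);
    const mat& g = cc.G.slice(t);
    const mat th = arma::tanh(cc.C.slice(t));
    mat dh = dH.slice(t) + dh_carry;
    mat d_o = dh % th;
    dc += dh % o % (1.0 - th % th);
    mat cprev(H, B, arma::fill::zeros);
    if (s > 0) cprev = cc.C.slice(tprev);
    mat di = dc % g;
    mat df = dc % cprev;
    mat dg = dc % i;
    mat dz(4 * H, B);
    dz.rows(0, H - 1)         = di % i % (1.0 - i);
    dz.rows(H, 2 * H - 1)     = df % f % (1.0 - f);
    dz.rows(2 * H, 3 * H - 1) = d_o % o % (1.0 - o);
    dz.rows(3 * H, 4 * H - 1) = dg % (1.0 - g % g);
    gW += dz * X.slice(t).t();
    if (s > 0) gU += dz * cc.H.slice(tprev).t();
    gb += arma::sum(dz, 1);
    dh_carry = p.U.t() * dz;
    dc = dc % f;
  }
}

struct Net {
  bool bidir;
  DirParams fwd, bwd;
  mat Wo; vec bo;
};

static Net parse_params(const List& prm) {
  Net n;
  n.bidir = as<bool>(prm["bidirectional"]);
  n.fwd.W = as<mat>(prm["Wf"]); n.fwd.U = as<mat>(prm["Uf"]); n.fwd.b = as<vec>(prm["bf"]);
  if (n.bidir) {
    n.bwd.W = as<mat>(prm["Wb"]); n.bwd.U = as<mat>(prm["Ub"]); n.bwd.b = as<vec>(prm["bb"]);
  }
  n.Wo = as<mat>(prm["Wo"]); n.bo = as<vec>(prm["bo"]);
  return n;
}

static List wrap_params(const Net& n) {
  List out = List::create(_["bidirectional"] = n.bidir,
                          _["Wf"] = n.fwd.W, _["Uf"] = n.fwd.U, _["bf"] = n.fwd.b,
                          _["Wo"] = n.Wo, _["bo"] = n.bo);
  if (n.bidir) {
    out["Wb"] = n.bwd.W; out["Ub"] = n.bwd.U; out["bb"] = n.bwd.b;
  }
  return out;
}

// Posteriors for one batch: C x B x T.
static cube net_posterior(const Net& net, const cube& X,
                          DirCache* cf = nullptr, DirCache* cb = nullptr) {
  const int T = X.n_slices, B = X.n_cols;
  const int H = net.fwd.U.n_cols;
  DirCache lf, lb;
  DirCache& f = cf ? *cf : lf;
  lstm_forward_dir(X, net.fwd, false, f);
  if (net.bidir) lstm_forward_dir(X, net.bwd, true, cb ? *cb : lb);
  DirCache& b = cb ? *cb : lb;
  const int C = net.Wo.n_rows;
  cube P(C, B, T);
  for (int t = 0; t < T; ++t) {
    mat hcat = net.bidir ? arma::join_cols(f.H.slice(t), b.H.slice(t))
                         : mat(f.H.slice(t));
    mat logits = net.Wo * hcat;
    logits.each_col() += net.bo;
    logits.each_row() -= arma::max(logits, 0);
    mat e = arma::exp(logits);
    mat denom = arma::sum(e, 0);
    e.each_row() /= denom;
    P.slice(t) = e;
  }
  (void)H;
  return P;
}

// Mean cross-entropy of a batch given integer labels (T x B, values 0..C-1).
static double batch_loss(const cube& P, const umat& Y) {
  const int T = P.n_slices, B = P.n_cols;
  double loss = 0.0;
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      loss -= std::log(std::max(P(Y(t, b), b, t), 1e-12));
  return loss / (double)(T * B);
}

struct Grads {
  mat gWf, gUf, gWb, gUb, gWo;
  vec gbf, gbb, gbo;
  void zero_like(const Net& n) {
    gWf.zeros(arma::size(n.fwd.W)); gUf.zeros(arma::size(n.fwd.U)); gbf.zeros(n.fwd.b.n_elem);
    if (n.bidir) {
      gWb.zeros(arma::size(n.bwd.W)); gUb.zeros(arma::size(n.bwd.U)); gbb.zeros(n.bwd.b.n_elem);
    }
    gWo.zeros(arma::size(n.Wo)); gbo.zeros(n.bo.n_elem);
  }
};

// Forward + backward on one batch; scale multiplies the per-window gradient
// (1 / total windows across all batches). Returns summed cross-entropy.
static double batch_grads(const Net& net, const cube& X, const umat& Y,
                          double scale, Grads& g) {
  const int T = X.n_slices, B = X.n_cols;
  const int H = net.fwd.U.n_cols;
  DirCache cf, cb;
  cube P = net_posterior(net, X, &cf, net.bidir ? &cb : nullptr);
  double loss = 0.0;
  cube dHf(H, B, T), dHb;
  if (net.bidir) dHb.set_size(H, B, T);
  const mat WoF = net.Wo.cols(0, H - 1);
  for (int t = 0; t < T; ++t) {
    mat dlog = P.slice(t);
    for (int b = 0; b < B; ++b) {
      loss -= std::log(std::max(P(Y(t, b), b, t), 1e-12));
      dlog(Y(t, b), b) -= 1.0;
    }
    dlog *= scale;
    mat hcat = net.bidir ? arma::join_cols(cf.H.slice(t), cb.H.slice(t))
                         : mat(cf.H.slice(t));
    g.gWo += dlog * hcat.t();
    g.gbo += arma::sum(dlog, 1);
    dHf.slice(t) = WoF.t() * dlog;
    if (net.bidir) {
      const mat WoB = net.Wo.cols(H, 2 * H - 1);
      dHb.slice(t) = WoB.t() * dlog;
    }
  }
  lstm_backward_dir(X, net.fwd, false, cf, dHf, g.gWf, g.gUf, g.gbf);
  if (net.bidir) lstm_backward_dir(X, net.bwd, true, cb, dHb, g.gWb, g.gUb, g.gbb);
  // chain rule scale already applied through dlog
  return loss;
}

struct Adam {
  std::vector<mat> m1, v1;
  std::vector<vec> mb1, vb1;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  void init(const std::vector<mat*>& ms, const std::vector<vec*>& vs) {
    for (auto* p : ms) { m1.emplace_back(arma::size(*p), arma::fill::zeros);
                         v1.emplace_back(arma::size(*p), arma::fill::zeros); }
    for (auto* p : vs) { mb1.emplace_back(p->n_elem, arma::fill::zeros);
                         vb1.emplace_back(p->n_elem, arma::fill::zeros); }
  }
  void update(std::vector<mat*>& ps, std::vector<mat*>& gs,
              std::vector<vec*>& pv, std::vector<vec*>& gv, double lr) {
    ++step;
    const double c1 = 1.0 - std::pow(b1, (double)step);
    const double c2 = 1.0 - std::pow(b2, (double)step);
    for (size_t i = 0; i < ps.size(); ++i) {
      m1[i] = b1 * m1[i] + (1 - b1) * (*gs[i]);
      v1[i] = b2 * v1[i] + (1 - b2) * arma::square(*gs[i]);
      *ps[i] -= lr * (m1[i] / c1) / (arma::sqrt(v1[i] / c2) + eps);
    }
    for (size_t i = 0; i < pv.size(); ++i) {
      mb1[i] = b1 * mb1[i] + (1 - b1) * (*gv[i]);
      vb1[i] = b2 * vb1[i] + (1 - b2) * arma::square(*gv[i]);
      *pv[i] -= lr * (mb1[i] / c1) / (arma::sqrt(vb1[i] / c2) + eps);
    }
  }
};

// Xs: list of D x B x T cubes (batches may differ in T and B);
// Ys: list of T x B integer matrices with labels in 0..C-1.
// [[Rcpp::export]]
List cpp_lstm_train(List prm, List Xs, List Ys, double lr, int max_epochs,
                    double clip_norm, Nullable<List> val, int patience,
                    int min_epochs) {
  Net net = parse_params(prm);
  const int nb = Xs.size();
  std::vector<cube> X(nb);
  std::vector<umat> Y(nb);
  double total_windows = 0.0;
  for (int i = 0; i < nb; ++i) {
    X[i] = as<cube>(Xs[i]);
    Y[i] = as<umat>(Ys[i]);
    total_windows += (double)X[i].n_slices * X[i].n_cols;
  }
  bool has_val = val.isNotNull();
  std::vector<cube> Xv;
  std::vector<umat> Yv;
  if (has_val) {
    List v(val);
    List vXs = v["x"], vYs = v["y"];
    for (int i = 0; i < vXs.size(); ++i) {
      Xv.push_back(as<cube>(vXs[i]));
      Yv.push_back(as<umat>(vYs[i]));
    }
  }
  Grads g;
  g.zero_like(net);
  std::vector<mat*> pm = { &net.fwd.W, &net.fwd.U, &net.Wo };
  std::vector<mat*> gm = { &g.gWf, &g.gUf, &g.gWo };
  std::vector<vec*> pv = { &net.fwd.b, &net.bo };
  std::vector<vec*> gv = { &g.gbf, &g.gbo };
  if (net.bidir) {
    pm.insert(pm.begin() + 2, &net.bwd.W);
    pm.insert(pm.begin() + 3, &net.bwd.U);
    gm.insert(gm.begin() + 2, &g.gWb);
    gm.insert(gm.begin() + 3, &g.gUb);
    pv.insert(pv.begin() + 1, &net.bwd.b);
    gv.insert(gv.begin() + 1, &g.gbb);
  }
  Adam opt;
  opt.init(pm, pv);
  std::vector<double> train_loss, val_loss;
  double best_val = R_PosInf;
  int best_epoch = -1, wait = 0;
  Net best = net;
  for (int ep = 0; ep < max_epochs; ++ep) {
    g.zero_like(net);
    double loss = 0.0;
    for (int i = 0; i < nb; ++i)
      loss += batch_grads(net, X[i], Y[i], 1.0 / total_windows, g);
    train_loss.push_back(loss / total_windows);
    // global gradient-norm clipping
    double nrm2 = 0.0;
    for (auto* gp : gm) nrm2 += arma::accu(arma::square(*gp));
    for (auto* gp : gv) nrm2 += arma::accu(arma::square(*gp));
    const double nrm = std::sqrt(nrm2);
    if (clip_norm > 0 && nrm > clip_norm) {
      const double sc = clip_norm / nrm;
      for (auto* gp : gm) (*gp) *= sc;
      for (auto* gp : gv) (*gp) *= sc;
    }
    opt.update(pm, gm, pv, gv, lr);
    if (has_val) {
      double vl = 0.0, vw = 0.0;
      for (size_t i = 0; i < Xv.size(); ++i) {
        cube P = net_posterior(net, Xv[i]);
        vl += batch_loss(P, Yv[i]) * (double)(Xv[i].n_slices * Xv[i].n_cols);
        vw += (double)(Xv[i].n_slices * Xv[i].n_cols);
      }
      vl /= vw;
      val_loss.push_back(vl);
      // model selection and stopping only after a burn-in, so a noisy
      // validation subject can never hand back a near-initial model
      if (ep + 1 < min_epochs) continue;
      if (vl < best_val - 1e-6) {
        best_val = vl; best = net; best_epoch = ep + 1; wait = 0;
      } else if (best_epoch < 0) {
        best_val = vl; best = net; best_epoch = ep + 1; wait = 0;
      } else if (++wait >= patience) break;
    }
  }
  const Net& fin = (has_val && best_epoch > 0) ? best : net;
  return List::create(_["params"] = wrap_params(fin),
                      _["train_loss"] = wrap(train_loss),
                      _["val_loss"] = wrap(val_loss),
                      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
NumericVector cpp_lstm_posterior(List prm, arma::cube X) {
  Net net = parse_params(prm);
  cube P = net_posterior(net, X);
  return wrap(P);
}
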