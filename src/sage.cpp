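// GraphSage-style edge classifier: minibatch forward/backward with sampled
// multi-hop neighborhoods, element-wise max-pool aggregation, optional
// per-layer L2 normalization and dropout, two edge heads (symmetric pair
// MLP, or the scalar-product head), weighted binary cross-entropy or focal
// loss, and Adam updates with L2 weight decay.
//
// All randomness (neighborhood sampling, dropout) is drawn from R's RNG so
// that set.seed() in R makes training bit-reproducible.

#include <RcppArmadillo.h>
#include <vector>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct LayerP {
  arma::mat Wpool;  // Hk x D_{k-1}
  arma::vec bpool;  // Hk
  arma::mat W;      // Hk x (D_{k-1} + Hk)
};

struct HeadP {
  std::string type;  // "pair_mlp" or "dot"
  arma::mat W1;      // Hh x 2H (pair_mlp)
  arma::vec b1;      // Hh
  arma::vec w2;      // Hh
  double b2;
  arma::vec w;       // H (dot)
  double b;
};

std::vector<LayerP> layers_from_list(List ll) {
  std::vector<LayerP> out(ll.size());
  for (int k = 0; k < ll.size(); ++k) {
    List l = ll[k];
    out[k].Wpool = as<arma::mat>(l["Wpool"]);
    out[k].bpool = as<arma::vec>(l["bpool"]);
    out[k].W = as<arma::mat>(l["W"]);
  }
  return out;
}

List layers_to_list(const std::vector<LayerP>& ls) {
  List out(ls.size());
  for (size_t k = 0; k < ls.size(); ++k) {
    out[k] = List::create(_["Wpool"] = ls[k].Wpool, _["bpool"] = ls[k].bpool,
                          _["W"] = ls[k].W);
  }
  return out;
}

HeadP head_from_list(List h) {
  HeadP out;
  out.type = as<std::string>(h["type"]);
  if (out.type == "pair_mlp") {
    out.W1 = as<arma::mat>(h["W1"]);
    out.b1 = as<arma::vec>(h["b1"]);
    out.w2 = as<arma::vec>(h["w2"]);
    out.b2 = as<double>(h["b2"]);
  } else if (out.type == "dot") {
    out.w = as<arma::vec>(h["w"]);
    out.b = as<double>(h["b"]);
  } else {
    stop("unknown head type '%s'", out.type.c_str());
  }
  return out;
}

List head_to_list(const HeadP& h) {
  if (h.type == "pair_mlp") {
    return List::create(_["type"] = h.type, _["W1"] = h.W1, _["b1"] = h.b1,
                        _["w2"] = h.w2, _["b2"] = h.b2);
  }
  return List::create(_["type"] = h.type, _["w"] = h.w, _["b"] = h.b);
}

const double P_CLAMP = 1e-7;

inline double clamp_p(double p) {
  if (p < P_CLAMP) return P_CLAMP;
  if (p > 1.0 - P_CLAMP) return 1.0 - P_CLAMP;
  return p;
}

// loss_type: 0 = positive-weighted binary cross-entropy, 1 = focal.
inline double edge_loss(double p, double y, int loss_type, double pos_weight,
                        double alpha, double gamma) {
  p = clamp_p(p);
  if (loss_type == 0) {
    return y > 0.5 ? -pos_weight * std::log(p) : -std::log(1.0 - p);
  }
  if (y > 0.5) return -alpha * std::pow(1.0 - p, gamma) * std::log(p);
  return -(1.0 - alpha) * std::pow(p, gamma) * std::log(1.0 - p);
}

// d(loss)/d(logit s), with p = sigmoid(s) already clamped.
inline double edge_loss_dlogit(double p, double y, int loss_type,
                               double pos_weight, double alpha, double gamma) {
  p = clamp_p(p);
  if (loss_type == 0) {
    return y > 0.5 ? -pos_weight * (1.0 - p) : p;
  }
  double dldp;
  if (y > 0.5) {
    dldp = -alpha * std::pow(1.0 - p, gamma) / p;
    if (gamma > 0.0)
      dldp += alpha * gamma * std::pow(1.0 - p, gamma - 1.0) * std::log(p);
  } else {
    dldp = (1.0 - alpha) * std::pow(p, gamma) / (1.0 - p);
    if (gamma > 0.0)
      dldp += -(1.0 - alpha) * gamma * std::pow(p, gamma - 1.0) *
              std::log(1.0 - p);
  }
  return dldp * p * (1.0 - p);
}

// Sample up to S distinct neighbors of v (all of them if degree <= S),
// consuming R's RNG only when subsampling is required.
void sample_neighbors(const IntegerVector& adj_ptr, const IntegerVector& adj_idx,
                      int v, int S, std::vector<int>& out) {
  out.clear();
  int lo = adj_ptr[v], hi = adj_ptr[v + 1];
  int deg = hi - lo;
  if (deg <= S) {
    for (int i = lo; i < hi; ++i) out.push_back(adj_idx[i]);
    return;
  }
  std::vector<int> tmp(deg);
  for (int i = 0; i < deg; ++i) tmp[i] = adj_idx[lo + i];
  for (int i = 0; i < S; ++i) {
    int j = i + (int)std::floor(unif_rand() * (deg - i));
    if (j >= deg) j = deg - 1;
    std::swap(tmp[i], tmp[j]);
    out.push_back(tmp[i]);
  }
}

struct LayerStore {
  arma::mat Hprev;  // input states, D_{k-1} x nprev
  arma::mat M;      // pooled activations, Hk x nprev
  arma::imat AMAX;  // winning neighbor (local, -1 if none), Hk x nk
  arma::mat C;      // concatenated [self ; agg], (D+Hk) x nk
  arma::mat HACT;   // post-activation, Hk x nk
  arma::mat HN;     // normalized, Hk x nk
  arma::vec rr;     // norms used for normalization
  arma::mat mask;   // dropout mask (empty if unused)
  std::vector<std::vector<int> > nbrs;  // per node, locals into level k-1
};

// Forward (and optional backward) pass over one batch of edges.
// Returns the mean loss over the batch; fills probs (one per edge) and, if
// grads are supplied, accumulates parameter gradients (already divided by
// the batch size).
double process_batch(const std::vector<int>& batch,
                     const arma::mat& X,
                     const IntegerVector& adj_ptr, const IntegerVector& adj_idx,
                     const IntegerMatrix& E, const NumericVector& yv,
                     std::vector<LayerP>& P, HeadP& H,
                     std::vector<LayerP>* G, HeadP* GH,
                     int S, double dropout, bool training, bool normalize,
                     int loss_type, double pos_weight, double alpha,
                     double gamma, double* probs_out) {
  const int K = (int)P.size();
  const int B = (int)batch.size();
  const bool want_grad = (G != nullptr);
  const bool have_y = (yv.size() > 0);

  // Need-sets per level, built from the targets down. need[k] is a prefix
  // of need[k-1] (same local indices), so the self part of the concat at
  // layer k is simply the first nk columns of the previous level's states.
  std::vector<std::vector<int> > need(K + 1);
  std::vector<std::vector<std::vector<int> > > nbrs(K + 1);
  std::vector<int> ei(B), ej(B);
  {
    std::unordered_map<int, int> loc;
    for (int b = 0; b < B; ++b) {
      int e = batch[b];
      int g1 = E(e, 0), g2 = E(e, 1);
      auto it = loc.find(g1);
      if (it == loc.end()) {
        loc[g1] = (int)need[K].size();
        need[K].push_back(g1);
      }
      ei[b] = loc[g1];
      it = loc.find(g2);
      if (it == loc.end()) {
        loc[g2] = (int)need[K].size();
        need[K].push_back(g2);
      }
      ej[b] = loc[g2];
    }
    for (int k = K; k >= 1; --k) {
      need[k - 1] = need[k];
      std::unordered_map<int, int> locp;
      for (size_t i = 0; i < need[k - 1].size(); ++i) locp[need[k - 1][i]] = (int)i;
      nbrs[k].resize(need[k].size());
      std::vector<int> samp;
      for (size_t v = 0; v < need[k].size(); ++v) {
        sample_neighbors(adj_ptr, adj_idx, need[k][v], S, samp);
        for (int g : samp) {
          auto it2 = locp.find(g);
          if (it2 == locp.end()) {
            locp[g] = (int)need[k - 1].size();
            need[k - 1].push_back(g);
            nbrs[k][v].push_back((int)need[k - 1].size() - 1);
          } else {
            nbrs[k][v].push_back(it2->second);
          }
        }
      }
    }
  }

  // Forward.
  std::vector<LayerStore> st(K + 1);
  arma::mat Hprev(X.n_rows, need[0].size());
  for (size_t i = 0; i < need[0].size(); ++i) Hprev.col(i) = X.col(need[0][i]);

  for (int k = 1; k <= K; ++k) {
    LayerStore& s = st[k];
    const int nk = (int)need[k].size();
    const int Hk = (int)P[k - 1].W.n_rows;
    s.Hprev = Hprev;
    s.nbrs = nbrs[k];
    arma::mat Apre = P[k - 1].Wpool * s.Hprev;
    Apre.each_col() += P[k - 1].bpool;
    s.M = arma::clamp(Apre, 0.0, arma::datum::inf);  // ReLU

    arma::mat AGG(Hk, nk, arma::fill::zeros);
    s.AMAX.set_size(Hk, nk);
    s.AMAX.fill(-1);
    for (int v = 0; v < nk; ++v) {
      const std::vector<int>& nb = s.nbrs[v];
      if (nb.empty()) continue;  // isolated node: zero vector
      AGG.col(v) = s.M.col(nb[0]);
      for (int t = 0; t < Hk; ++t) s.AMAX(t, v) = nb[0];
      for (size_t u = 1; u < nb.size(); ++u) {
        for (int t = 0; t < Hk; ++t) {
          if (s.M(t, nb[u]) > AGG(t, v)) {
            AGG(t, v) = s.M(t, nb[u]);
            s.AMAX(t, v) = nb[u];
          }
        }
      }
    }

    s.C = arma::join_cols(s.Hprev.cols(0, nk - 1), AGG);
    arma::mat PRE = P[k - 1].W * s.C;
    s.HACT = arma::clamp(PRE, 0.0, arma::datum::inf);
    if (normalize) {
      s.rr.set_size(nk);
      s.HN = s.HACT;
      for (int v = 0; v < nk; ++v) {
        double r = arma::norm(s.HACT.col(v), 2);
        s.rr(v) = std::max(r, 1e-12);
        s.HN.col(v) /= s.rr(v);
      }
    } else {
      s.HN = s.HACT;
    }
    if (training && dropout > 0.0) {
      s.mask.set_size(Hk, nk);
      const double keep_scale = 1.0 / (1.0 - dropout);
      for (int v = 0; v < nk; ++v)
        for (int t = 0; t < Hk; ++t)
          s.mask(t, v) = (unif_rand() < dropout) ? 0.0 : keep_scale;
      Hprev = s.HN % s.mask;
    } else {
      Hprev = s.HN;
    }
  }
  const arma::mat& Z = Hprev;  // columns = need[K]
  const int HK = (int)Z.n_rows;

  // Head forward.
  arma::vec svec(B), pvec(B);
  arma::mat Cpair, Hpair, SGN;
  arma::vec onode;
  if (H.type == "pair_mlp") {
    Cpair.set_size(2 * HK, B);
    SGN.set_size(HK, B);
    for (int b = 0; b < B; ++b) {
      arma::vec zi = Z.col(ei[b]), zj = Z.col(ej[b]);
      arma::vec d = zi - zj;
      SGN.col(b) = arma::sign(d);
      Cpair.col(b) = arma::join_cols(zi + zj, arma::abs(d));
    }
    arma::mat HPRE = H.W1 * Cpair;
    HPRE.each_col() += H.b1;
    Hpair = arma::clamp(HPRE, 0.0, arma::datum::inf);
    svec = Hpair.t() * H.w2 + H.b2;
  } else {
    onode = Z.t() * H.w + H.b;
    for (int b = 0; b < B; ++b) svec(b) = onode(ei[b]) * onode(ej[b]);
  }
  double total = 0.0;
  arma::vec dsv(B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double p = 1.0 / (1.0 + std::exp(-svec(b)));
    pvec(b) = clamp_p(p);
    if (probs_out) probs_out[b] = pvec(b);
    if (have_y) {
      double y = yv[batch[b]];
      total += edge_loss(pvec(b), y, loss_type, pos_weight, alpha, gamma);
      if (want_grad) {
        dsv(b) = edge_loss_dlogit(pvec(b), y, loss_type, pos_weight, alpha,
                                  gamma) / B;
      }
    }
  }
  double mean_loss = have_y ? total / B : NA_REAL;
  if (!want_grad) return mean_loss;

  // Backward.
  arma::mat dH(HK, need[K].size(), arma::fill::zeros);
  if (H.type == "pair_mlp") {
    arma::mat dHpre(H.W1.n_rows, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::vec dh = dsv(b) * H.w2;
      arma::vec dhp = dh % arma::conv_to<arma::vec>::from(
          arma::vec(Hpair.col(b)) > 0.0);
      dHpre.col(b) = dhp;
      GH->w2 += dsv(b) * Hpair.col(b);
      GH->b2 += dsv(b);
    }
    GH->W1 += dHpre * Cpair.t();
    GH->b1 += arma::sum(dHpre, 1);
    arma::mat dC = H.W1.t() * dHpre;
    for (int b = 0; b < B; ++b) {
      arma::vec du = dC.col(b).head(HK);
      arma::vec dw = dC.col(b).tail(HK);
      arma::vec sg = SGN.col(b);
      dH.col(ei[b]) += du + sg % dw;
      dH.col(ej[b]) += du - sg % dw;
    }
  } else {
    arma::vec don(need[K].size(), arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      don(ei[b]) += dsv(b) * onode(ej[b]);
      don(ej[b]) += dsv(b) * onode(ei[b]);
    }
    GH->w += Z * don;
    GH->b += arma::accu(don);
    dH += H.w * don.t();
  }

  for (int k = K; k >= 1; --k) {
    LayerStore& s = st[k];
    const int nk = (int)need[k].size();
    const int Hk = (int)P[k - 1].W.n_rows;
    const int D = (int)s.Hprev.n_rows;
    arma::mat dHN = (s.mask.n_elem > 0) ? arma::mat(dH % s.mask) : dH;
    arma::mat dHACT(Hk, nk);
    if (normalize) {
      for (int v = 0; v < nk; ++v) {
        arma::vec g = dHN.col(v);
        arma::vec h = s.HN.col(v);
        dHACT.col(v) = (g - arma::dot(g, h) * h) / s.rr(v);
      }
    } else {
      dHACT = dHN;
    }
    arma::mat dPRE = dHACT % arma::conv_to<arma::mat>::from(s.HACT > 0.0);
    (*G)[k - 1].W += dPRE * s.C.t();
    arma::mat dC = P[k - 1].W.t() * dPRE;

    arma::mat dHprev(D, s.Hprev.n_cols, arma::fill::zeros);
    dHprev.cols(0, nk - 1) += dC.rows(0, D - 1);
    arma::mat dM(Hk, s.Hprev.n_cols, arma::fill::zeros);
    for (int v = 0; v < nk; ++v) {
      for (int t = 0; t < Hk; ++t) {
        int j = s.AMAX(t, v);
        if (j >= 0) dM(t, j) += dC(D + t, v);
      }
    }
    arma::mat dApre = dM % arma::conv_to<arma::mat>::from(s.M > 0.0);
    (*G)[k - 1].Wpool += dApre * s.Hprev.t();
    (*G)[k - 1].bpool += arma::sum(dApre, 1);
    dHprev += P[k - 1].Wpool.t() * dApre;
    dH = dHprev;
  }
  return mean_loss;
}

void adam_step(arma::mat& p, const arma::mat& g0, arma::mat& m, arma::mat& v,
               double lr, double wd, double b1, double b2, double eps,
               double t) {
  arma::mat g = g0 + wd * p;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

void adam_step_vec(arma::vec& p, const arma::vec& g0, arma::vec& m,
                   arma::vec& v, double lr, double wd, double b1, double b2,
                   double eps, double t) {
  arma::vec g = g0 + wd * p;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

void adam_step_scalar(double& p, double g0, double& m, double& v, double lr,
                      double wd, double b1, double b2, double eps, double t) {
  double g = g0 + wd * p;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * g * g;
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  p -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
}

std::vector<LayerP> zeros_like_layers(const std::vector<LayerP>& P) {
  std::vector<LayerP> G(P.size());
  for (size_t k = 0; k < P.size(); ++k) {
    G[k].Wpool.zeros(P[k].Wpool.n_rows, P[k].Wpool.n_cols);
    G[k].bpool.zeros(P[k].bpool.n_elem);
    G[k].W.zeros(P[k].W.n_rows, P[k].W.n_cols);
  }
  return G;
}

HeadP zeros_like_head(const HeadP& H) {
  HeadP G;
  G.type = H.type;
  if (H.type == "pair_mlp") {
    G.W1.zeros(H.W1.n_rows, H.W1.n_cols);
    G.b1.zeros(H.b1.n_elem);
    G.w2.zeros(H.w2.n_elem);
    G.b2 = 0.0;
  } else {
    G.w.zeros(H.w.n_elem);
    G.b = 0.0;
  }
  return G;
}

} // namespace

// One training epoch: shuffled edge order is supplied by the caller; one
// Adam step per minibatch. Returns updated parameters, optimizer state, the
// mean training loss and the (training-time) probability for every edge.
// [[Rcpp::export(name = ".cpp_sage_epoch")]]
List cpp_sage_epoch(List layers, List head, List adam,
                    const arma::mat& X, IntegerVector adj_ptr,
                    IntegerVector adj_idx, IntegerMatrix E, NumericVector y,
                    IntegerVector order, int batch_size, int S,
                    double dropout, bool normalize, double lr,
                    double weight_decay, int loss_type, double pos_weight,
                    double alpha, double gamma) {
  std::vector<LayerP> P = layers_from_list(layers);
  HeadP H = head_from_list(head);
  const int M = order.size();
  double t_adam = as<double>(adam["t"]);
  List adam_layers = adam["layers"];
  List adam_head = adam["head"];
  std::vector<LayerP> Gm = layers_from_list(adam_layers["m"]);
  std::vector<LayerP> Gv = layers_from_list(adam_layers["v"]);
  HeadP Hm = head_from_list(adam_head["m"]);
  HeadP Hv = head_from_list(adam_head["v"]);

  std::vector<LayerP> G = zeros_like_layers(P);
  HeadP GH = zeros_like_head(H);
  NumericVector probs(M);
  double loss_sum = 0.0;
  int n_edges_done = 0;

  for (int start = 0; start < M; start += batch_size) {
    int stop_at = std::min(start + batch_size, M);
    std::vector<int> batch;
    for (int i = start; i < stop_at; ++i) batch.push_back(order[i]);
    for (auto& g : G) { g.Wpool.zeros(); g.bpool.zeros(); g.W.zeros(); }
    if (GH.type == "pair_mlp") {
      GH.W1.zeros(); GH.b1.zeros(); GH.w2.zeros(); GH.b2 = 0.0;
    } else {
      GH.w.zeros(); GH.b = 0.0;
    }
    std::vector<double> bp(batch.size());
    double l = process_batch(batch, X, adj_ptr, adj_idx, E, y, P, H, &G, &GH,
                             S, dropout, true, normalize, loss_type,
                             pos_weight, alpha, gamma, bp.data());
    for (size_t i = 0; i < batch.size(); ++i) probs[batch[i]] = bp[i];
    loss_sum += l * batch.size();
    n_edges_done += (int)batch.size();

    t_adam += 1.0;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    for (size_t k = 0; k < P.size(); ++k) {
      adam_step(P[k].Wpool, G[k].Wpool, Gm[k].Wpool, Gv[k].Wpool, lr,
                weight_decay, b1, b2, eps, t_adam);
      adam_step_vec(P[k].bpool, G[k].bpool, Gm[k].bpool, Gv[k].bpool, lr,
                    weight_decay, b1, b2, eps, t_adam);
      adam_step(P[k].W, G[k].W, Gm[k].W, Gv[k].W, lr, weight_decay, b1, b2,
                eps, t_adam);
    }
    if (H.type == "pair_mlp") {
      adam_step(H.W1, GH.W1, Hm.W1, Hv.W1, lr, weight_decay, b1, b2, eps,
                t_adam);
      adam_step_vec(H.b1, GH.b1, Hm.b1, Hv.b1, lr, weight_decay, b1, b2, eps,
                    t_adam);
      adam_step_vec(H.w2, GH.w2, Hm.w2, Hv.w2, lr, weight_decay, b1, b2, eps,
                    t_adam);
      adam_step_scalar(H.b2, GH.b2, Hm.b2, Hv.b2, lr, weight_decay, b1, b2,
                       eps, t_adam);
    } else {
      adam_step_vec(H.w, GH.w, Hm.w, Hv.w, lr, weight_decay, b1, b2, eps,
                    t_adam);
      adam_step_scalar(H.b, GH.b, Hm.b, Hv.b, lr, weight_decay, b1, b2, eps,
                       t_adam);
    }
  }

  return List::create(
      _["layers"] = layers_to_list(P),
      _["head"] = head_to_list(H),
      _["adam"] = List::create(
          _["t"] = t_adam,
          _["layers"] = List::create(_["m"] = layers_to_list(Gm),
                                     _["v"] = layers_to_list(Gv)),
          _["head"] = List::create(_["m"] = head_to_list(Hm),
                                   _["v"] = head_to_list(Hv))),
      _["loss"] = loss_sum / std::max(n_edges_done, 1),
      _["probs"] = probs);
}

// Edge probabilities for a set of edges (no dropout). With S at least the
// maximum degree the pass is exhaustive and deterministic.
// [[Rcpp::export(name = ".cpp_sage_probs")]]
NumericVector cpp_sage_probs(List layers, List head, const arma::mat& X,
                             IntegerVector adj_ptr, IntegerVector adj_idx,
                             IntegerMatrix E, int S, bool normalize) {
  std::vector<LayerP> P = layers_from_list(layers);
  HeadP H = head_from_list(head);
  const int M = E.nrow();
  NumericVector probs(M);
  if (M == 0) return probs;
  std::vector<int> batch(M);
  for (int i = 0; i < M; ++i) batch[i] = i;
  NumericVector dummy_y(0);
  std::vector<double> bp(M);
  process_batch(batch, X, adj_ptr, adj_idx, E, dummy_y, P, H, nullptr,
                nullptr, S, 0.0, false, normalize, 0, 1.0, 0.25, 2.0,
                bp.data());
  for (int i = 0; i < M; ++i) probs[i] = bp[i];
  return probs;
}

// Mean loss and full parameter gradient over a set of edges (no dropout,
// no weight decay); used for finite-difference verification.
// [[Rcpp::export(name = ".cpp_sage_loss_grad")]]
List cpp_sage_loss_grad(List layers, List head, const arma::mat& X,
                        IntegerVector adj_ptr, IntegerVector adj_idx,
                        IntegerMatrix E, NumericVector y, int S,
                        bool normalize, int loss_type, double pos_weight,
                        double alpha, double gamma) {
  std::vector<LayerP> P = layers_from_list(layers);
  HeadP H = head_from_list(head);
  std::vector<LayerP> G = zeros_like_layers(P);
  HeadP GH = zeros_like_head(H);
  const int M = E.nrow();
  std::vector<int> batch(M);
  for (int i = 0; i < M; ++i) batch[i] = i;
  std::vector<double> bp(M);
  double loss = process_batch(batch, X, adj_ptr, adj_idx, E, y, P, H, &G, &GH,
                              S, 0.0, false, normalize, loss_type, pos_weight,
                              alpha, gamma, bp.data());
  return List::create(_["loss"] = loss,
                      _["grad_layers"] = layers_to_list(G),
                      _["grad_head"] = head_to_list(GH),
                      _["probs"] = NumericVector(bp.begin(), bp.end()));
}
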