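// Felsenstein pruning over 61 codon states, the hot path of all model fits.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// pruning for one transition-matrix cube; returns per-pattern log-likelihood
static arma::vec prune_one(const arma::imat& edge,
                           const std::vector<const arma::mat*>& P,
                           const arma::imat& tips, const arma::vec& pi,
                           const int n_node) {
  const int n_tip = tips.n_rows;
  const int n_pat = tips.n_cols;
  const int n_state = pi.n_elem;
  const int n_edge = edge.n_rows;

  std::vector<arma::mat> part(n_node + 1);
  arma::rowvec logscale(n_pat, arma::fill::zeros);

  for (int e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    arma::mat msg(n_state, n_pat);
    if (child <= n_tip) {
      arma::uvec st(n_pat);
      for (int j = 0; j < n_pat; ++j) st(j) = tips(child - 1, j) - 1;
      msg = P[e]->cols(st);
    } else {
      msg = (*P[e]) * part[child];
    }
    arma::rowvec m = arma::max(msg, 0);
    m.replace(0.0, 1.0);
    msg.each_row() /= m;
    logscale += arma::log(m);
    if (part[parent].n_elem == 0)
      part[parent] = msg;
    else
      part[parent] %= msg;
  }
  const int root = edge(n_edge - 1, 0);
  arma::rowvec lik = pi.t() * part[root];
  return (arma::log(lik) + logscale).t();
}

// edge: n_edge x 2 (parent, child), 1-based, postorder
// P: 61 x 61 x n_edge cube
// [[Rcpp::export]]
arma::vec site_loglik_cpp(const arma::imat& edge, const arma::cube& P,
                          const arma::imat& tips, const arma::vec& pi,
                          const int n_node) {
  std::vector<arma::mat> Ps(edge.n_rows);
  std::vector<const arma::mat*> Pv(edge.n_rows);
  for (unsigned e = 0; e < edge.n_rows; ++e) {
    Ps[e] = P.slice(e);
    Pv[e] = &Ps[e];
  }
  return prune_one(edge, Pv, tips, pi, n_node);
}

// Per-class per-pattern log-likelihoods for a site-class mixture, building
// the per-edge transition matrices internally from the (shared-scale)
// eigendecompositions of the distinct omega generators:
//   P(t) = U diag(exp(lambda t)) V.
// U, V, lam: one entry per distinct omega; bg/fg map each class to an omega
// index (1-based); fg_edge flags foreground branches.
// [[Rcpp::export]]
arma::mat class_logliks_cpp(const arma::imat& edge, const arma::imat& tips,
                            const arma::vec& pi, const int n_node,
                            const arma::vec& bl,
                            const List& U, const List& V, const List& lam,
                            const IntegerVector& bg, const IntegerVector& fg,
                            const LogicalVector& fg_edge) {
  const int n_edge = edge.n_rows;
  const int n_omega = U.size();
  const int K = bg.size();

  // per-omega per-edge transition matrices, built on demand
  std::vector<std::vector<arma::mat>> P(n_omega,
                                        std::vector<arma::mat>(n_edge));
  std::vector<std::vector<bool>> have(n_omega,
                                      std::vector<bool>(n_edge, false));
  std::vector<arma::mat> Us(n_omega), Vs(n_omega);
  std::vector<arma::vec> ls(n_omega);
  for (int w = 0; w < n_omega; ++w) {
    Us[w] = as<arma::mat>(U[w]);
    Vs[w] = as<arma::mat>(V[w]);
    ls[w] = as<arma::vec>(lam[w]);
  }
  auto getP = [&](int w, int e) -> const arma::mat& {
    if (!have[w][e]) {
      arma::mat M = Us[w];
      M.each_row() %= arma::exp(ls[w] * bl(e)).t();
      P[w][e] = M * Vs[w];
      P[w][e].clamp(0.0, arma::datum::inf);
      // renormalise rows against rounding noise
      arma::vec rs = arma::sum(P[w][e], 1);
      P[w][e].each_col() /= rs;
      have[w][e] = true;
    }
    return P[w][e];
  };

  arma::mat out(tips.n_cols, K);
  for (int k = 0; k < K; ++k) {
    std::vector<const arma::mat*> Pv(n_edge);
    for (int e = 0; e < n_edge; ++e) {
      const int w = fg_edge[e] ? fg[k] - 1 : bg[k] - 1;
      Pv[e] = &getP(w, e);
    }
    out.col(k) = prune_one(edge, Pv, tips, pi, n_node);
  }
  return out;
}
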