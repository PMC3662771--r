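// Felsenstein pruning for a k-state Mk model on a rooted tree.
// Branch transition matrices P(t) = expm(Q t) are computed from one
// eigendecomposition of Q per call (with an expmat fallback when the
// eigenvector matrix is ill-conditioned) and cached by branch length.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct PCache {
  const arma::mat& Q;
  bool use_eig = false;
  arma::cx_mat V, Vinv;
  arma::cx_vec eval;
  std::map<double, arma::mat> cache;

  explicit PCache(const arma::mat& Q_) : Q(Q_) {
    arma::cx_mat Vl;
    if (arma::eig_gen(eval, Vl, Q)) {
      double rc = arma::rcond(Vl);
      if (rc > 1e-3) {  // keep eigen route only when well-conditioned
        V = Vl;
        Vinv = arma::inv(Vl);
        use_eig = true;
      }
    }
  }

  const arma::mat& get(double t) {
    auto it = cache.find(t);
    if (it != cache.end()) return it->second;
    arma::mat P;
    if (use_eig) {
      P = arma::real(V * arma::diagmat(arma::exp(eval * t)) * Vinv);
      P.clamp(0.0, 1.0);
    } else {
      P = arma::expmat(Q * t);
    }
    return cache.emplace(t, std::move(P)).first->second;
  }
};

}  // namespace

// edge: E x 2 matrix of 1-based node indices (parent, child), in postorder.
// tip_state: length n_tip, 1-based state index, 0 = ambiguous (all states).
// Returns the k per-state log partial likelihoods at the root.
// [[Rcpp::export(name = ".mk_root_logpartials")]]
arma::vec mk_root_logpartials(const arma::imat& edge,
                              const arma::vec& edge_length,
                              const arma::ivec& tip_state,
                              const arma::mat& Q) {
  const int k = Q.n_rows;
  const int n_tip = tip_state.n_elem;
  const int n_node = edge.max();
  arma::mat L(n_node, k, arma::fill::ones);
  arma::vec logscale(n_node, arma::fill::zeros);
  for (int t = 0; t < n_tip; ++t) {
    if (tip_state(t) > 0) {
      L.row(t).zeros();
      L(t, tip_state(t) - 1) = 1.0;
    }
  }
  PCache pc(Q);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const arma::mat& P = pc.get(edge_length(e));
    arma::rowvec contrib = L.row(child) * P.t();  // P %*% L_child, as row
    L.row(parent) %= contrib;
    logscale(parent) += logscale(child);
    double m = L.row(parent).max();
    if (m > 0 && (m < 1e-12 || m > 1e12)) {
      L.row(parent) /= m;
      logscale(parent) += std::log(m);
    }
  }
  const int root = n_tip;  // ape convention: root is node n_tip + 1
  arma::vec out(k);
  for (int s = 0; s < k; ++s)
    out(s) = (L(root, s) > 0 ? std::log(L(root, s)) : -arma::datum::inf) +
             logscale(root);
  return out;
}

// Conditional (downward) partial likelihoods for every node, row-normalized,
// plus the per-edge transition matrices. Used by the marginal reconstruction.
// [[Rcpp::export(name = ".mk_down_partials")]]
Rcpp::List mk_down_partials(const arma::imat& edge,
                            const arma::vec& edge_length,
                            const arma::ivec& tip_state,
                            const arma::mat& Q) {
  const int k = Q.n_rows;
  const int n_tip = tip_state.n_elem;
  const int n_node = edge.max();
  arma::mat L(n_node, k, arma::fill::ones);
  arma::vec logscale(n_node, arma::fill::zeros);
  arma::cube P(k, k, edge.n_rows);
  for (int t = 0; t < n_tip; ++t) {
    if (tip_state(t) > 0) {
      L.row(t).zeros();
      L(t, tip_state(t) - 1) = 1.0;
    }
  }
  PCache pc(Q);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    P.slice(e) = pc.get(edge_length(e));
    arma::rowvec contrib = L.row(child) * P.slice(e).t();
    L.row(parent) %= contrib;
    logscale(parent) += logscale(child);
    double m = L.row(parent).max();
    if (m > 0) {
      L.row(parent) /= m;
      logscale(parent) += std::log(m);
    }
  }
  return Rcpp::List::create(Rcpp::Named("L") = L,
                            Rcpp::Named("logscale") = logscale,
                            Rcpp::Named("P") = P);
}
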