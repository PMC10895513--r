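// Constrained Gaussian graphical model fitting by iterative proportional
// scaling (IPS) over edge cliques, plus the greedy stepwise BIC search.
// The concentration matrix K is fitted so that the implied covariance
// inv(K) matches the sample correlation matrix S on the diagonal and on
// every linked pair, with K_ij = 0 on non-edges.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One IPS pass structure: edges of the current graph plus singleton
// cliques for isolated vertices (their marginal variance is otherwise
// never fitted).
static void graph_edges(const umat& adj, std::vector<std::pair<int, int> >& edges,
                        std::vector<int>& isolated) {
  const int p = adj.n_rows;
  edges.clear();
  isolated.clear();
  for (int i = 0; i < p; ++i) {
    bool any = false;
    for (int j = 0; j < p; ++j) {
      if (i != j && adj(i, j)) {
        any = true;
        if (j > i) edges.push_back(std::make_pair(i, j));
      }
    }
    if (!any) isolated.push_back(i);
  }
}

// Core IPS loop. K must be symmetric, zero on non-edges, and positive
// definite on entry. Returns true on convergence; iters reports the number
// of full sweeps used. Throws (std::runtime_error) if K leaves the PD cone.
static bool ips_core(const mat& S, const umat& adj, mat& K,
                     double tol, int maxit, int& iters) {
  std::vector<std::pair<int, int> > edges;
  std::vector<int> isolated;
  graph_edges(adj, edges, isolated);

  // Isolated vertices: single exact update, never revisited.
  for (size_t a = 0; a < isolated.size(); ++a) {
    int i = isolated[a];
    K(i, i) = 1.0 / S(i, i);
  }
  if (edges.empty()) { iters = 1; return true; }

  mat Sigma;
  for (iters = 1; iters <= maxit; ++iters) {
    double maxchg = 0.0;
    for (size_t e = 0; e < edges.size(); ++e) {
      const int i = edges[e].first, j = edges[e].second;
      if (!inv_sympd(Sigma, K))
        throw std::runtime_error("concentration matrix left the positive-definite cone");
      mat Scc(2, 2), Wcc(2, 2);
      Scc(0, 0) = S(i, i); Scc(1, 1) = S(j, j);
      Scc(0, 1) = Scc(1, 0) = S(i, j);
      Wcc(0, 0) = Sigma(i, i); Wcc(1, 1) = Sigma(j, j);
      Wcc(0, 1) = Wcc(1, 0) = Sigma(i, j);
      mat D = inv(Scc) - inv(Wcc);
      K(i, i) += D(0, 0);
      K(j, j) += D(1, 1);
      K(i, j) += D(0, 1);
      K(j, i) = K(i, j);
      double chg = abs(D).max();
      if (chg > maxchg) maxchg = chg;
    }
    // tolerance is relative to the scale of K so that fits on repaired,
    // near-singular correlation matrices (huge concentrations) terminate
    if (maxchg < tol * std::max(1.0, abs(K).max())) return true;
  }
  iters = maxit;
  return false;
}

static int count_edges(const umat& adj) {
  int m = 0;
  const int p = adj.n_rows;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j)
      if (adj(i, j)) ++m;
  return m;
}

// Profile log-likelihood of the Gaussian model at concentration K:
// (n/2) (log det K - trace(S K)), additive constant dropped.
static double gauss_loglik(const mat& K, const mat& S, double n) {
  double ld, sign;
  log_det(ld, sign, K);
  return 0.5 * n * (ld - accu(S % K));
}

// Fit with a warm start; falls back to the identity start if the warm
// start is not usable. Returns false when no convergent fit was obtained.
// The saturated graph is closed form (K = inv(S)), which also keeps the
// search usable on repaired, nearly singular correlation matrices where
// IPS would converge too slowly toward the exploding concentrations.
static bool safe_ips(const mat& S, const umat& adj, mat& K,
                     double tol, int maxit, int& iters) {
  const int p = S.n_rows;
  if (count_edges(adj) == p * (p - 1) / 2) {
    iters = 1;
    return inv_sympd(K, S);
  }
  mat K0 = K;
  try {
    if (ips_core(S, adj, K, tol, maxit, iters)) return true;
  } catch (...) {
    // fall through to cold start
  }
  K = eye(size(S));
  try {
    return ips_core(S, adj, K, tol, maxit, iters);
  } catch (...) {
    return false;
  }
}

// [[Rcpp::export]]
Rcpp::List ips_ggm_cpp(const arma::mat& S, const arma::umat& adj,
                       Rcpp::Nullable<Rcpp::NumericMatrix> K0,
                       double n, double tol, int maxit) {
  mat K;
  if (K0.isNotNull()) {
    K = Rcpp::as<mat>(K0.get());
  } else {
    K = eye(size(S));
  }
  int iters = 0;
  bool conv = false;
  std::string err;
  try {
    conv = ips_core(S, adj, K, tol, maxit, iters);
  } catch (std::exception& ex) {
    err = ex.what();
  }
  return Rcpp::List::create(
    Rcpp::Named("K") = K,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("loglik") = conv ? gauss_loglik(K, S, n) : NA_REAL,
    Rcpp::Named("error") = err);
}

// Greedy stepwise search over single-edge additions and removals.
// Ties within 1e-10 break toward removal, then lexicographic edge order
// (guaranteed by evaluating removals first, in order, and only accepting a
// strictly better candidate).
// [[Rcpp::export]]
Rcpp::List ggm_stepwise_cpp(const arma::mat& S, double n, arma::umat adj,
                            int max_sweeps, double tol, int maxit) {
  const int p = S.n_rows;
  const double logn = std::log(n);
  const double tie = 1e-10;

  mat K = eye(p, p);
  int iters = 0;
  if (!safe_ips(S, adj, K, tol, maxit, iters))
    Rcpp::stop("initial constrained fit did not converge");
  int m = count_edges(adj);
  double bic_cur = -2.0 * gauss_loglik(K, S, n) + m * logn;

  std::vector<double> bic_trace;
  bic_trace.push_back(bic_cur);

  int sweeps = 0;
  bool stabilized = false;
  while (sweeps < max_sweeps) {
    ++sweeps;
    double best_bic = datum::inf;
    int best_i = -1, best_j = -1;
    mat best_K;
    // pass 0: removals, pass 1: additions; each lexicographic in (i, j)
    for (int pass = 0; pass < 2; ++pass) {
      for (int i = 0; i < p; ++i) {
        for (int j = i + 1; j < p; ++j) {
          const bool present = adj(i, j) != 0;
          if ((pass == 0) != present) continue;
          umat adj2 = adj;
          adj2(i, j) = adj2(j, i) = present ? 0 : 1;
          mat K2 = K;
          if (present) { K2(i, j) = 0.0; K2(j, i) = 0.0; }
          int it2 = 0;
          if (!safe_ips(S, adj2, K2, tol, maxit, it2)) continue;
          const int m2 = m + (present ? -1 : 1);
          const double b = -2.0 * gauss_loglik(K2, S, n) + m2 * logn;
          if (b < best_bic - tie) {
            best_bic = b;
            best_i = i;
            best_j = j;
            best_K = K2;
          }
        }
      }
    }
    if (best_i < 0 || best_bic >= bic_cur - tie) {
      stabilized = true;
      break;
    }
    const bool was_present = adj(best_i, best_j) != 0;
    adj(best_i, best_j) = adj(best_j, best_i) = was_present ? 0 : 1;
    m += was_present ? -1 : 1;
    K = best_K;
    bic_cur = best_bic;
    bic_trace.push_back(bic_cur);
  }

  return Rcpp::List::create(
    Rcpp::Named("adjacency") = adj,
    Rcpp::Named("K") = K,
    Rcpp::Named("loglik") = gauss_loglik(K, S, n),
    Rcpp::Named("bic") = bic_cur,
    Rcpp::Named("n_edges") = m,
    Rcpp::Named("sweeps") = sweeps,
    Rcpp::Named("stabilized") = stabilized,
    Rcpp::Named("bic_trace") = bic_trace);
}
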