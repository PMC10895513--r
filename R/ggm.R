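# Unregularised GGM estimation: maximum-likelihood concentration matrices
# under a fixed zero pattern (iterative proportional scaling, in C++), and
# greedy stepwise BIC model selection over single-edge changes.

#' Repair an indefinite correlation matrix
#'
#' Rank correlations on ordinal data can be indefinite. Eigenvalues are
#' clipped at `eig_floor`, the matrix is reconstructed and re-standardized
#' to unit diagonal.
#'
#' @param r Correlation matrix.
#' @param eig_floor Minimum eigenvalue after repair.
#' @return Positive-definite correlation matrix.
#' @export
repair_corr <- function(r, eig_floor = 1e-6) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(r)
  v <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(r)
  (out + t(out)) / 2
}

#' Fit a Gaussian graphical model with a fixed zero pattern
#'
#' Maximum-likelihood concentration matrix `K` with `K_ij = 0` wherever
#' `adjacency_ij = 0`, matching the (repaired) correlation matrix on all
#' linked pairs and the diagonal, by iterative proportional scaling over
#' edge cliques. Convergence: maximum entrywise change in `K` per sweep
#' below `tol`.
#'
#' @param corr A `corr_matrix` (or plain matrix, in which case `n` must be
#'   given).
#' @param adjacency Symmetric 0/1 matrix, zero diagonal.
#' @param n Sample size for the log-likelihood; defaults to
#'   `corr$n_effective`.
#' @param tol Convergence tolerance on K entries. Default `1e-8`.
#' @param maxit Maximum IPS sweeps.
#' @return List with `K` (concentration matrix), `loglik`
#'   (`(n/2)(log det K - trace(S K))`, additive constant dropped) and
#'   `iterations`.
#' @export
fit_constrained_ggm <- function(corr, adjacency, n = NULL,
                                tol = 1e-8, maxit = 2000L) {
  s <- if (inherits(corr, "corr_matrix")) corr$values else as.matrix(corr)
  if (is.null(n)) {
    if (!inherits(corr, "corr_matrix"))
      stop("fit_constrained_ggm: n is required when corr is a plain matrix")
    n <- corr$n_effective
  }
  adjacency <- as.matrix(adjacency)
  if (!isTRUE(all.equal(adjacency, t(adjacency))) || any(diag(adjacency) != 0))
    stop("fit_constrained_ggm: adjacency must be symmetric with zero diagonal")
  if (!all(adjacency %in% c(0, 1)))
    stop("fit_constrained_ggm: adjacency must be 0/1")
  s <- repair_corr(s)
  res <- ips_ggm_cpp(s, matrix(as.integer(adjacency), nrow(s)), NULL,
                     as.numeric(n), tol, as.integer(maxit))
  if (nzchar(res$error))
    stop("fit_constrained_ggm: ", res$error)
  if (!res$converged)
    stop("fit_constrained_ggm: IPS did not converge in ", res$iterations,
         " sweeps (tol = ", tol, ")")
  K <- res$K
  dimnames(K) <- dimnames(s)
  list(K = K, loglik = res$loglik, iterations = res$iterations)
}

#' Partial correlations from a concentration matrix
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` for `i != j`; zero diagonal.
#'
#' @param K Symmetric positive-definite concentration matrix.
#' @return Partial-correlation matrix.
#' @export
precision_to_partial <- function(K) {
  K <- as.matrix(K)
  if (any(diag(K) <= 0))
    stop("precision_to_partial: non-positive diagonal")
  d <- 1 / sqrt(diag(K))
  w <- -K * outer(d, d)
  diag(w) <- 0
  dimnames(w) <- dimnames(K)
  (w + t(w)) / 2
}

#' BIC of a fitted GGM
#'
#' `-2 loglik + n_edges log(n)`; the free-parameter count is the number of
#' edges (correlation-scale model; the diagonal is constant across models
#' and not counted).
#'
#' @param loglik Model log-likelihood.
#' @param n_edges Number of edges.
#' @param n Sample size (>= 2).
#' @return BIC value.
#' @export
ggm_bic <- function(loglik, n_edges, n) {
  if (n < 2) stop("ggm_bic: n must be >= 2")
  -2 * loglik + n_edges * log(n)
}

#' @keywords internal
new_ggm_network <- function(weights, adjacency, labels, communities,
                            loglik, bic, n) {
  weights[adjacency == 0] <- 0
  diag(weights) <- 0
  stopifnot(max(abs(weights - t(weights))) < 1e-10,
            all(abs(weights) < 1))
  if (any((abs(weights) > 1e-10) != (adjacency == 1)))
    stop("ggm_network: weights and adjacency disagree")
  dimnames(weights) <- dimnames(adjacency) <- list(labels, labels)
  structure(list(weights = weights, adjacency = adjacency, labels = labels,
                 communities = communities, loglik = loglik, bic = bic,
                 n = n, n_edges = sum(adjacency[upper.tri(adjacency)])),
            class = "ggm_network")
}

# Start graph: edges whose saturated-model partial correlations are
# significant by Fisher-z test at sig_alpha (n - p - 1 effective df for
# p - 2 conditioning variables).
significance_start <- function(s, n, sig_alpha) {
  p <- nrow(s)
  if (n - p - 1 <= 0) return(matrix(0L, p, p))
  w <- precision_to_partial(solve(s))
  w <- pmin(pmax(w, -0.999999), 0.999999)
  z <- abs(atanh(w)) * sqrt(n - p - 1)
  adj <- matrix(as.integer(z > qnorm(1 - sig_alpha / 2)), p, p)
  diag(adj) <- 0L
  adj
}

#' Select a GGM by greedy stepwise BIC search
#'
#' From a start graph, repeatedly evaluates all single-edge additions and
#' removals (each candidate refitted by constrained maximum likelihood),
#' applies the change with the largest BIC decrease and stops when no
#' change decreases BIC. Ties within `1e-10` break toward removal, then
#' lexicographic edge order. The default start graph keeps the edges whose
#' saturated-model partial correlations are significant at
#' `sig_alpha = 0.01` (Fisher-z test), which typically lands near the BIC
#' optimum; `start = "empty"` begins from the empty graph.
#'
#' @param corr A `corr_matrix`.
#' @param start `"sig"` (default) or `"empty"`, or an explicit 0/1
#'   adjacency matrix.
#' @param sig_alpha Significance level for the start graph.
#' @param max_sweeps Maximum number of applied changes. Default 500.
#' @param communities Optional named community vector carried into the
#'   result.
#' @param tol,maxit IPS settings per candidate fit.
#' @return A `ggm_network`: partial-correlation `weights`, `adjacency`,
#'   `labels`, `communities`, `loglik`, `bic`, `n`, `n_edges`.
#' @export
select_ggm <- function(corr, start = c("sig", "empty"), sig_alpha = 0.01,
                       max_sweeps = 500L, communities = NULL,
                       tol = 1e-8, maxit = 2000L) {
  stopifnot(inherits(corr, "corr_matrix"))
  s <- repair_corr(corr$values)
  n <- corr$n_effective
  p <- nrow(s)
  if (is.matrix(start)) {
    adj0 <- matrix(as.integer(start), p, p)
  } else {
    start <- match.arg(start)
    adj0 <- if (start == "sig") significance_start(s, n, sig_alpha)
            else matrix(0L, p, p)
  }
  res <- ggm_stepwise_cpp(s, as.numeric(n), adj0, as.integer(max_sweeps),
                          tol, as.integer(maxit))
  if (!res$stabilized)
    stop("select_ggm: stepwise search did not stabilize in ", res$sweeps,
         " sweeps; BIC trace: ",
         paste(sprintf("%.2f", utils::tail(res$bic_trace, 5)), collapse = ", "))
  w <- precision_to_partial(res$K)
  new_ggm_network(w, res$adjacency, corr$labels,
                  communities, res$loglik, res$bic, n)
}

#' Density and edge-weight summary of a network
#'
#' @param net A `ggm_network`.
#' @return List: `n_edges`, `n_possible` (`p(p-1)/2`), `density`,
#'   `mean_abs_weight` (over nonzero edges; 0 with `empty = TRUE` when
#'   there are none), `min_abs_nonzero`, `max_abs`, `empty`.
#' @export
density_stats <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  p <- length(net$labels)
  if (p < 2) stop("density_stats: need at least 2 nodes")
  n_possible <- p * (p - 1) / 2
  wu <- net$weights[upper.tri(net$weights)]
  nz <- wu[wu != 0]
  empty <- length(nz) == 0
  list(n_edges = net$n_edges,
       n_possible = n_possible,
       density = net$n_edges / n_possible,
       mean_abs_weight = if (empty) 0 else mean(abs(nz)),
       min_abs_nonzero = if (empty) NA_real_ else min(abs(nz)),
       max_abs = if (empty) 0 else max(abs(nz)),
       empty = empty)
}

#' @export
print.ggm_network <- function(x, ...) {
  ds <- density_stats(x)
  cat("GGM network:", length(x$labels), "nodes,", x$n_edges, "edges",
      sprintf("(density %.2f, mean |w| %.3f), BIC %.1f, n = %d\n",
              ds$density, ds$mean_abs_weight, x$bic, x$n))
  invisible(x)
}

#' Edge list of a network
#' @param net A `ggm_network`.
#' @return data.frame with node1, node2, weight for every edge.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  ut <- which(upper.tri(net$weights) & net$adjacency == 1, arr.ind = TRUE)
  data.frame(node1 = net$labels[ut[, 1]],
             node2 = net$labels[ut[, 2]],
             weight = net$weights[ut],
             stringsAsFactors = FALSE)
}
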