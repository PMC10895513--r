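# Permutation network comparison test (global strength invariance and
# network structure invariance) and the split-half replication driver.

#' Global strength of a network
#'
#' The weighted sum of all edges: sum of absolute weights over unique node
#' pairs.
#'
#' @param net A `ggm_network`.
#' @return Numeric scalar.
#' @export
global_strength <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  sum(abs(net$weights)) / 2
}

#' Permutation network comparison test
#'
#' Estimates a network per group, takes the observed absolute difference in
#' global strength and the maximum absolute edge-weight difference, then
#' builds their null distributions by randomly reassigning rows to two
#' groups of the original sizes and re-estimating both networks per
#' permutation. P-values use the add-one formula
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`, so they are never exactly
#' zero.
#'
#' @param table_a,table_b `symptom_table`s over identical node sets.
#' @param config A [pipeline_config()] with the selection settings.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return An `nct_result`: observed statistics, p-values, permutation
#'   distributions, `n_perm`, `seed`.
#' @export
nct <- function(table_a, table_b, config = pipeline_config(),
                n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(table_a, "symptom_table"),
            inherits(table_b, "symptom_table"))
  if (!identical(table_a$node_labels, table_b$node_labels))
    stop("nct: the two tables must share an identical node set")
  if (n_perm < 100) stop("nct: n_perm must be >= 100")
  method <- resolve_corr_method(config, table_a)
  net_a <- refit_once(table_a$values, config, table_a$communities, method)
  net_b <- refit_once(table_b$values, config, table_b$communities, method)
  obs_strength <- abs(global_strength(net_a) - global_strength(net_b))
  obs_maxedge <- max(abs(net_a$weights - net_b$weights))

  pooled <- rbind(table_a$values, table_b$values)
  na <- nrow(table_a$values)
  ntot <- nrow(pooled)
  set.seed(as.integer(seed))
  perm_strength <- rep(NA_real_, n_perm)
  perm_maxedge <- rep(NA_real_, n_perm)
  failed <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(ntot, na)
    pa <- tryCatch(refit_once(pooled[idx, , drop = FALSE], config,
                              method = method),
                   error = function(e) NULL)
    pb <- tryCatch(refit_once(pooled[-idx, , drop = FALSE], config,
                              method = method),
                   error = function(e) NULL)
    if (is.null(pa) || is.null(pb)) {
      failed <- failed + 1L
      next
    }
    perm_strength[k] <- abs(global_strength(pa) - global_strength(pb))
    perm_maxedge[k] <- max(abs(pa$weights - pb$weights))
  }
  if (failed > 0.1 * n_perm)
    stop("nct: ", failed, " of ", n_perm, " permutations failed (> 10%)")
  ps <- perm_strength[!is.na(perm_strength)]
  pe <- perm_maxedge[!is.na(perm_maxedge)]
  eps <- 1e-12
  structure(list(observed_strength_diff = obs_strength,
                 observed_max_edge_diff = obs_maxedge,
                 p_strength = (1 + sum(ps >= obs_strength - eps)) / (1 + length(ps)),
                 p_structure = (1 + sum(pe >= obs_maxedge - eps)) / (1 + length(pe)),
                 perm_strength = ps, perm_maxedge = pe,
                 n_perm = length(ps), n_failed = failed,
                 network_a = net_a, network_b = net_b,
                 seed = as.integer(seed)),
            class = "nct_result")
}

#' Split-half replication test
#'
#' Halves the sample at random (split sizes differing by at most one) and
#' runs the network comparison test on the halves; a non-significant result
#' indicates that the estimated structure replicates across halves.
#'
#' @param table A `symptom_table` with at least 40 rows.
#' @param config A [pipeline_config()].
#' @param n_perm Permutations for the comparison test.
#' @param seed Integer seed (drives both the split and the permutations).
#' @return An `nct_result` (with the row indices of the first half attached
#'   as `split_idx`).
#' @export
split_half_replication <- function(table, config = pipeline_config(),
                                   n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(table, "symptom_table"))
  n <- nrow(table$values)
  if (n < 40) stop("split_half_replication: need at least 40 rows")
  set.seed(as.integer(seed))
  idx <- sample.int(n, floor(n / 2))
  half_a <- new_symptom_table(table$values[idx, , drop = FALSE],
                              table$node_labels, table$communities,
                              table$scale, seed = table$seed)
  half_b <- new_symptom_table(table$values[-idx, , drop = FALSE],
                              table$node_labels, table$communities,
                              table$scale, seed = table$seed)
  out <- nct(half_a, half_b, config, n_perm = n_perm, seed = seed + 1L)
  out$split_idx <- idx
  out
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf(paste0("Network comparison test (%d permutations):\n",
                     "  global strength diff = %.3f (p = %.3f)\n",
                     "  max edge diff        = %.3f (p = %.3f)\n"),
              x$n_perm, x$observed_strength_diff, x$p_strength,
              x$observed_max_edge_diff, x$p_structure))
  invisible(x)
}
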