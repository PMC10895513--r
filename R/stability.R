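# Stability diagnostics: nonparametric edge-weight bootstrap with
# percentile confidence intervals, case-dropping subset bootstrap of
# centralities, the correlation-stability (CS) coefficient, and
# bootstrapped difference tests.

# Correlation method for an estimation run. Rank correlations are the
# study condition for ordinal symptom data; on a fully continuous table
# (e.g. latent-scale simulations) the rank transform would only bias the
# estimand, so "auto" falls back to the product-moment correlation there.
resolve_corr_method <- function(config, table) {
  method <- config$corr_method
  if (is.null(method) || method == "auto") {
    if (inherits(table, "symptom_table") &&
        all(table$scale == "continuous")) "pearson" else "spearman"
  } else {
    match.arg(method, c("spearman", "pearson"))
  }
}

# One full re-estimation: complete-case correlations, then stepwise BIC
# selection with the settings carried in config.
refit_once <- function(values, config, communities = NULL,
                       method = "spearman") {
  cm <- corr_matrix_of(values, method = method)
  select_ggm(cm, start = config$start, sig_alpha = config$sig_alpha,
             max_sweeps = config$max_sweeps, communities = communities)
}

#' Bootstrap edge-weight confidence intervals
#'
#' Nonparametric row-resampling with full re-estimation (Spearman
#' correlations, then stepwise BIC selection) per replicate; percentile
#' 2.5/97.5% intervals per node pair, edges absent in a replicate
#' contributing weight zero. Replicates whose estimation fails are skipped
#' and counted; more than 10% failures is an error.
#'
#' @param table A `symptom_table` (all of its columns enter the network).
#' @param config A [pipeline_config()] carrying the selection settings.
#' @param B Number of bootstrap replicates (>= 100). Default 1000.
#' @param seed Integer seed.
#' @return An `edge_bootstrap`: `observed` network, `edges` data.frame
#'   (node1, node2, observed, boot_mean, ci_low, ci_high), `replicates`
#'   (B x n_pairs matrix of replicate weights, columns named
#'   `"node1--node2"`), `B`, `n_failed`, `seed`.
#' @export
bootstrap_edges <- function(table, config = pipeline_config(), B = 1000L,
                            seed = 1L) {
  stopifnot(inherits(table, "symptom_table"))
  if (B < 100) stop("bootstrap_edges: B must be >= 100")
  method <- resolve_corr_method(config, table)
  observed <- refit_once(table$values, config, table$communities, method)
  p <- length(observed$labels)
  ut <- which(upper.tri(observed$weights), arr.ind = TRUE)
  pair_names <- paste0(observed$labels[ut[, 1]], "--", observed$labels[ut[, 2]])
  n <- nrow(table$values)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, B, nrow(ut),
                 dimnames = list(NULL, pair_names))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(refit_once(table$values[idx, , drop = FALSE], config,
                                 method = method),
                      error = function(e) NULL)
    if (is.null(net_b)) {
      failed <- failed + 1L
      next
    }
    reps[b, ] <- net_b$weights[ut]
  }
  if (failed > 0.1 * B)
    stop("bootstrap_edges: ", failed, " of ", B, " replicates failed (> 10%)")
  ok <- complete.cases(reps)
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile, probs = c(0.025, 0.975))
  edges <- data.frame(node1 = observed$labels[ut[, 1]],
                      node2 = observed$labels[ut[, 2]],
                      observed = observed$weights[ut],
                      boot_mean = colMeans(reps[ok, , drop = FALSE]),
                      ci_low = ci[1, ], ci_high = ci[2, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(observed = observed, edges = edges,
                 replicates = reps[ok, , drop = FALSE],
                 B = B, n_failed = failed, seed = as.integer(seed)),
            class = "edge_bootstrap")
}

# centrality of a network as a named vector, by kind
centrality_by_kind <- function(net, kind, communities = NULL) {
  switch(kind,
         strength = node_centrality(net, signed = FALSE),
         expected_influence = node_centrality(net, signed = TRUE),
         bridge_strength = bridge_centrality(
           net, communities = if (is.null(communities)) net$communities
                              else communities, signed = FALSE),
         stop("unknown centrality kind: ", kind))
}

#' Case-dropping subset bootstrap of centrality
#'
#' For each drop proportion, draws `B` subsamples without replacement of
#' the retained fraction, re-estimates the network and the chosen
#' centrality index, and records the correlation with the full-sample
#' centrality.
#'
#' @param table A `symptom_table`.
#' @param config A [pipeline_config()].
#' @param drop_proportions Grid of drop proportions within (0, 0.95\].
#'   Default `seq(0.05, 0.75, by = 0.10)`.
#' @param B Subsamples per proportion (>= 100). Default 500.
#' @param centrality_kind `"strength"` (default), `"expected_influence"` or
#'   `"bridge_strength"`.
#' @param seed Integer seed.
#' @return A `casedrop_result`: `drop_proportions`, `correlations`
#'   (B x length(grid) matrix), `cs` (CS coefficient at the conventional
#'   0.7 floor / 95% certainty), `centrality_kind`, `full` (full-sample
#'   centralities), `seed`.
#' @export
casedrop_bootstrap <- function(table, config = pipeline_config(),
                               drop_proportions = seq(0.05, 0.75, by = 0.10),
                               B = 500L,
                               centrality_kind = "strength",
                               seed = 1L) {
  stopifnot(inherits(table, "symptom_table"))
  if (B < 100) stop("casedrop_bootstrap: B must be >= 100")
  if (any(drop_proportions <= 0 | drop_proportions > 0.95))
    stop("casedrop_bootstrap: drop proportions must lie in (0, 0.95]")
  method <- resolve_corr_method(config, table)
  full_net <- refit_once(table$values, config, table$communities, method)
  c0 <- centrality_by_kind(full_net, centrality_kind, table$communities)
  n <- nrow(table$values)
  set.seed(as.integer(seed))
  cors <- matrix(NA_real_, B, length(drop_proportions),
                 dimnames = list(NULL, paste0("drop_", drop_proportions)))
  failed <- 0L
  for (g in seq_along(drop_proportions)) {
    m <- max(3L, round((1 - drop_proportions[g]) * n))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      net_b <- tryCatch(refit_once(table$values[idx, , drop = FALSE], config,
                                   method = method),
                        error = function(e) NULL)
      if (is.null(net_b)) {
        failed <- failed + 1L
        next
      }
      cb <- centrality_by_kind(net_b, centrality_kind, table$communities)
      cors[b, g] <- suppressWarnings(cor(c0, cb))
    }
  }
  if (failed > 0.1 * B * length(drop_proportions))
    stop("casedrop_bootstrap: more than 10% of replicates failed")
  res <- structure(list(drop_proportions = drop_proportions,
                        correlations = cors,
                        centrality_kind = centrality_kind,
                        full = c0, n_failed = failed,
                        seed = as.integer(seed)),
                   class = "casedrop_result")
  res$cs <- cs_coefficient(res)
  res
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion at which at least `certainty` of the
#' subsample centralities correlate at least `cor_floor` with the
#' full-sample centralities; zero when no proportion qualifies. Values
#' above 0.25 indicate a stable index, above 0.5 preferred.
#'
#' @param result A `casedrop_result`.
#' @param cor_floor Correlation floor. Default 0.7.
#' @param certainty Required share of qualifying subsamples. Default 0.95.
#' @return CS coefficient (drawn from the tested grid, or 0).
#' @export
cs_coefficient <- function(result, cor_floor = 0.7, certainty = 0.95) {
  stopifnot(inherits(result, "casedrop_result"))
  if (!length(result$drop_proportions))
    stop("cs_coefficient: empty case-drop result")
  share <- apply(result$correlations, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(0)
    mean(col >= cor_floor)
  })
  ok <- share >= certainty
  if (!any(ok)) return(0)
  max(result$drop_proportions[ok])
}

#' Bootstrapped difference test
#'
#' Two items (edges, or node strengths derived from the same replicates)
#' differ significantly when the 95% percentile interval of their
#' replicate-wise difference excludes zero.
#'
#' @param boot An `edge_bootstrap`.
#' @param item_a,item_b For `what = "edge"`, pair names `"node1--node2"`
#'   (order within the pair is normalized); for `what = "strength"`, node
#'   labels.
#' @param what `"edge"` (default) or `"strength"`.
#' @param level Interval coverage. Default 0.95.
#' @return List: `significant`, `ci_low`, `ci_high`, `diff_observed`.
#' @export
difference_test <- function(boot, item_a, item_b, what = c("edge", "strength"),
                            level = 0.95) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  what <- match.arg(what)
  a2 <- (1 - level) / 2
  if (what == "edge") {
    norm_pair <- function(it) {
      parts <- strsplit(it, "--", fixed = TRUE)[[1]]
      cand <- c(paste0(parts[1], "--", parts[2]),
                if (length(parts) == 2) paste0(parts[2], "--", parts[1]))
      hit <- cand[cand %in% colnames(boot$replicates)]
      if (!length(hit)) stop("difference_test: unknown edge '", it, "'")
      hit[1]
    }
    va <- boot$replicates[, norm_pair(item_a)]
    vb <- boot$replicates[, norm_pair(item_b)]
    oa <- boot$observed$weights[strsplit(norm_pair(item_a), "--")[[1]][1],
                                strsplit(norm_pair(item_a), "--")[[1]][2]]
    ob <- boot$observed$weights[strsplit(norm_pair(item_b), "--")[[1]][1],
                                strsplit(norm_pair(item_b), "--")[[1]][2]]
  } else {
    labs <- boot$observed$labels
    if (!all(c(item_a, item_b) %in% labs))
      stop("difference_test: unknown node label")
    strength_reps <- function(node) {
      cols <- grep(paste0("(^", node, "--)|(--", node, "$)"),
                   colnames(boot$replicates))
      rowSums(abs(boot$replicates[, cols, drop = FALSE]))
    }
    va <- strength_reps(item_a)
    vb <- strength_reps(item_b)
    s <- node_centrality(boot$observed)
    oa <- s[[item_a]]
    ob <- s[[item_b]]
  }
  d <- va - vb
  ci <- quantile(d, probs = c(a2, 1 - a2), names = FALSE)
  list(significant = ci[1] > 0 || ci[2] < 0,
       ci_low = ci[1], ci_high = ci[2], diff_observed = oa - ob)
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat("Edge bootstrap: B =", x$B, "(", x$n_failed, "failed ), ",
      nrow(x$edges), "node pairs\n")
  invisible(x)
}

#' @export
print.casedrop_result <- function(x, ...) {
  cat("Case-dropping bootstrap (", x$centrality_kind, "): CS =", x$cs, "\n")
  invisible(x)
}
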