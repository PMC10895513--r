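# Synthetic ground truth: sparse partial-correlation networks over mother /
# father / child communities, and ordinal family symptom data sampled from
# the implied latent multivariate normal.

# Ten postnatal depression items; the study network uses the first nine
# (the reverse-coded "funny side" item is the one dropped by redundancy
# review), so n_mother = 9 picks up exactly the analysed set.
epds_item_pool <- c("sad", "cry", "guilt", "selfharm", "insomnia",
                    "anhedonia", "panic", "worry", "overwhelm", "laugh")

parent_labels <- function(prefix, n) {
  if (n <= length(epds_item_pool)) {
    paste0(prefix, "_", epds_item_pool[seq_len(n)])
  } else {
    c(paste0(prefix, "_", epds_item_pool),
      paste0(prefix, "_item", seq_len(n - length(epds_item_pool)) +
               length(epds_item_pool)))
  }
}

#' Construct a ground-truth family symptom network
#'
#' Builds a sparse partial-correlation matrix over two parent communities
#' (and optionally a child factor node) with a known edge set: within-parent
#' edges are sampled at a given density, cross-parent edges are exactly the
#' designated bridge pairs, and the child node (when requested) links only to
#' the named parent symptoms. Off-diagonals are uniformly shrunk (factor
#' 0.95 per step, at most 100 steps) until the implied precision matrix is
#' positive definite with minimum eigenvalue at least `1e-6`, preserving the
#' sparsity pattern.
#'
#' @param n_mother,n_father Number of mother / father symptom nodes (>= 3).
#' @param within_density Probability that any within-community pair is an
#'   edge, in (0, 1].  Zero gives an empty within-community graph.
#' @param bridge_pairs List of two-element character vectors naming the
#'   cross-community edges (the designated bridge edges), or `NULL`.
#' @param weight_low,weight_high Uniform range for within-community edge
#'   weights, `0 < weight_low <= weight_high < 1`.
#' @param bridge_weight_low,bridge_weight_high Uniform range for bridge edge
#'   weights; defaults to the within range.
#' @param child_links Named numeric vector of partial correlations from the
#'   child factor node to parent symptoms (names must be parent labels), or
#'   `NULL` for a parents-only network.
#' @param seed Integer seed; all randomness in the construction flows from it.
#' @return A `true_network` object: list with `pcor` (symmetric, zero
#'   diagonal), `node_labels`, `communities` (named character vector with
#'   values `"mother"`, `"father"`, `"child"`), `bridge_edges`, `seed`.
#' @examples
#' tn <- build_true_network(4, 4, within_density = 0.4,
#'                          bridge_pairs = list(c("m_guilt", "f_guilt")),
#'                          weight_low = 0.1, weight_high = 0.3, seed = 1)
#' tn$pcor["m_guilt", "f_guilt"] != 0
#' @export
build_true_network <- function(n_mother, n_father, within_density,
                               bridge_pairs = NULL,
                               weight_low = 0.04, weight_high = 0.41,
                               bridge_weight_low = weight_low,
                               bridge_weight_high = weight_high,
                               child_links = NULL, seed = 1L) {
  if (n_mother < 3 || n_father < 3)
    stop("build_true_network: n_mother and n_father must both be >= 3")
  if (within_density < 0 || within_density > 1)
    stop("build_true_network: within_density must lie in [0, 1]")
  check_range <- function(lo, hi, what) {
    if (!(lo > 0 && lo <= hi && hi < 1))
      stop("build_true_network: ", what,
           " weight bounds must satisfy 0 < low <= high < 1")
  }
  if (within_density > 0) check_range(weight_low, weight_high, "within")
  if (length(bridge_pairs)) check_range(bridge_weight_low, bridge_weight_high, "bridge")

  labels <- c(parent_labels("m", n_mother), parent_labels("f", n_father))
  communities <- c(rep("mother", n_mother), rep("father", n_father))
  if (!is.null(child_links)) {
    labels <- c(labels, "child_emotional")
    communities <- c(communities, "child")
  }
  names(communities) <- labels
  p <- length(labels)

  set.seed(as.integer(seed))
  pcor <- matrix(0, p, p, dimnames = list(labels, labels))

  # within-community edges
  for (comm in c("mother", "father")) {
    idx <- which(communities == comm)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (runif(1) < within_density) {
          w <- runif(1, weight_low, weight_high)
          pcor[idx[a], idx[b]] <- pcor[idx[b], idx[a]] <- w
        }
      }
    }
  }

  # designated cross-community (bridge) edges
  bridge_edges <- list()
  for (pr in bridge_pairs) {
    if (length(pr) != 2 || !all(pr %in% labels))
      stop("build_true_network: bridge pair (", paste(pr, collapse = ", "),
           ") names an unknown node")
    if (communities[pr[1]] == communities[pr[2]])
      stop("build_true_network: bridge pair (", paste(pr, collapse = ", "),
           ") does not cross communities")
    w <- runif(1, bridge_weight_low, bridge_weight_high)
    pcor[pr[1], pr[2]] <- pcor[pr[2], pr[1]] <- w
    bridge_edges[[length(bridge_edges) + 1L]] <- pr
  }

  # child factor links (cross-community by construction)
  if (!is.null(child_links)) {
    if (is.null(names(child_links)) || !all(names(child_links) %in% labels[communities != "child"]))
      stop("build_true_network: child_links must be named with parent node labels")
    for (nm in names(child_links)) {
      pcor[nm, "child_emotional"] <- pcor["child_emotional", nm] <- child_links[[nm]]
      bridge_edges[[length(bridge_edges) + 1L]] <- c(nm, "child_emotional")
    }
  }

  # shrink until the implied precision (unit diagonal, -pcor off-diagonal)
  # is positive definite with min eigenvalue >= 1e-6
  shrink <- 0L
  repeat {
    K0 <- diag(p) - pcor
    ev <- min(eigen(K0, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= 1e-6) break
    if (shrink >= 100L)
      stop("build_true_network: could not reach a positive-definite precision in 100 shrinkage steps")
    pcor <- pcor * 0.95
    shrink <- shrink + 1L
  }

  structure(list(pcor = pcor, node_labels = labels, communities = communities,
                 bridge_edges = bridge_edges, seed = as.integer(seed),
                 shrink_steps = shrink),
            class = "true_network")
}

#' Default study-condition family truth
#'
#' The 19-node population analogue of the analysed cohort networks: nine
#' symptoms per parent, within-parent density 55/72, within weights uniform
#' on the printed edge-magnitude band (0.04-0.41), six same-symptom
#' cross-parent bridge edges on the printed cross-parent band (0.04-0.09),
#' and a child emotional-difficulties factor node linked to mother guilt,
#' anhedonia, panic and sadness plus father overwhelm.
#'
#' @param seed Integer seed.
#' @param child Include the child factor node (default `TRUE`).
#' @return A `true_network` object.
#' @export
family_truth <- function(seed = 1L, child = TRUE) {
  bridges <- lapply(c("insomnia", "sad", "anhedonia", "overwhelm",
                      "selfharm", "guilt"),
                    function(s) c(paste0("m_", s), paste0("f_", s)))
  links <- if (child)
    c(m_guilt = 0.09, m_anhedonia = 0.05, m_panic = 0.04, m_sad = 0.06,
      f_overwhelm = 0.05)
  else NULL
  build_true_network(9, 9, within_density = 55 / 72,
                     bridge_pairs = bridges,
                     weight_low = 0.04, weight_high = 0.41,
                     bridge_weight_low = 0.04, bridge_weight_high = 0.09,
                     child_links = links, seed = seed)
}

#' Covariance implied by a partial-correlation matrix
#'
#' Inverts the standard GGM identity: given partial correlations `pcor`, the
#' precision on the standardized scale is `K0 = I - pcor` (unit diagonal),
#' and the returned matrix is `cov2cor(solve(K0))`, a correlation-scaled
#' covariance whose inverse `K` satisfies `-K_ij / sqrt(K_ii K_jj) = pcor_ij`
#' for all `i != j`.
#'
#' @param pcor Symmetric matrix, zero diagonal, all `|values| < 1`.
#' @return Correlation matrix (unit diagonal).
#' @export
partial_to_covariance <- function(pcor) {
  if (inherits(pcor, "true_network")) pcor <- pcor$pcor
  if (!is.matrix(pcor) || nrow(pcor) != ncol(pcor))
    stop("partial_to_covariance: pcor must be a square matrix")
  if (max(abs(pcor - t(pcor))) > 1e-12)
    stop("partial_to_covariance: pcor must be symmetric")
  if (any(abs(diag(pcor)) > 1e-12))
    stop("partial_to_covariance: pcor must have a zero diagonal")
  if (any(abs(pcor) >= 1))
    stop("partial_to_covariance: all |pcor| must be < 1")
  K0 <- diag(nrow(pcor)) - pcor
  ev <- min(eigen(K0, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("partial_to_covariance: implied precision is not positive definite")
  sigma <- solve(K0)
  sigma <- stats::cov2cor(sigma)
  dimnames(sigma) <- dimnames(pcor)
  (sigma + t(sigma)) / 2
}

#' Sample ordinal family symptom data from a ground-truth network
#'
#' Draws latent vectors from the multivariate normal implied by the truth,
#' discretizes parent nodes to the 1-4 ordinal symptom scale by fixed
#' cutpoints, and maps the child latent value (when present) to three wave
#' scores on the 0-10 subscale: `round(wave_mean + wave_scale *
#' (loading * latent + noise))`, clipped into \[0, 10\].  A binary
#' `child_female` demographic column reproducing the cohort's share of girls
#' is appended when `female_prop` is non-`NULL`.  Fully reproducible given
#' `seed`; the latent draw, the child measurement noise and the demographic
#' draw use fixed seed offsets so each sub-stream is stable.
#'
#' @param truth A `true_network`.
#' @param n_families Number of rows (>= 10).
#' @param ordinal_thresholds Three strictly increasing latent-scale cutpoints
#'   (recycled to every parent node), or a `p x 3` matrix of per-node
#'   cutpoints, or `NULL` to keep parent nodes continuous (latent scale).
#'   The default `(0.25, 1.0, 1.9)` yields right-skewed endorsement typical
#'   of postnatal depression items.
#' @param child_loadings Three factor loadings for the wave scores.
#' @param child_noise_sd Gaussian measurement noise SD per wave. The
#'   default 0.6, with loadings 0.75, puts the observed inter-wave rank
#'   correlations near 0.54 after the rounding/clipping attenuation of the
#'   0-10 scale.
#' @param wave_mean,wave_scale Location and scale mapping the latent wave
#'   value onto the 0-10 subscale.
#' @param female_prop Probability that the child is female, or `NULL` to
#'   omit the demographic column. Default 2204/4492, the cohort share.
#' @param seed Integer seed.
#' @return A `symptom_table`: list with `values` (data.frame), `node_labels`,
#'   `communities`, `scale` (per column: `"ordinal_1_4"`, `"subscale_0_10"`,
#'   `"continuous"` or `"binary"`), `missing_mask`, `seed`.
#' @export
sample_family_data <- function(truth, n_families,
                               ordinal_thresholds = c(0.25, 1.0, 1.9),
                               child_loadings = c(0.75, 0.75, 0.75),
                               child_noise_sd = 0.6,
                               wave_mean = 1.5, wave_scale = 2.0,
                               female_prop = 2204 / 4492,
                               seed = 1L) {
  stopifnot(inherits(truth, "true_network"))
  if (n_families < 10)
    stop("sample_family_data: n_families must be >= 10")
  p <- length(truth$node_labels)
  parent_idx <- which(truth$communities != "child")
  child_idx <- which(truth$communities == "child")

  if (!is.null(ordinal_thresholds)) {
    if (is.matrix(ordinal_thresholds)) {
      cuts <- ordinal_thresholds
      if (nrow(cuts) != length(parent_idx) || ncol(cuts) != 3)
        stop("sample_family_data: per-node cutpoints must be length(parents) x 3")
    } else {
      if (length(ordinal_thresholds) != 3)
        stop("sample_family_data: ordinal_thresholds must have 3 cutpoints per node")
      cuts <- matrix(ordinal_thresholds, length(parent_idx), 3, byrow = TRUE)
    }
    if (any(apply(cuts, 1, function(z) any(diff(z) <= 0))))
      stop("sample_family_data: ordinal_thresholds must be strictly increasing")
  }

  sigma <- partial_to_covariance(truth$pcor)
  seed <- as.integer(seed)
  set.seed(seed)
  latent <- matrix(rnorm(n_families * p), n_families, p) %*% chol(sigma)
  colnames(latent) <- truth$node_labels

  values <- list()
  labels <- character(0)
  comms <- character(0)
  scales <- character(0)

  for (k in seq_along(parent_idx)) {
    j <- parent_idx[k]
    nm <- truth$node_labels[j]
    if (is.null(ordinal_thresholds)) {
      col <- latent[, j]
      sc <- "continuous"
    } else {
      col <- findInterval(latent[, j], cuts[k, ]) + 1L
      sc <- "ordinal_1_4"
    }
    values[[nm]] <- col
    labels <- c(labels, nm)
    comms <- c(comms, unname(truth$communities[j]))
    scales <- c(scales, sc)
  }

  if (length(child_idx) == 1L) {
    if (length(child_loadings) != 3)
      stop("sample_family_data: child_loadings must have length 3")
    set.seed(seed + 1L)
    for (w in 1:3) {
      raw <- child_loadings[w] * latent[, child_idx] +
        rnorm(n_families, 0, child_noise_sd)
      score <- pmin(pmax(round(wave_mean + wave_scale * raw), 0), 10)
      nm <- paste0("sdq_w", w)
      values[[nm]] <- score
      labels <- c(labels, nm)
      comms <- c(comms, "child")
      scales <- c(scales, "subscale_0_10")
    }
  }

  if (!is.null(female_prop)) {
    set.seed(seed + 2L)
    values[["child_female"]] <- rbinom(n_families, 1, female_prop)
    labels <- c(labels, "child_female")
    comms <- c(comms, "demographic")
    scales <- c(scales, "binary")
  }

  df <- as.data.frame(values, check.names = FALSE)
  new_symptom_table(df, labels, setNames(comms, labels),
                    setNames(scales, labels), seed = seed)
}

#' @keywords internal
new_symptom_table <- function(values, node_labels, communities, scale,
                              missing_mask = NULL, seed = NA_integer_) {
  stopifnot(is.data.frame(values),
            identical(colnames(values), node_labels),
            !anyDuplicated(node_labels),
            all(node_labels %in% names(communities)),
            all(node_labels %in% names(scale)))
  ord <- scale[node_labels] == "ordinal_1_4"
  if (any(ord)) {
    v <- as.matrix(values[, node_labels[ord], drop = FALSE])
    if (!all(v[!is.na(v)] %in% 1:4))
      stop("symptom_table: ordinal_1_4 columns must take values in {1,2,3,4}")
  }
  sub <- scale[node_labels] == "subscale_0_10"
  if (any(sub)) {
    v <- as.matrix(values[, node_labels[sub], drop = FALSE])
    if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 10))
      stop("symptom_table: subscale_0_10 columns must lie in [0, 10]")
  }
  if (is.null(missing_mask))
    missing_mask <- is.na(as.matrix(values))
  structure(list(values = values, node_labels = node_labels,
                 communities = communities[node_labels],
                 scale = scale[node_labels],
                 missing_mask = missing_mask, seed = seed),
            class = "symptom_table")
}

#' Subset the columns of a symptom table
#'
#' @param table A `symptom_table`.
#' @param labels Column labels to keep (order preserved as given).
#' @return A `symptom_table` over the selected columns.
#' @export
subset_symptoms <- function(table, labels) {
  stopifnot(inherits(table, "symptom_table"))
  missing <- setdiff(labels, table$node_labels)
  if (length(missing))
    stop("subset_symptoms: unknown columns: ", paste(missing, collapse = ", "))
  new_symptom_table(table$values[, labels, drop = FALSE], labels,
                    table$communities, table$scale, seed = table$seed)
}

#' @export
print.true_network <- function(x, ...) {
  m <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat("True family symptom network:", length(x$node_labels), "nodes,",
      m, "edges (", length(x$bridge_edges), "cross-community )\n")
  invisible(x)
}

#' @export
print.symptom_table <- function(x, ...) {
  cat("Symptom table:", nrow(x$values), "families x", length(x$node_labels),
      "columns (", sum(x$scale == "ordinal_1_4"), "ordinal,",
      sum(x$scale == "subscale_0_10"), "subscale )\n")
  invisible(x)
}

#' Write a symptom table to CSV (one row per family)
#' @param table A `symptom_table`.
#' @param path Output path.
#' @export
write_symptom_csv <- function(table, path) {
  stopifnot(inherits(table, "symptom_table"))
  write.table(table$values, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a symptom table from CSV
#' @param path CSV path (header row = node labels).
#' @param communities Named character vector mapping every column to a
#'   community.
#' @param scale Named character vector mapping every column to a scale; when
#'   `NULL`, integer 1-4 columns are treated as ordinal and everything else
#'   as continuous.
#' @export
read_symptom_csv <- function(path, communities, scale = NULL) {
  df <- read.csv(path, check.names = FALSE, comment.char = "#")
  if (is.null(scale)) {
    scale <- vapply(df, function(col) {
      if (all(col[!is.na(col)] %in% 1:4)) "ordinal_1_4" else "continuous"
    }, character(1))
  }
  new_symptom_table(df, colnames(df), communities, scale)
}

#' Write a true network as a JSON edge list with community map
#' @param truth A `true_network`.
#' @param path Output path.
#' @export
write_true_network_json <- function(truth, path) {
  stopifnot(inherits(truth, "true_network"))
  ut <- which(upper.tri(truth$pcor) & truth$pcor != 0, arr.ind = TRUE)
  edges <- data.frame(node1 = truth$node_labels[ut[, 1]],
                      node2 = truth$node_labels[ut[, 2]],
                      weight = truth$pcor[ut])
  jsonlite::write_json(list(nodes = truth$node_labels,
                            communities = as.list(truth$communities),
                            edges = edges, seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
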