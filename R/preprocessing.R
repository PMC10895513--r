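# Preprocessing: Spearman correlation matrices on complete cases,
# redundancy screening of near-duplicate symptom items (dependent
# correlation tests on shared-variable correlation profiles), and the child
# emotional-difficulties one-factor model with its adequacy statistics.

#' Spearman rank-correlation matrix on complete cases
#'
#' Ordinal, non-normally distributed symptom data call for rank
#' correlations: each column is rank-transformed (average ranks for ties)
#' and the product-moment correlation of the ranks is returned.
#'
#' @param table A `symptom_table`, data.frame or matrix.
#' @return A `corr_matrix`: list with `values` (symmetric, unit diagonal),
#'   `n_effective` (number of complete rows used) and `labels`.
#' @export
spearman_matrix <- function(table) {
  corr_matrix_of(table, method = "spearman")
}

# shared complete-case correlation constructor (Spearman or Pearson)
corr_matrix_of <- function(table, method = "spearman") {
  x <- if (inherits(table, "symptom_table")) table$values else as.data.frame(table)
  x <- as.matrix(x)
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3)
    stop("spearman_matrix: fewer than 3 complete rows")
  const <- apply(x, 2, function(col) length(unique(col)) < 2)
  if (any(const))
    stop("spearman_matrix: constant column(s): ",
         paste(colnames(x)[const], collapse = ", "))
  r <- cor(x, method = method)
  new_corr_matrix(r, nrow(x), colnames(x))
}

#' @keywords internal
new_corr_matrix <- function(values, n_effective, labels = colnames(values)) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10)
    stop("corr_matrix: values must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-10)
    stop("corr_matrix: unit diagonal required")
  if (any(values < -1 - 1e-10 | values > 1 + 1e-10))
    stop("corr_matrix: entries must lie in [-1, 1]")
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, n_effective = as.integer(n_effective),
                 labels = labels),
            class = "corr_matrix")
}

#' Test the difference of two dependent correlations sharing one variable
#'
#' Tests `H0: rho_jk = rho_jh` where the two correlations share variable j
#' and the remaining pair has correlation `r_kh`, via the Fisher-z
#' difference with the pooled covariance term of the Steiger family. The
#' default `"hittner"` variant plugs the back-transformed average Fisher z
#' into the covariance term; `"steiger"` uses the plain average correlation.
#'
#' @param r_jk,r_jh The two correlations under comparison (share variable j).
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 10).
#' @param method `"hittner"` (default) or `"steiger"`.
#' @return Two-sided p-value.
#' @export
dependent_corr_test <- function(r_jk, r_jh, r_kh, n,
                                method = c("hittner", "steiger")) {
  method <- match.arg(method)
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("dependent_corr_test: |r| = 1 leaves the Fisher z undefined")
  if (n < 10)
    stop("dependent_corr_test: n must be >= 10")
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rbar <- switch(method,
                 hittner = tanh((z1 + z2) / 2),
                 steiger = (r_jk + r_jh) / 2)
  c_term <- (r_kh * (1 - 2 * rbar^2) -
               0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) / (1 - rbar^2)^2
  denom <- 2 - 2 * c_term
  if (denom <= 0)
    stop("dependent_corr_test: degenerate correlation configuration")
  z <- (z1 - z2) * sqrt((n - 3) / denom)
  2 * pnorm(-abs(z))
}

#' Screen within-community item pairs for redundancy
#'
#' Goldbricker-style node-redundancy detection: within each screened
#' community, every item pair whose Spearman correlation reaches `corr_min`
#' is probed by dependent-correlation tests of its correlation profile
#' against every remaining item of the community (`rho_jh` vs `rho_kh`,
#' overlap `r_jk`). A pair is flagged as potentially redundant when the
#' proportion of significantly different profile correlations falls below
#' `prop_threshold`.
#'
#' @param table A `symptom_table`.
#' @param corr_min Minimum absolute Spearman correlation for a candidate
#'   pair, in (0, 1). Default 0.50.
#' @param prop_threshold Flag a pair when the proportion of significant
#'   profile differences is below this value, in (0, 1). Default 0.25.
#' @param alpha Significance level for each dependent-correlation test.
#' @param communities Communities screened (separately). Default mother and
#'   father.
#' @param method Dependent-correlation variant, see [dependent_corr_test()].
#' @return A `redundancy_result`: data.frame `candidate_pairs` with columns
#'   community, node_i, node_j, r_ij, prop_signif_diff, flagged; plus the
#'   threshold configuration.
#' @export
find_redundant_pairs <- function(table, corr_min = 0.50,
                                 prop_threshold = 0.25, alpha = 0.05,
                                 communities = c("mother", "father"),
                                 method = "hittner") {
  stopifnot(inherits(table, "symptom_table"))
  if (corr_min <= 0 || corr_min >= 1 || prop_threshold <= 0 || prop_threshold >= 1)
    stop("find_redundant_pairs: corr_min and prop_threshold must lie in (0, 1)")
  out <- list()
  for (comm in communities) {
    nodes <- table$node_labels[table$communities == comm]
    if (length(nodes) < 3)
      stop("find_redundant_pairs: community '", comm, "' has fewer than 3 nodes")
    cm <- spearman_matrix(subset_symptoms(table, nodes))
    r <- cm$values
    n <- cm$n_effective
    for (a in seq_along(nodes)) {
      for (b in seq_along(nodes)) {
        if (b <= a) next
        if (abs(r[a, b]) < corr_min) next
        others <- setdiff(seq_along(nodes), c(a, b))
        pvals <- vapply(others, function(h) {
          dependent_corr_test(r[a, h], r[b, h], r[a, b], n, method = method)
        }, numeric(1))
        prop <- mean(pvals < alpha)
        out[[length(out) + 1L]] <- data.frame(
          community = comm, node_i = nodes[a], node_j = nodes[b],
          r_ij = r[a, b], prop_signif_diff = prop,
          flagged = prop < prop_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(community = character(0), node_i = character(0),
               node_j = character(0), r_ij = numeric(0),
               prop_signif_diff = numeric(0), flagged = logical(0))
  structure(list(candidate_pairs = pairs,
                 threshold_config = list(corr_min = corr_min,
                                         prop_threshold = prop_threshold,
                                         alpha = alpha, method = method)),
            class = "redundancy_result")
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: `sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal
#' pairs, where `q` are the anti-image partial correlations obtained from
#' the inverse correlation matrix.
#'
#' @param corr A `corr_matrix` or plain correlation matrix.
#' @return KMO value in \[0, 1\].
#' @export
kmo <- function(corr) {
  r <- if (inherits(corr, "corr_matrix")) corr$values else as.matrix(corr)
  ki <- tryCatch(solve(r), error = function(e)
    stop("kmo: correlation matrix is singular"))
  d <- 1 / sqrt(diag(ki))
  q <- -ki * outer(d, d)
  off <- upper.tri(r)
  r2 <- sum(r[off]^2)
  q2 <- sum(q[off]^2)
  if (r2 + q2 == 0)
    stop("kmo: all off-diagonal correlations are zero")
  r2 / (r2 + q2)
}

#' Cronbach's alpha
#'
#' `(k / (k - 1)) * (1 - sum of item variances / variance of row sums)`.
#'
#' @param items Matrix or data.frame of item columns (>= 2 columns, >= 3
#'   complete rows).
#' @return Alpha (<= 1; can be negative).
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  x <- x[complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2 || nrow(x) < 3)
    stop("cronbach_alpha: need >= 2 columns and >= 3 complete rows")
  total_var <- var(rowSums(x))
  if (total_var == 0)
    stop("cronbach_alpha: zero total-score variance")
  k <- ncol(x)
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' One-factor model for the three child emotional-difficulty waves
#'
#' Fits the just-identified congeneric one-factor model to exactly three
#' indicator columns by maximum likelihood, extracts factor scores
#' (regression method by default, mean zero over the fitted sample), and
#' reports the KMO, Cronbach's alpha and pairwise Spearman wave
#' correlations of the indicators. A Heywood solution (vanishing
#' uniqueness) is clamped at `1e-6` with a warning.
#'
#' @param waves Data.frame or matrix with exactly 3 columns (complete rows
#'   are used).
#' @param scores `"regression"` (default) or `"Bartlett"`.
#' @return A `factor_result`: list with `loadings` (standardized),
#'   `uniquenesses`, `scores`, `kmo`, `alpha`, `wave_correlations`,
#'   `n_used`.
#' @export
fit_one_factor <- function(waves, scores = c("regression", "Bartlett")) {
  scores <- match.arg(scores)
  x <- as.matrix(waves)
  if (ncol(x) != 3)
    stop("fit_one_factor: exactly 3 indicator columns are required")
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 10)
    stop("fit_one_factor: fewer than 10 complete rows")
  fa <- factanal(x, factors = 1, scores = scores,
                 control = list(lower = 1e-6))
  lambda <- as.numeric(fa$loadings)
  sc <- as.numeric(fa$scores)
  if (sum(lambda) < 0) {       # fix the sign indeterminacy
    lambda <- -lambda
    sc <- -sc
  }
  uniq <- as.numeric(fa$uniquenesses)
  if (any(uniq <= 1e-6 + 1e-9))
    warning("fit_one_factor: Heywood solution; uniqueness clamped at 1e-6")
  r <- cor(x, method = "spearman")
  wave_cors <- r[upper.tri(r)]
  structure(list(loadings = setNames(lambda, colnames(x)),
                 uniquenesses = setNames(uniq, colnames(x)),
                 scores = sc - mean(sc),
                 kmo = kmo(r),
                 alpha = cronbach_alpha(x),
                 wave_correlations = wave_cors,
                 n_used = nrow(x), method = scores),
            class = "factor_result")
}

#' @export
print.factor_result <- function(x, ...) {
  cat("One-factor model:", x$n_used, "rows; loadings",
      paste(sprintf("%.3f", x$loadings), collapse = ", "),
      "; KMO", sprintf("%.3f", x$kmo),
      "; alpha", sprintf("%.3f", x$alpha), "\n")
  invisible(x)
}

#' @export
print.redundancy_result <- function(x, ...) {
  cat("Redundancy screen:", nrow(x$candidate_pairs), "candidate pair(s),",
      sum(x$candidate_pairs$flagged), "flagged\n")
  invisible(x)
}
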