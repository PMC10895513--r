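# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Partial correlations by Schur complement (regression-residual route):
# for each pair, the covariance of the two variables after projecting out
# all remaining ones.
oracle_partials_from_cov <- function(sigma) {
  p <- nrow(sigma)
  out <- matrix(0, p, p, dimnames = dimnames(sigma))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rest <- setdiff(seq_len(p), c(i, j))
      s <- if (length(rest)) {
        sigma[c(i, j), c(i, j)] -
          sigma[c(i, j), rest] %*% solve(sigma[rest, rest], sigma[rest, c(i, j)])
      } else {
        sigma[c(i, j), c(i, j)]
      }
      out[i, j] <- out[j, i] <- s[1, 2] / sqrt(s[1, 1] * s[2, 2])
    }
  }
  out
}

# Data whose sample correlation matrix equals sigma exactly (whiten an
# arbitrary draw, then color it).
exact_moment_data <- function(n, sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(crossprod(z) / (n - 1)))
  x <- z %*% chol(sigma)
  colnames(x) <- colnames(sigma)
  x
}

# Numeric maximum-likelihood oracle for a GGM with a fixed zero pattern:
# direct BFGS over the free concentration entries (independent of the IPS
# route used by the package).
oracle_ggm_fit <- function(S, adj, n) {
  p <- nrow(S)
  ut <- which(upper.tri(adj) & adj == 1)
  build <- function(par) {
    K <- matrix(0, p, p)
    diag(K) <- par[seq_len(p)]
    K[ut] <- par[-seq_len(p)]
    K + t(K) - diag(diag(K))
  }
  nll <- function(par) {
    K <- build(par)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(S * K))
  }
  opt <- stats::optim(c(rep(1, p), rep(0, length(ut))), nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  K <- build(opt$par)
  ll <- (n / 2) * (sum(log(eigen(K, symmetric = TRUE,
                                 only.values = TRUE)$values)) - sum(S * K))
  list(K = K, loglik = ll)
}

# Random sparse positive-definite partial-correlation matrix.
random_pcor <- function(p, density = 0.4, wmax = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density)
        m[i, j] <- m[j, i] <- runif(1, 0.05, wmax) * sample(c(-1, 1), 1)
    }
  }
  while (min(eigen(diag(p) - m, symmetric = TRUE,
                   only.values = TRUE)$values) < 1e-4) {
    m <- 0.9 * m
  }
  m
}

# Independent transcription of the pooled-variance Fisher-z difference test
# for two dependent correlations with one shared variable.
oracle_hittner_p <- function(r_jk, r_jh, r_kh, n) {
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rm <- tanh((z1 + z2) / 2)
  cov_term <- (r_kh * (1 - rm^2 - rm^2) -
                 (rm^2 / 2) * (1 - 2 * rm^2 - r_kh^2)) / ((1 - rm^2)^2)
  z <- (z1 - z2) / sqrt((2 - 2 * cov_term) / (n - 3))
  2 * stats::pnorm(-abs(z))
}

# Tiny parent-only truth + data fixture used by several suites.
small_fixture <- function(n = 600, seed = 7, density = 0.4,
                          wlow = 0.15, whigh = 0.3, continuous = FALSE) {
  tn <- build_true_network(3, 3, within_density = density,
                           bridge_pairs = list(c("m_sad", "f_sad")),
                           weight_low = wlow, weight_high = whigh,
                           seed = seed)
  tab <- sample_family_data(
    tn, n, female_prop = NULL, seed = seed + 1,
    ordinal_thresholds = if (continuous) NULL else c(0.25, 1.0, 1.9))
  list(truth = tn, table = tab)
}
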