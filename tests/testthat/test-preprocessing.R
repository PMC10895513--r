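# Spearman matrices, the dependent-correlation test, redundancy screening,
# KMO, Cronbach's alpha, and the one-factor child model.

test_that("spearman correlation is invariant to monotone transforms and matches the rank oracle", {
  set.seed(1)
  x <- rnorm(50)
  m <- spearman_matrix(data.frame(a = x, b = exp(3 * x)))
  expect_equal(m$values["a", "b"], 1)

  # hand-computed average-rank oracle for x = (1,2,2,3), y = (1,3,2,4)
  rx <- c(1, 2.5, 2.5, 4)
  ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  m2 <- spearman_matrix(data.frame(x = c(1, 2, 2, 3), y = c(1, 3, 2, 4)))
  expect_equal(m2$values["x", "y"], oracle, tolerance = 1e-12)
  expect_equal(m2$n_effective, 4L)
})

test_that("independent columns give near-zero correlations and constant columns error", {
  set.seed(2)
  df <- data.frame(a = rnorm(10000), b = rnorm(10000))
  expect_lt(abs(spearman_matrix(df)$values["a", "b"]), 0.05)
  expect_error(spearman_matrix(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant column")
  expect_error(spearman_matrix(data.frame(a = 1:2, b = 2:1)), "complete rows")
})

test_that("dependent correlation test matches the independent formula transcription", {
  expect_equal(dependent_corr_test(0.4, 0.4, 0.1, 200), 1)
  p <- dependent_corr_test(0.6, 0.2, 0.3, 500)
  expect_equal(p, oracle_hittner_p(0.6, 0.2, 0.3, 500), tolerance = 1e-6)
  for (n in c(50, 200, 1000)) {
    expect_equal(dependent_corr_test(0.5, 0.25, 0.4, n),
                 oracle_hittner_p(0.5, 0.25, 0.4, n), tolerance = 1e-6)
  }
  expect_error(dependent_corr_test(1, 0.2, 0.3, 100), "undefined")
  expect_error(dependent_corr_test(0.5, 0.2, 0.3, 5), "n must be")
})

test_that("dependent correlation p-value decreases with sample size", {
  ns <- c(20, 50, 100, 500, 2000)
  ps <- vapply(ns, function(n) dependent_corr_test(0.6, 0.2, 0.3, n),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("a duplicated item is flagged as redundant, divergent profiles are not", {
  set.seed(3)
  n <- 400
  hub <- rnorm(n)
  a <- hub + rnorm(n)
  vals <- data.frame(m_sad = a,
                     m_cry = a + rnorm(n, 0, 1e-3),   # near-duplicate
                     m_guilt = hub + rnorm(n),
                     m_worry = rnorm(n),
                     f_sad = rnorm(n), f_cry = rnorm(n), f_guilt = rnorm(n))
  labels <- colnames(vals)
  comm <- setNames(c(rep("mother", 4), rep("father", 3)), labels)
  scl <- setNames(rep("continuous", 7), labels)
  tab <- famnet:::new_symptom_table(vals, labels, comm, scl)
  res <- find_redundant_pairs(tab, corr_min = 0.5, prop_threshold = 0.25,
                              alpha = 0.05)
  pairs <- res$candidate_pairs
  dup <- pairs[pairs$node_i == "m_sad" & pairs$node_j == "m_cry", ]
  expect_equal(nrow(dup), 1)
  expect_true(dup$flagged)
  expect_equal(dup$prop_signif_diff, 0)

  # strongly correlated pair whose correlations with a hub have opposite
  # signs: profiles differ, so the pair must not be flagged
  pop <- diag(7)
  dimnames(pop) <- list(labels, labels)
  pop["m_sad", "m_cry"] <- pop["m_cry", "m_sad"] <- 0.8
  pop["m_sad", "m_guilt"] <- pop["m_guilt", "m_sad"] <- 0.25
  pop["m_cry", "m_guilt"] <- pop["m_guilt", "m_cry"] <- -0.25
  set.seed(31)
  x2 <- matrix(rnorm(2000 * 7), ncol = 7) %*% chol(pop)
  colnames(x2) <- labels
  tab2 <- famnet:::new_symptom_table(as.data.frame(x2), labels, comm, scl)
  res2 <- find_redundant_pairs(tab2, corr_min = 0.5, prop_threshold = 0.25)
  p2 <- res2$candidate_pairs
  row <- p2[p2$node_i == "m_sad" & p2$node_j == "m_cry", ]
  expect_equal(nrow(row), 1)
  expect_false(row$flagged)
})

test_that("redundancy screening equals brute-force enumeration on a 6-node table", {
  fx <- small_fixture(n = 500, seed = 11)
  tab <- fx$table
  res <- find_redundant_pairs(tab, corr_min = 0.05, prop_threshold = 0.25,
                              alpha = 0.05)
  # brute force: recompute every candidate pair and test by the oracle
  for (comm in c("mother", "father")) {
    nodes <- tab$node_labels[tab$communities == comm]
    r <- cor(tab$values[, nodes], method = "spearman")
    n <- nrow(tab$values)
    for (a in 1:2) {
      for (b in (a + 1):3) {
        if (abs(r[a, b]) < 0.05) next
        others <- setdiff(1:3, c(a, b))
        ps <- vapply(others, function(h)
          oracle_hittner_p(r[a, h], r[b, h], r[a, b], n), numeric(1))
        row <- res$candidate_pairs
        row <- row[row$community == comm & row$node_i == nodes[a] &
                     row$node_j == nodes[b], ]
        expect_equal(nrow(row), 1)
        expect_equal(row$prop_signif_diff, mean(ps < 0.05), tolerance = 1e-9)
        expect_equal(row$flagged, mean(ps < 0.05) < 0.25)
      }
    }
  }
  # corr_min above every observed correlation returns an empty set
  empty <- find_redundant_pairs(tab, corr_min = 0.999, prop_threshold = 0.25)
  expect_equal(nrow(empty$candidate_pairs), 0)
  expect_error(find_redundant_pairs(tab, corr_min = 1.5, prop_threshold = 0.25),
               "corr_min")
})

test_that("KMO matches the equicorrelation closed form and is permutation invariant", {
  r <- matrix(0.5, 3, 3)
  diag(r) <- 1
  # closed form for 3x3 equicorrelation r: K_ii = (1+r)/((1-r)(1+2r)),
  # K_ij = -r/((1-r)(1+2r)), q = r/(1+r), KMO = r^2/(r^2 + q^2) = 9/13
  expect_equal(kmo(r), 9 / 13, tolerance = 1e-12)

  set.seed(4)
  x <- matrix(rnorm(200 * 4), 200, 4) %*% chol(0.4 + 0.6 * diag(4))
  rr <- cor(x)
  perm <- c(3, 1, 4, 2)
  expect_equal(kmo(rr), kmo(rr[perm, perm]), tolerance = 1e-12)
  expect_error(kmo(diag(3)), "zero")
})

test_that("sample KMO of factor-model data approaches the population value", {
  lam <- 0.75
  rho <- lam^2
  pop <- matrix(rho, 3, 3)
  diag(pop) <- 1
  set.seed(5)
  x <- matrix(rnorm(20000 * 3), ncol = 3) %*% chol(pop)
  expect_lt(abs(kmo(cor(x)) - kmo(pop)), 0.02)
  expect_gt(kmo(pop), 0.65)   # the 0.7-range plateau for moderate loadings
  expect_lt(kmo(pop), 0.75)
})

test_that("cronbach alpha honours its closed-form identities and the covariance oracle", {
  x <- matrix(rnorm(100), 100, 1)[, c(1, 1, 1)]
  expect_equal(cronbach_alpha(x), 1, tolerance = 1e-12)
  toy <- matrix(c(2, 4, 3, 5, 1,
                  3, 4, 2, 5, 2,
                  1, 5, 4, 4, 2,
                  2, 3, 3, 5, 1), 5, 4)
  # oracle via the covariance-matrix route
  cv <- cov(toy)
  k <- ncol(toy)
  oracle <- (k / (k - 1)) * (1 - sum(diag(cv)) / sum(cv))
  expect_equal(cronbach_alpha(toy), oracle, tolerance = 1e-12)
  set.seed(6)
  indep <- matrix(rnorm(50000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)   # population alpha is 0
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
})

test_that("one-factor loadings match the tetrad closed form on exact-moment data", {
  lam <- c(0.8, 0.7, 0.6)
  pop <- tcrossprod(lam) + diag(1 - lam^2)
  colnames(pop) <- rownames(pop) <- paste0("w", 1:3)
  x <- exact_moment_data(500, pop, seed = 7)
  fit <- fit_one_factor(x)
  r12 <- pop[1, 2]; r13 <- pop[1, 3]; r23 <- pop[2, 3]
  tetrad <- c(sqrt(r12 * r13 / r23), sqrt(r12 * r23 / r13),
              sqrt(r13 * r23 / r12))
  expect_equal(unname(fit$loadings), tetrad, tolerance = 1e-5)
  expect_equal(unname(fit$uniquenesses), 1 - tetrad^2, tolerance = 1e-4)
  expect_equal(mean(fit$scores), 0, tolerance = 1e-10)
  # scores are a linear function of the indicators
  pred <- cbind(1, x) %*% qr.solve(cbind(1, x), fit$scores)
  expect_equal(as.numeric(pred), fit$scores, tolerance = 1e-8)
})

test_that("factor scores track the true factor in simulation", {
  set.seed(8)
  n <- 5000
  f <- rnorm(n)
  waves <- sapply(1:3, function(k) 0.75 * f + sqrt(1 - 0.75^2) * rnorm(n))
  colnames(waves) <- paste0("w", 1:3)
  fit <- fit_one_factor(waves)
  expect_gt(cor(fit$scores, f), 0.85)
  expect_true(fit$kmo >= 0 && fit$kmo <= 1)
  expect_lte(fit$alpha, 1)
  expect_error(fit_one_factor(waves[, 1:2]), "exactly 3")
})
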