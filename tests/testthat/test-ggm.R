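# Constrained GGM fitting (IPS), partial-correlation conversion, BIC, and
# the stepwise model search.

corr_fixture <- function(p = 5, n = 400, seed = 1) {
  pc <- random_pcor(p, density = 0.5, seed = seed)
  x <- exact_moment_data(n, partial_to_covariance(pc), seed = seed + 100)
  famnet:::new_corr_matrix(cor(x), n, paste0("v", seq_len(p)))
}

test_that("the saturated fit equals the matrix inverse and the empty fit the identity", {
  cm <- corr_fixture(5, 400, seed = 2)
  p <- 5
  full <- matrix(1L, p, p) - diag(p)
  fit <- fit_constrained_ggm(cm, full)
  expect_lt(max(abs(fit$K - solve(cm$values))), 1e-8)
  empty <- matrix(0L, p, p)
  fit0 <- fit_constrained_ggm(cm, empty)
  expect_equal(unname(fit0$K), diag(p), tolerance = 1e-12)
  expect_true(all(precision_to_partial(fit0$K) == 0))
})

test_that("a chain model recovers its generating partial correlations", {
  w <- c(0.3, 0.25, 0.2)
  pc <- matrix(0, 4, 4)
  for (i in 1:3) pc[i, i + 1] <- pc[i + 1, i] <- w[i]
  sig <- partial_to_covariance(pc)
  cm <- famnet:::new_corr_matrix(sig, 1000, paste0("v", 1:4))
  adj <- matrix(0L, 4, 4)
  for (i in 1:3) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  fit <- fit_constrained_ggm(cm, adj)
  got <- precision_to_partial(fit$K)
  expect_lt(max(abs(got - pc)), 1e-6)
  # and the likelihood agrees with the numeric ML oracle
  oracle <- oracle_ggm_fit(sig, adj, 1000)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
})

test_that("constrained fits match the numeric ML oracle on random graphs", {
  for (seed in 1:3) {
    cm <- corr_fixture(4, 300, seed = seed + 10)
    adj <- matrix(0L, 4, 4)
    adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[1, 4] <- adj[4, 1] <- 1L
    fit <- fit_constrained_ggm(cm, adj)
    oracle <- oracle_ggm_fit(cm$values, adj, 300)
    expect_lt(max(abs(fit$K - oracle$K)), 1e-4)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
    # zero pattern honoured exactly
    expect_true(all(fit$K[adj == 0 & upper.tri(adj)] == 0))
  }
})

test_that("precision_to_partial follows the sign convention and residual oracle", {
  expect_true(all(precision_to_partial(diag(3)) == 0))
  K2 <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(precision_to_partial(K2)[1, 2], 0.5)
  set.seed(20)
  A <- matrix(rnorm(25), 5, 5)
  K <- crossprod(A) + diag(5)
  expect_lt(max(abs(precision_to_partial(K) -
                      oracle_partials_from_cov(solve(K)))), 1e-8)
  expect_error(precision_to_partial(diag(c(1, -1, 1))), "diagonal")
})

test_that("BIC follows its definition", {
  expect_equal(ggm_bic(0, 0, 100), 0)
  ll <- -123.4
  expect_equal(ggm_bic(ll, 7, 500) - ggm_bic(ll, 6, 500), log(500))
  expect_error(ggm_bic(0, 0, 1), "n must be")
})

test_that("stepwise selection attains the exhaustive-search BIC on 3-node problems", {
  all_adj <- list()
  combos <- expand.grid(e12 = 0:1, e13 = 0:1, e23 = 0:1)
  for (r in seq_len(nrow(combos))) {
    a <- matrix(0L, 3, 3)
    a[1, 2] <- a[2, 1] <- combos$e12[r]
    a[1, 3] <- a[3, 1] <- combos$e13[r]
    a[2, 3] <- a[3, 2] <- combos$e23[r]
    all_adj[[r]] <- a
  }
  n_match <- 0
  for (seed in 1:50) {
    set.seed(seed)
    pc <- random_pcor(3, density = 0.6, wmax = 0.4, seed = seed)
    x <- matrix(rnorm(200 * 3), ncol = 3) %*% chol(partial_to_covariance(pc))
    cm <- famnet:::new_corr_matrix(cor(x), 200, paste0("v", 1:3))
    best <- min(vapply(all_adj, function(a) {
      fit <- fit_constrained_ggm(cm, a)
      ggm_bic(fit$loglik, sum(a) / 2, 200)
    }, numeric(1)))
    net <- select_ggm(cm, start = "empty")
    if (abs(net$bic - best) < 1e-6) n_match <- n_match + 1
    expect_lte(best, net$bic + 1e-6)
  }
  expect_gte(n_match / 50, 0.95)
})

test_that("data from an empty truth mostly select the empty graph", {
  tn <- build_true_network(3, 3, within_density = 0, seed = 1)
  zero <- 0
  for (seed in 1:20) {
    tab <- sample_family_data(tn, 4000, female_prop = NULL, seed = seed)
    net <- select_ggm(spearman_matrix(tab$values))
    if (net$n_edges == 0) zero <- zero + 1
  }
  expect_gte(zero / 20, 0.9)
})

test_that("selection is idempotent and beats the empty and saturated models", {
  fx <- small_fixture(n = 1500, seed = 21)
  cm <- spearman_matrix(fx$table$values)
  net <- select_ggm(cm, communities = fx$table$communities)
  refit <- fit_constrained_ggm(cm, net$adjacency)
  expect_lt(max(abs(precision_to_partial(refit$K) - net$weights)), 1e-7)
  p <- length(net$labels)
  for (adj in list(matrix(0L, p, p), matrix(1L, p, p) - diag(p))) {
    fit <- fit_constrained_ggm(cm, adj)
    expect_lte(net$bic, ggm_bic(fit$loglik, sum(adj) / 2, cm$n_effective) + 1e-8)
  }
})

test_that("selection is equivariant under node relabeling", {
  fx <- small_fixture(n = 800, seed = 22)
  cm <- spearman_matrix(fx$table$values)
  net <- select_ggm(cm)
  perm <- c(4, 2, 6, 1, 3, 5)
  cmp <- famnet:::new_corr_matrix(cm$values[perm, perm], cm$n_effective,
                                  cm$labels[perm])
  netp <- select_ggm(cmp)
  expect_equal(unname(netp$weights),
               unname(net$weights[perm, perm]), tolerance = 1e-6)
})

test_that("density stats implement the stated definition", {
  fx <- small_fixture(n = 900, seed = 23)
  net <- select_ggm(spearman_matrix(fx$table$values))
  ds <- density_stats(net)
  expect_equal(ds$n_possible, 15)
  expect_equal(ds$density, ds$n_edges / 15)
  w <- net$weights[upper.tri(net$weights)]
  expect_equal(ds$mean_abs_weight, mean(abs(w[w != 0])))
  # empty network reports zero with a flag
  tn <- build_true_network(3, 3, within_density = 0, seed = 1)
  tab <- sample_family_data(tn, 3000, female_prop = NULL, seed = 40)
  net0 <- select_ggm(spearman_matrix(tab$values), start = "empty",
                     max_sweeps = 1000L)
  if (net0$n_edges == 0) {
    ds0 <- density_stats(net0)
    expect_equal(ds0$density, 0)
    expect_equal(ds0$mean_abs_weight, 0)
    expect_true(ds0$empty)
  }
})

test_that("indefinite correlation matrices are repaired before fitting", {
  r <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.9,
                0.2, 0.9, 1), 3, 3)   # indefinite
  expect_lt(min(eigen(r, only.values = TRUE)$values), 0)
  rep <- repair_corr(r)
  expect_gte(min(eigen(rep, only.values = TRUE)$values), 1e-8)
  expect_equal(diag(rep), rep(1, 3))
  cm <- famnet:::new_corr_matrix(r, 200, paste0("v", 1:3))
  net <- select_ggm(cm)   # must not error
  expect_s3_class(net, "ggm_network")
})
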