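# Ground-truth construction, the partial-correlation / covariance
# identity, and the ordinal family data generator.

test_that("zero density and no bridges give an empty graph", {
  tn <- build_true_network(3, 3, within_density = 0, seed = 1)
  expect_true(all(tn$pcor == 0))
  expect_identical(tn$node_labels,
                   c("m_sad", "m_cry", "m_guilt", "f_sad", "f_cry", "f_guilt"))
})

test_that("cross-community entries are exactly the designated bridge pairs", {
  tn <- build_true_network(9, 9, within_density = 0.3,
                           bridge_pairs = list(c("m_guilt", "f_guilt"),
                                               c("m_selfharm", "f_selfharm")),
                           weight_low = 0.05, weight_high = 0.4, seed = 7)
  comm <- tn$communities
  cross <- outer(comm, comm, FUN = "!=") & tn$pcor != 0
  hits <- which(cross & upper.tri(cross), arr.ind = TRUE)
  got <- apply(hits, 1, function(ix) {
    paste(sort(tn$node_labels[ix]), collapse = "|")
  })
  expect_setequal(got, c("f_guilt|m_guilt", "f_selfharm|m_selfharm"))
  expect_true(all(abs(tn$pcor) < 1) && all(diag(tn$pcor) == 0))
  expect_true(min(eigen(diag(nrow(tn$pcor)) - tn$pcor,
                        only.values = TRUE)$values) >= 1e-6)
})

test_that("invalid bridge pairs and bounds are labelled errors", {
  expect_error(build_true_network(3, 3, 0.2,
                                  bridge_pairs = list(c("m_sad", "m_cry")),
                                  weight_low = 0.1, weight_high = 0.2),
               "does not cross communities")
  expect_error(build_true_network(3, 3, 0.2,
                                  bridge_pairs = list(c("m_sad", "f_nope")),
                                  weight_low = 0.1, weight_high = 0.2),
               "unknown node")
  expect_error(build_true_network(3, 3, 1.5), "within_density")
  expect_error(build_true_network(3, 3, 0.5, weight_low = 0,
                                  weight_high = 0.3), "weight bounds")
  expect_error(build_true_network(2, 3, 0.5), "n_mother")
})

test_that("partial_to_covariance handles the trivial and bivariate cases", {
  expect_equal(partial_to_covariance(matrix(0, 4, 4)), diag(4))
  pc <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sig <- partial_to_covariance(pc)
  expect_equal(sig[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(sig), c(1, 1))
  bad <- matrix(0.9, 3, 3)
  diag(bad) <- 0
  expect_error(partial_to_covariance(bad), "positive definite")
})

test_that("partial correlations round-trip through the implied covariance", {
  for (seed in 1:5) {
    pc <- random_pcor(5, density = 0.5, seed = seed)
    sig <- partial_to_covariance(pc)
    expect_lt(max(abs(oracle_partials_from_cov(sig) - pc)), 1e-8)
  }
  tn <- build_true_network(4, 4, within_density = 0.5,
                           bridge_pairs = list(c("m_cry", "f_cry")),
                           weight_low = 0.1, weight_high = 0.35, seed = 3)
  sig <- partial_to_covariance(tn$pcor)
  expect_lt(max(abs(oracle_partials_from_cov(sig) - tn$pcor)), 1e-8)
})

test_that("the generator is deterministic given the seed", {
  tn <- family_truth(seed = 2)
  a <- sample_family_data(tn, 200, seed = 9)
  b <- sample_family_data(tn, 200, seed = 9)
  expect_identical(a$values, b$values)
  c <- sample_family_data(tn, 200, seed = 10)
  expect_false(identical(a$values, c$values))
})

test_that("ordinal margins under an empty graph match the Gaussian cutpoint probabilities", {
  tn <- build_true_network(3, 3, within_density = 0, seed = 1)
  cuts <- c(-0.5, 0.5, 1.5)
  tab <- sample_family_data(tn, 100000, ordinal_thresholds = cuts,
                            female_prop = NULL, seed = 5)
  probs <- diff(c(0, pnorm(cuts), 1))
  for (nm in tn$node_labels) {
    freq <- tabulate(tab$values[[nm]], 4) / 100000
    expect_lt(max(abs(freq - probs)), 0.01)
  }
})

test_that("generated item correlations track the attenuated latent value", {
  tn <- build_true_network(3, 3, within_density = 0, seed = 1)
  tn$pcor["m_sad", "m_cry"] <- tn$pcor["m_cry", "m_sad"] <- 0.41
  sig <- partial_to_covariance(tn$pcor)
  rho <- sig["m_sad", "m_cry"]
  tab <- sample_family_data(tn, 50000, female_prop = NULL, seed = 2)
  r_obs <- cor(tab$values$m_sad, tab$values$m_cry, method = "spearman")
  # Monte-Carlo oracle: discretize a large bivariate normal draw directly
  set.seed(99)
  z1 <- rnorm(2e5)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(2e5)
  cuts <- c(0.25, 1.0, 1.9)
  r_oracle <- cor(findInterval(z1, cuts), findInterval(z2, cuts),
                  method = "spearman")
  expect_gt(r_obs, 0)
  expect_lt(abs(r_obs - r_oracle), 0.05)
})

test_that("raising a partial correlation does not lower the observed item correlation", {
  base <- build_true_network(3, 3, within_density = 0, seed = 1)
  r_at <- function(w) {
    tn <- base
    tn$pcor["m_sad", "m_cry"] <- tn$pcor["m_cry", "m_sad"] <- w
    tab <- sample_family_data(tn, 20000, female_prop = NULL, seed = 3)
    cor(tab$values$m_sad, tab$values$m_cry, method = "spearman")
  }
  rs <- vapply(c(0.1, 0.25, 0.4), r_at, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("generator validates cutpoints and table invariants hold", {
  tn <- family_truth(seed = 1)
  expect_error(sample_family_data(tn, 100, ordinal_thresholds = c(1, 0.5, 2)),
               "strictly increasing")
  expect_error(sample_family_data(tn, 5), "n_families")
  tab <- sample_family_data(tn, 150, seed = 4)
  ord <- tab$node_labels[tab$scale == "ordinal_1_4"]
  expect_true(all(as.matrix(tab$values[, ord]) %in% 1:4))
  sdq <- tab$node_labels[tab$scale == "subscale_0_10"]
  v <- as.matrix(tab$values[, sdq])
  expect_true(all(v >= 0 & v <= 10))
  expect_false(anyDuplicated(tab$node_labels) > 0)
  expect_true(all(tab$node_labels %in% names(tab$communities)))
})

test_that("symptom tables and true networks survive the CSV/JSON round trip", {
  tn <- family_truth(seed = 6)
  tab <- sample_family_data(tn, 120, seed = 6)
  csv <- tempfile(fileext = ".csv")
  write_symptom_csv(tab, csv)
  back <- read_symptom_csv(csv, communities = tab$communities,
                           scale = tab$scale)
  expect_equal(back$values, tab$values, ignore_attr = TRUE)
  js <- tempfile(fileext = ".json")
  write_true_network_json(tn, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$edges), sum(tn$pcor[upper.tri(tn$pcor)] != 0))
  expect_equal(sort(unlist(parsed$nodes)), sort(tn$node_labels), ignore_attr = TRUE)
})
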