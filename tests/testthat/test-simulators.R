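# Ground-truth generators: exactness of the density oracle, reproducibility,
# and programmed structure of the omics fixture.

test_that("gmm truth matches an independent multivariate-normal oracle", {
  skip_if_not_installed("mclust")
  sim <- simulate_cluster_gmm(n = 50, n_components = 3, dim = 4, seed = 5)
  x <- sim$states
  g <- sim$truth
  oracle <- rowSums(vapply(seq_along(g$weights), function(k)
    g$weights[k] * mclust::dmvnorm(x, g$means[k, ], g$covs[[k]]),
    numeric(nrow(x))))
  expect_equal(unname(gmm_log_density(g, x)), log(oracle), tolerance = 1e-8)
})

test_that("single-component truth is the Gaussian closed form at its mean", {
  sim <- simulate_tree_gmm(n = 20, dim = 3, depth = 1,
                           segments_per_edge = 1, seed = 2)
  g <- sim$truth
  expect_length(g$weights, 1)
  det_sigma <- det(g$covs[[1]])
  expect_equal(unname(gmm_log_density(g, g$means)),
               -(3 / 2) * log(2 * pi) - 0.5 * log(det_sigma))
})

test_that("samples match the mixture mean within Monte-Carlo error", {
  sim <- simulate_cluster_gmm(n = 4000, n_components = 2, dim = 3, seed = 9)
  g <- sim$truth
  mix_mean <- colSums(g$weights * g$means)
  total_var <- sapply(seq_len(3), function(j) {
    second <- sum(g$weights * (sapply(g$covs, function(s) s[j, j]) + g$means[, j]^2))
    second - mix_mean[j]^2
  })
  se <- sqrt(total_var / 4000)
  expect_true(all(abs(colMeans(sim$states) - mix_mean) < 3 * se))
})

test_that("cluster truth integrates to one on a 2-D case", {
  skip_if_not_installed("pracma")
  sim <- simulate_cluster_gmm(n = 10, n_components = 2, dim = 2,
                              separation = 1.5, scale_sd = 0.1, seed = 3)
  g <- sim$truth
  total <- pracma::integral2(function(x, y) {
    pts <- cbind(as.vector(x), as.vector(y))
    matrix(exp(gmm_log_density(g, pts)), nrow(x), ncol(x))
  }, -12, 12, -12, 12, reltol = 1e-8)$Q
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("generators are pure functions of their seed", {
  a <- simulate_tree_gmm(n = 100, dim = 5, depth = 3, seed = 21)
  b <- simulate_tree_gmm(n = 100, dim = 5, depth = 3, seed = 21)
  expect_identical(a$states, b$states)
  expect_identical(a$truth$means, b$truth$means)
  c1 <- simulate_time_series(n_per_time = 30, seed = 4)
  c2 <- simulate_time_series(n_per_time = 30, seed = 4)
  expect_identical(c1$states, c2$states)
  expect_false(identical(a$states,
                         simulate_tree_gmm(n = 100, dim = 5, depth = 3, seed = 22)$states))
})

test_that("mixture weights normalize and covariances are positive definite", {
  sim <- simulate_tree_gmm(n = 50, dim = 6, depth = 4, seed = 1)
  expect_equal(sum(sim$truth$weights), 1, tolerance = 1e-12)
  eigs <- vapply(sim$truth$covs, function(s) min(eigen(s, TRUE, TRUE)$values),
                 numeric(1))
  expect_true(all(eigs > 0))
})

test_that("time-series drift shifts means linearly and zero drift is stationary", {
  sim <- simulate_time_series(n_per_time = 30, timepoints = c(0, 0.5, 1),
                              drift = 2, seed = 6)
  m0 <- sim$truths[["0"]]$means
  m1 <- sim$truths[["1"]]$means
  mid <- sim$truths[["0.5"]]$means
  expect_equal(mid, (m0 + m1) / 2)
  expect_equal(sqrt(rowSums((m1 - m0)^2)), rep(2, nrow(m0)))
  still <- simulate_time_series(n_per_time = 30, timepoints = c(0, 1),
                                drift = 0, seed = 6)
  expect_equal(still$truths[["0"]]$means, still$truths[["1"]]$means)
})

test_that("the omics fixture programs its corridor and peak classes", {
  sim <- simulate_expression_and_peaks(seed = 17)
  s <- sim$pseudotime
  # the corridor is sparsely populated relative to the ends
  inside <- mean(s >= sim$corridor[1] & s <= sim$corridor[2]) /
    diff(sim$corridor)
  outside <- mean(s < sim$corridor[1] | s > sim$corridor[2]) /
    (1 - diff(sim$corridor))
  expect_lt(inside, outside / 2)
  # primed peaks are open at the start, lineage-specific are not
  start <- s < 0.2
  acc <- sim$peak_accessibility
  primed <- sim$peak_class == "primed"
  lin <- sim$peak_class == "lineage_specific"
  expect_gt(min(colMeans(acc[start, primed])), 0.3)
  expect_lt(max(colMeans(acc[start, lin])), 0.05)
  expect_identical(sim$peak_counts,
                   simulate_expression_and_peaks(seed = 17)$peak_counts)
})
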