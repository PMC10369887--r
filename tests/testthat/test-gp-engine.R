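# Kernel, hyperparameter heuristics, landmarks, initialization, rank check
# and the generic GP trend.

test_that("Matern-5/2 kernel matches its closed form", {
  expect_equal(matern52(c(1, 2), c(1, 2), length_scale = 3), 1)
  expect_equal(matern52(c(0, 0), c(0, 0), length_scale = 1, variance = 2.5), 2.5)
  # at one length scale of separation
  expect_equal(matern52(0, 1, length_scale = 1),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)), tolerance = 1e-12)
  expect_equal(matern52(0, 1, length_scale = 1), 0.524, tolerance = 1e-4)
  # monotone decay to zero
  r <- seq(0.1, 50, by = 0.1)
  v <- matern52(matrix(0), matrix(r, ncol = 1), length_scale = 2)
  expect_true(all(diff(drop(v)) < 0))
  expect_lt(v[length(r)], 1e-8)
  # symmetry on matrices
  set.seed(1)
  a <- matrix(rnorm(12), 4, 3)
  expect_equal(matern52(a, a, length_scale = 1.5),
               t(matern52(a, a, length_scale = 1.5)))
})

test_that("length-scale heuristic follows exp(lambda + mean log dn)", {
  expect_equal(length_scale_heuristic(rep(1, 10)), exp(3))
  expect_equal(length_scale_heuristic(rep(exp(-3), 5)), 1)
  set.seed(2)
  dn <- rexp(50) + 0.1
  expect_equal(length_scale_heuristic(3 * dn), 3 * length_scale_heuristic(dn))
  expect_error(length_scale_heuristic(c(1, 0)), "positive")
})

test_that("prior mean is the 1st percentile minus 10", {
  expect_equal(prior_mean(rep(2.5, 8)), -7.5)
  expect_equal(prior_mean(0:100), quantile(0:100, 0.01, type = 7)[[1]] - 10)
  set.seed(3)
  v <- rnorm(200)
  expect_equal(prior_mean(v + 4), prior_mean(v) + 4)
  expect_error(prior_mean(numeric(0)), "nonempty")
})

test_that("landmark selection recovers cluster structure deterministically", {
  fx <- three_cluster_states()
  z <- select_landmarks(fx$states, 3, seed = 9)
  # each true center is matched by some landmark within 0.1 cluster sds
  d <- sqrt(celldensity:::cross_dist2(fx$centers, z))
  expect_true(all(apply(d, 1, min) < 0.1 * 0.5 * sqrt(nrow(fx$states) / 3)))
  expect_identical(z, select_landmarks(fx$states, 3, seed = 9))
  # full fallback
  expect_equal(select_landmarks(fx$states, 1000, seed = 1), unname(fx$states))
  expect_error(select_landmarks(fx$states, 0), "k >= 1")
})

test_that("covariance rank check flags exhausted landmark sets", {
  z <- diag(100, 5)  # separations of ~140 length scales
  expect_equal(as.integer(covariance_rank_check(z, length_scale = 1)), 5L)
  expect_warning(r <- covariance_rank_check(rbind(z, z[1, ]), length_scale = 1),
                 "exhausted")
  expect_lte(as.integer(r), 5L)
  # rank never increases with the length scale
  set.seed(4)
  zz <- matrix(rnorm(40), 20, 2)
  ranks <- vapply(c(0.01, 0.1, 1, 10), function(l)
    as.integer(suppressWarnings(covariance_rank_check(zz, l))), integer(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("ridge initialization matches closed form and a numeric minimizer", {
  v <- c(2, -4, 6)
  expect_equal(initialize_latent(v, diag(3)), v / 2)
  expect_equal(initialize_latent(rep(0, 4), diag(4)), rep(0, 4))
  set.seed(6)
  L <- matrix(rnorm(30), 10, 3)
  v <- rnorm(10)
  y_closed <- initialize_latent(v, L)
  obj <- function(y) sum((v - L %*% y)^2) + sum(y^2)
  y_num <- optim(rep(0, 3), obj, method = "BFGS",
                 control = list(reltol = 1e-14))$par
  expect_equal(y_closed, y_num, tolerance = 1e-6)
  expect_error(initialize_latent(rnorm(5), L), "mismatch")
})

test_that("gp_trend interpolates constants, lines, and smooths noise", {
  t <- seq(0, 1, length.out = 60)
  expect_equal(predict(gp_trend(t, rep(3, 60), noise = 0.1), seq(0, 1, 0.05)),
               rep(3, 21), tolerance = 1e-6)
  fit <- gp_trend(t, 2 * t, noise = 1e-4)
  grid <- seq(0.1, 0.9, length.out = 30)
  expect_lt(max(abs(predict(fit, grid) - 2 * grid)), 0.05)
  set.seed(8)
  y <- 2 * t + rnorm(60, sd = 0.5)
  sm <- predict(gp_trend(t, y, noise = 0.25), t)
  expect_lt(sqrt(mean((sm - 2 * t)^2)), sqrt(mean((y - 2 * t)^2)))
  # inducing-point approximation stays close to the full solution
  sp <- predict(gp_trend(t, y, noise = 0.25, landmarks = 25), t)
  expect_lt(max(abs(sp - sm)), 0.05)
  expect_error(gp_trend(t, y[-1]), "lengths differ")
})
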