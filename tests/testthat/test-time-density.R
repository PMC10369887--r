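# Per-timepoint densities, cross-time correlations, temporal length scale,
# and the product-kernel time-continuous model.

test_that("per-timepoint fits agree on identical coordinates and honor min_cells", {
  set.seed(40)
  x <- matrix(rnorm(120 * 2), 120, 2)
  states <- rbind(x, x)
  times <- rep(c(0, 1), each = 120)
  fits <- fit_timepoint_densities(states, times, min_cells = 50)
  r <- cor(predict(fits[["0"]], x), predict(fits[["1"]], x),
           method = "spearman")
  expect_gt(r, 0.999)
  # undersized timepoint is skipped with a warning
  st2 <- rbind(x, x[1:10, ] + 0.01, x + 1)
  t2 <- c(rep(0, 120), rep(1, 10), rep(2, 120))
  expect_warning(f2 <- fit_timepoint_densities(st2, t2, min_cells = 50),
                 "skipped")
  expect_setequal(names(f2), c("0", "2"))
})

test_that("undersized timepoints abort when configured", {
  set.seed(41)
  x <- matrix(rnorm(70 * 2), 70, 2)
  times <- c(rep(0, 60), rep(1, 10))
  expect_warning(fit_timepoint_densities(x, times, min_cells = 50),
                 "skipped") |> expect_error("fewer than 2 timepoints")
  expect_error(fit_timepoint_densities(x, times, min_cells = 50,
                                       on_small = "abort"), "10 < 50")
})

test_that("the time correlation matrix is symmetric with unit diagonal", {
  ts <- simulate_time_series(n_per_time = 80, timepoints = c(0, 0.5, 1),
                             dim = 3, drift = 3, seed = 7)
  fits <- fit_timepoint_densities(ts$states, ts$times, min_cells = 50)
  P <- time_correlations(fits, ts$states)
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 3))
  expect_true(all(P >= -1 & P <= 1))
  # adjacent timepoints correlate more than distant ones under drift
  expect_gt(P["0", "0.5"], P["0", "1"])
})

test_that("the temporal length scale is recovered from an exact kernel matrix", {
  times <- c(0, 0.25, 0.5, 0.75, 1)
  P <- matern52(matrix(times), matrix(times), length_scale = 0.5)
  expect_equal(fit_time_length_scale(P, times), 0.5, tolerance = 1e-3)
  # invariant under a common time shift
  expect_equal(fit_time_length_scale(P, times + 7), 0.5, tolerance = 1e-3)
  # an all-ones matrix drives the scale to the upper bound
  expect_warning(lt <- fit_time_length_scale(matrix(1, 5, 5), times), "bound")
  expect_gt(lt, 99)
})

test_that("the product kernel reduces to the state kernel at equal times", {
  set.seed(42)
  x <- matrix(rnorm(100 * 2), 100, 2)
  times <- rep(0.5, 100) + 0  # a single timepoint
  expect_error(cell_density_time(x, times), "distinct")
  # two timepoints with identical state distributions: prediction at either
  # time tracks a state-only fit
  states <- rbind(x, x + 0.01)
  tt <- rep(c(0, 1), each = 100)
  tfit <- cell_density_time(states, tt, time_length_scale = 100)
  sfit <- cell_density(x)
  r <- cor(predict(tfit, x, time = 0.5), predict(sfit, x), method = "spearman")
  expect_gt(r, 0.95)
})

test_that("interpolated densities move between the endpoint landscapes", {
  ts <- simulate_time_series(n_per_time = 120, timepoints = c(0, 1),
                             dim = 2, n_components = 1, drift = 4, seed = 9)
  tfit <- cell_density_time(ts$states, ts$times, min_cells = 50)
  m0 <- ts$truths[["0"]]$means
  m1 <- ts$truths[["1"]]$means
  mid <- (m0 + m1) / 2
  # at t = 0.5 the midpoint is denser than either endpoint mean
  p <- predict(tfit, rbind(m0, mid, m1), time = 0.5)
  expect_gt(p[2], p[1])
  expect_gt(p[2], p[3])
  # and at t = 0 the ordering flips toward the early mean
  p0 <- predict(tfit, rbind(m0, m1), time = 0)
  expect_gt(p0[1], p0[2])
  expect_warning(predict(tfit, m0, time = 2), "extrapolating")
})

test_that("time derivatives match finite differences and detect drift signs", {
  ts <- simulate_time_series(n_per_time = 100, timepoints = c(0, 0.5, 1),
                             dim = 2, n_components = 1, drift = 4, seed = 11)
  tfit <- cell_density_time(ts$states, ts$times, min_cells = 50)
  set.seed(1)
  probes <- ts$states[sample(nrow(ts$states), 20), ]
  for (t in c(0.25, 0.5, 0.75)) {
    an <- density_time_derivative(tfit, probes, t)
    fd <- density_time_derivative(tfit, probes, t, method = "fd")
    expect_equal(an, fd, tolerance = 1e-4)
  }
  # mass grows where the mode is arriving and shrinks where it left
  m0 <- ts$truths[["0"]]$means
  m1 <- ts$truths[["1"]]$means
  dd <- density_time_derivative(tfit, rbind(m0, m1), 0.5)
  expect_lt(dd[1], 0)
  expect_gt(dd[2], 0)
})

test_that("a stationary process has near-zero time derivatives", {
  ts <- simulate_time_series(n_per_time = 100, timepoints = c(0, 0.5, 1),
                             dim = 2, n_components = 1, drift = 0, seed = 13)
  tfit <- cell_density_time(ts$states, ts$times, min_cells = 50)
  set.seed(2)
  probes <- ts$states[sample(nrow(ts$states), 30), ]
  dd <- density_time_derivative(tfit, probes, 0.5)
  expect_lt(max(abs(dd)), 0.1 * diff(range(predict(tfit))))
})
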