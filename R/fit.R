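# MAP inference of the continuous log-density function.
#
# Model: nearest-neighbor distance dn_i ~ NN(rho(x_i), d) with
# log rho = f ~ GP(m, Matern52(l)). The GP is whitened: f = m + L y with y
# standard normal a priori and L the (possibly low-rank) covariance factor.
# The MAP objective in y, dropping the parameter-free log(db/dr) term, is
#   sum_i [ -rho_i b(dn_i, d) + log rho_i ] - ||y||^2 / 2.

default_control <- function(control) {
  ctl <- list(maxit = 500L, factr = 1e7, pgtol = 1e-6,
              jitter = 1e-6, max_jitter = 1e-2)
  ctl[names(control)] <- control
  ctl
}

# Shared MAP engine: minimizes the negative log posterior over y given the
# factor L, log ball volumes lb and prior mean m.
map_fit_latent <- function(L, lb, m, y0, control) {
  obj <- function(y) {
    f <- m + drop(L %*% y)
    val <- sum(exp(f + lb)) - sum(f) + 0.5 * sum(y^2)
    if (!is.finite(val)) stop("non-finite MAP objective; check inputs and length scale")
    val
  }
  grad <- function(y) {
    f <- m + drop(L %*% y)
    drop(crossprod(L, exp(f + lb) - 1)) + y
  }
  opt <- optim(y0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = control$maxit, factr = control$factr,
                              pgtol = control$pgtol))
  if (opt$convergence != 0)
    warning(sprintf("optimizer did not fully converge (code %d): %s",
                    opt$convergence, opt$message %||% ""))
  opt
}

#' Fit a continuous cell-state density model
#'
#' Infers a log-density function over the cell-state space from
#' nearest-neighbor distances via a Poisson point-process likelihood with a
#' Gaussian-process prior (Matern-5/2 kernel). With more cells than
#' `landmarks`, a sparse model over k-means landmark states (inducing points)
#' is fitted; otherwise the full GP is used. The fitted function can be
#' evaluated at any state with [predict.cell_density()].
#'
#' @param x numeric matrix of cell states (cells in rows), e.g. diffusion
#'   components; row names are used as cell ids.
#' @param density_dim dimensionality `d` used in the nearest-neighbor
#'   likelihood; defaults to `ncol(x)`. Override for intrinsic-dimensionality
#'   experiments. Must be at least 2.
#' @param landmarks landmark budget (default 5000) or an explicit matrix of
#'   landmark locations.
#' @param length_scale kernel length scale; `NULL` (default) uses
#'   [length_scale_heuristic()].
#' @param lambda constant of the length-scale heuristic.
#' @param nn_distances optional precomputed nearest-neighbor distances.
#' @param seed integer seed for landmark selection.
#' @param rank_check run [covariance_rank_check()] on the landmark set;
#'   `NULL` (default) does so only for sparse fits with at most 2000
#'   landmarks, where the eigendecomposition is cheap.
#' @param control list overriding optimizer/numerics defaults: `maxit` (500),
#'   `factr` (1e7), `pgtol` (1e-6), `jitter` (1e-6), `max_jitter` (1e-2).
#' @return an object of class `cell_density` with components including
#'   `mean` (prior mean constant), `kernel`, `landmarks`, `latent` (whitened
#'   coefficients y), `weights` (prediction weights), `log_density` (fitted
#'   values at the training states) and `optim` diagnostics.
#' @examples
#' sim <- simulate_cluster_gmm(n = 300, n_components = 2, dim = 2, seed = 1)
#' fit <- cell_density(sim$states)
#' summary(fit)
#' cor(predict(fit), gmm_log_density(sim$truth, sim$states),
#'     method = "spearman")
#' @export
cell_density <- function(x, density_dim = NULL, landmarks = 5000,
                         length_scale = NULL, lambda = 3, nn_distances = NULL,
                         seed = 0L, rank_check = NULL, control = list()) {
  cl <- match.call()
  x <- as_state_matrix(x)
  n <- nrow(x)
  d <- as.integer(density_dim %||% ncol(x))
  ctl <- default_control(control)
  dn <- nn_distances %||% compute_nn_distances(x)
  if (length(dn) != n) stop("'nn_distances' length must match the number of cells")

  l <- length_scale %||% length_scale_heuristic(dn, lambda)
  log_est <- ml_density_estimate(dn, d, log = TRUE)
  m <- prior_mean(log_est)

  if (is.matrix(landmarks)) {
    z <- unname(as.matrix(landmarks))
  } else {
    z <- select_landmarks(x, as.integer(landmarks), seed = seed)
  }
  mode <- if (nrow(z) >= n) "full" else "sparse"
  if (is.null(rank_check)) rank_check <- mode == "sparse" && nrow(z) <= 2000
  if (rank_check) covariance_rank_check(z, l)

  if (mode == "full") {
    fac <- chol_jitter(matern52_r(cross_dist(x, x), l), ctl$jitter, ctl$max_jitter)
    L <- fac$lower
  } else {
    fac <- chol_jitter(matern52_r(cross_dist(z, z), l), ctl$jitter, ctl$max_jitter)
    k_xz <- matern52_r(cross_dist(x, z), l)
    L <- t(forwardsolve(fac$lower, t(k_xz)))
  }

  lb <- log_ball_volume(dn, d)
  y0 <- initialize_latent(log_est - m, L)
  opt <- map_fit_latent(L, lb, m, y0, ctl)
  y <- opt$par
  w <- drop(backsolve(t(fac$lower), y))
  fit <- m + drop(L %*% y)

  structure(list(
    mean = m,
    kernel = list(type = "matern52", length_scale = l, variance = 1),
    landmarks = z, latent = y, weights = w,
    density_dim = d, mode = mode, n = n, dim = ncol(x),
    nn_distances = dn, log_density = setNames(fit, rownames(x)),
    jitter = fac$jitter, seed = as.integer(seed),
    optim = list(convergence = opt$convergence, counts = opt$counts,
                 value = opt$value, message = opt$message),
    call = cl), class = "cell_density")
}

#' Evaluate a fitted density model at arbitrary states
#'
#' Posterior-mean log-density `m + k(query, landmarks) %*% weights`; far from
#' all landmarks the value reverts to the prior mean constant.
#'
#' @param object a `cell_density` fit.
#' @param newdata matrix of query states (`NULL` returns the fitted values at
#'   the training states).
#' @param ... unused.
#' @return numeric vector of log-densities.
#' @export
predict.cell_density <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$log_density))
      stop("this model carries no stored fitted values (e.g. it was read from disk); supply 'newdata'")
    return(object$log_density)
  }
  q <- as_state_matrix(newdata, "newdata")
  if (ncol(q) != ncol(object$landmarks))
    stop(sprintf("query has %d dimensions but the model expects %d",
                 ncol(q), ncol(object$landmarks)))
  k <- model_kernel(object, q)
  setNames(drop(object$mean + k %*% object$weights), rownames(q))
}

#' @export
print.cell_density <- function(x, ...) {
  cat(sprintf("Cell-state density model (%s GP)\n", x$mode))
  cat(sprintf("  cells: %d  state dims: %d  density dim: %d\n", x$n, x$dim, x$density_dim))
  cat(sprintf("  landmarks: %d  length scale: %.4g  prior mean: %.4g\n",
              nrow(x$landmarks), x$kernel$length_scale, x$mean))
  cat(sprintf("  optimizer: %s (%d objective evaluations)\n",
              if (x$optim$convergence == 0) "converged" else "not converged",
              x$optim$counts[1]))
  invisible(x)
}

#' @export
summary.cell_density <- function(object, ...) {
  out <- list(model = object,
              log_density_quantiles = quantile(object$log_density,
                                               c(0, 0.01, 0.25, 0.5, 0.75, 0.99, 1)))
  class(out) <- "summary.cell_density"
  out
}

#' @export
print.summary.cell_density <- function(x, ...) {
  print(x$model)
  cat("  fitted log-density quantiles:\n")
  print(round(x$log_density_quantiles, 3))
  invisible(x)
}

#' @export
coef.cell_density <- function(object, ...) object$latent

#' Normalized quantile residuals of the nearest-neighbor likelihood
#'
#' Probability-integral-transform residuals: under a well-calibrated model the
#' CDF of each observed nearest-neighbor distance at its fitted density is
#' uniform, so `qnorm()` of it is standard normal.
#'
#' @param object a `cell_density` fit.
#' @param ... unused.
#' @export
residuals.cell_density <- function(object, ...) {
  rho_b <- exp(object$log_density + log_ball_volume(object$nn_distances, object$density_dim))
  stats::qnorm(pmin(pmax(1 - exp(-rho_b), 1e-12), 1 - 1e-12))
}

#' @export
logLik.cell_density <- function(object, ...) {
  ll <- sum(nn_log_pdf(object$nn_distances, exp(object$log_density), object$density_dim))
  structure(ll, df = length(object$latent), nobs = object$n, class = "logLik")
}

#' Plot a fitted density model
#'
#' Scatter of two state-space coordinates colored by fitted log-density.
#'
#' @param x a `cell_density` fit.
#' @param dims two coordinate indices to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cell_density <- function(x, dims = c(1, 2), ...) {
  states <- x$landmarks
  if (x$mode == "full") {
    vals <- x$log_density
  } else {
    vals <- predict(x, states)
  }
  if (x$dim == 1L) {
    plot(states[, 1], vals, xlab = "state", ylab = "log density", ...)
    return(invisible(x))
  }
  pal <- grDevices::hcl.colors(64, "viridis")
  idx <- cut(vals, breaks = 64, labels = FALSE)
  plot(states[, dims[1]], states[, dims[2]], col = pal[idx], pch = 16,
       xlab = sprintf("dim %d", dims[1]), ylab = sprintf("dim %d", dims[2]), ...)
  invisible(x)
}
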