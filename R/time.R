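# Time-continuous density: per-timepoint fits, cross-timepoint correlation,
# temporal length-scale fitting and the product-kernel model over
# (state, time) with interpolation and time derivatives.

split_times <- function(times, n) {
  if (length(times) != n) stop("'times' length must match the number of cells")
  if (!all(is.finite(times))) stop("'times' must be finite")
  ut <- sort(unique(times))
  if (length(ut) < 2L) stop("at least 2 distinct timepoints are required")
  ut
}

# Nearest-neighbor distances computed within each timepoint's cells: each
# snapshot is a realization of the point process at that measurement time.
nn_distances_by_time <- function(x, times) {
  dn <- numeric(nrow(x))
  for (t in unique(times)) {
    i <- which(times == t)
    if (length(i) < 2L)
      stop(sprintf("timepoint %g has fewer than 2 cells", t))
    dn[i] <- compute_nn_distances(x[i, , drop = FALSE])
  }
  dn
}

#' Fit one density model per measurement timepoint
#'
#' Runs [cell_density()] separately on the cells of each timepoint.
#' Timepoints with fewer than `min_cells` cells are skipped with a warning
#' (or abort, per `on_small`).
#'
#' @param x state matrix for all cells.
#' @param times per-cell measurement times.
#' @param min_cells minimum cells a timepoint needs to be fitted.
#' @param on_small `"skip"` (warn and drop) or `"abort"`.
#' @param ... passed to [cell_density()].
#' @return named list of `cell_density` fits, names = timepoint values.
#' @export
fit_timepoint_densities <- function(x, times, min_cells = 50,
                                    on_small = c("skip", "abort"), ...) {
  on_small <- match.arg(on_small)
  x <- as_state_matrix(x)
  ut <- split_times(times, nrow(x))
  fits <- list()
  for (t in ut) {
    i <- which(times == t)
    if (length(i) < min_cells) {
      msg <- sprintf("timepoint %g has %d < %d cells", t, length(i), min_cells)
      if (on_small == "abort") stop(msg)
      warning(paste(msg, "- skipped"))
      next
    }
    fits[[as.character(t)]] <- cell_density(x[i, , drop = FALSE], ...)
  }
  if (length(fits) < 2L) stop("fewer than 2 timepoints could be fitted")
  fits
}

#' Cross-timepoint density correlation matrix
#'
#' Each timepoint's density function is evaluated on the union of all cells
#' and the Pearson correlation of the log-density vectors is taken, giving a
#' symmetric, unit-diagonal timepoint-by-timepoint matrix.
#'
#' @param fits named list from [fit_timepoint_densities()].
#' @param x state matrix of all cells (the evaluation set).
#' @export
time_correlations <- function(fits, x) {
  if (length(fits) < 2L) stop("need at least 2 fitted timepoints")
  x <- as_state_matrix(x)
  evals <- vapply(fits, function(f) unname(predict(f, x)), numeric(nrow(x)))
  if (any(apply(evals, 2, sd) == 0))
    stop("a timepoint's density evaluations are constant; correlation undefined")
  p <- cor(evals)
  dimnames(p) <- list(names(fits), names(fits))
  p
}

#' Fit the temporal length scale to observed density correlations
#'
#' Finds the Matern-5/2 length scale whose kernel matrix over the timepoint
#' differences best matches the observed correlation matrix `P` in Frobenius
#' norm, by bounded 1-D minimization over
#' `[lower, upper] = c(0.01, 100) * diff(range(times))`.
#'
#' @param P timepoint correlation matrix ([time_correlations()]).
#' @param times the ordered distinct timepoint values.
#' @param lower,upper search bounds; defaults scale with the time range.
#' @param tol convergence tolerance of the 1-D search.
#' @export
fit_time_length_scale <- function(P, times, lower = NULL, upper = NULL,
                                  tol = 1e-8) {
  times <- as.numeric(times)
  if (nrow(P) != length(times)) stop("'P' and 'times' sizes differ")
  span <- diff(range(times))
  if (span <= 0) stop("'times' must contain at least 2 distinct values")
  lower <- lower %||% (0.01 * span)
  upper <- upper %||% (100 * span)
  dt <- abs(outer(times, times, "-"))
  fr <- function(l) sum((P - matern52_r(dt, l))^2)
  opt <- optimize(fr, c(lower, upper), tol = tol)
  lt <- opt$minimum
  if (lt - lower < 1e-4 * (upper - lower) || upper - lt < 1e-4 * (upper - lower))
    warning(sprintf("fitted temporal length scale %g sits on the search bound [%g, %g]",
                    lt, lower, upper))
  lt
}

#' Fit a time-continuous cell-state density model
#'
#' Adds the measurement time as an extra coordinate with its own Matern-5/2
#' kernel; the covariance between two cells is the product of the state kernel
#' and the time kernel. The temporal length scale is fitted from the
#' cross-timepoint density correlations unless supplied. Nearest-neighbor
#' distances are computed within each timepoint's cells. The fitted model
#' interpolates densities at any time, including unmeasured ones, and is
#' differentiable in time.
#'
#' @inheritParams cell_density
#' @param times per-cell measurement times.
#' @param time_length_scale temporal kernel length scale; `NULL` fits it via
#'   [fit_time_length_scale()].
#' @param min_cells minimum cells per timepoint for the per-timepoint fits.
#' @return an object of class `c("cell_density_time", "cell_density")`; use
#'   [predict.cell_density_time()] with a `time` argument.
#' @export
cell_density_time <- function(x, times, time_length_scale = NULL,
                              density_dim = NULL, landmarks = 5000,
                              length_scale = NULL, lambda = 3, seed = 0L,
                              min_cells = 50, control = list()) {
  cl <- match.call()
  x <- as_state_matrix(x)
  n <- nrow(x)
  times <- as.numeric(times)
  ut <- split_times(times, n)
  d <- as.integer(density_dim %||% ncol(x))
  ctl <- default_control(control)

  dn <- nn_distances_by_time(x, times)
  l <- length_scale %||% length_scale_heuristic(dn, lambda)
  log_est <- ml_density_estimate(dn, d, log = TRUE)
  m <- prior_mean(log_est)

  correlations <- NULL
  if (is.null(time_length_scale)) {
    fits <- fit_timepoint_densities(x, times, min_cells = min_cells,
                                    landmarks = landmarks,
                                    length_scale = l, seed = seed,
                                    control = control)
    correlations <- time_correlations(fits, x)
    time_length_scale <- fit_time_length_scale(
      correlations, as.numeric(names(fits)))
  }
  lt <- time_length_scale
  stopifnot(lt > 0)

  k_budget <- if (is.matrix(landmarks)) nrow(landmarks) else as.integer(landmarks)
  if (k_budget >= n) {
    z <- unname(x); zt <- times; mode <- "full"
  } else {
    # k-means in augmented coordinates with time rescaled so both kernels see
    # comparable distances.
    aug <- cbind(x, times * l / lt)
    cz <- select_landmarks(aug, k_budget, seed = seed)
    z <- cz[, seq_len(ncol(x)), drop = FALSE]
    zt <- cz[, ncol(x) + 1L] * lt / l
    mode <- "sparse"
  }

  k_zz <- matern52_r(cross_dist(z, z), l) * matern52_r(abs(outer(zt, zt, "-")), lt)
  fac <- chol_jitter(k_zz, ctl$jitter, ctl$max_jitter)
  if (mode == "full") {
    L <- fac$lower
  } else {
    k_xz <- matern52_r(cross_dist(x, z), l) *
      matern52_r(abs(outer(times, zt, "-")), lt)
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
    time_kernel = list(type = "matern52", length_scale = lt),
    landmarks = z, landmark_times = zt, latent = y, weights = w,
    density_dim = d, mode = mode, n = n, dim = ncol(x),
    nn_distances = dn, times = times, time_range = range(times),
    correlations = correlations,
    log_density = setNames(fit, rownames(x)),
    jitter = fac$jitter, seed = as.integer(seed),
    optim = list(convergence = opt$convergence, counts = opt$counts,
                 value = opt$value, message = opt$message),
    call = cl), class = c("cell_density_time", "cell_density"))
}

#' Evaluate a time-continuous density model
#'
#' Log-density at the query states and a given time; times between the
#' measured instances are interpolated, times outside the observed range are
#' flagged with a warning.
#'
#' @param object a `cell_density_time` fit.
#' @param newdata matrix of query states (`NULL` with `time = NULL` returns
#'   the fitted values).
#' @param time scalar evaluation time.
#' @param ... unused.
#' @export
predict.cell_density_time <- function(object, newdata = NULL, time = NULL, ...) {
  if (is.null(newdata) && is.null(time)) return(object$log_density)
  if (is.null(time) || length(time) != 1L)
    stop("'time' must be a single evaluation time")
  q <- as_state_matrix(newdata, "newdata")
  if (ncol(q) != ncol(object$landmarks))
    stop("query dimensionality does not match the model")
  tr <- object$time_range
  if (time < tr[1] || time > tr[2])
    warning(sprintf("time %g lies outside the measured range [%g, %g]: extrapolating",
                    time, tr[1], tr[2]))
  k <- model_kernel(object, q, time)
  setNames(drop(object$mean + k %*% object$weights), rownames(q))
}

# Log-density on a (state grid) x (time grid) via one matrix product.
predict_time_grid <- function(object, states, t_grid) {
  ks <- matern52_r(cross_dist(states, object$landmarks),
                   object$kernel$length_scale, 1)
  kt <- matern52_r(abs(outer(t_grid, object$landmark_times, "-")),
                   object$time_kernel$length_scale, 1)
  object$mean + ks %*% (object$weights * t(kt))
}

#' Time derivative of the log-density
#'
#' The partial derivative of the interpolated log-density with respect to
#' measurement time, by analytic differentiation of the temporal kernel
#' (`method = "analytic"`) or central finite differences (`method = "fd"`,
#' step `1e-4` temporal length scales).
#'
#' @param object a `cell_density_time` fit.
#' @param newdata matrix of query states.
#' @param time scalar evaluation time.
#' @param method derivative scheme.
#' @export
density_time_derivative <- function(object, newdata, time,
                                    method = c("analytic", "fd")) {
  method <- match.arg(method)
  q <- as_state_matrix(newdata, "newdata")
  lt <- object$time_kernel$length_scale
  if (method == "fd") {
    h <- 1e-4 * lt
    up <- suppressWarnings(predict(object, q, time + h))
    dw <- suppressWarnings(predict(object, q, time - h))
    return((up - dw) / (2 * h))
  }
  ks <- matern52_r(cross_dist(q, object$landmarks), object$kernel$length_scale, 1)
  dt <- time - object$landmark_times
  dkt <- matern52_dr(abs(dt), lt) * sign(dt)
  setNames(drop((ks * matrix(dkt, nrow(q), length(dkt), byrow = TRUE)) %*%
                  object$weights), rownames(q))
}
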