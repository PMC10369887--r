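# Gaussian-process building blocks: hyperparameter heuristics, landmark
# (inducing-point) selection, ridge initialization, rank diagnostics and a
# generic 1-D trend estimator.

#' Length-scale heuristic from nearest-neighbor distances
#'
#' `exp(lambda + mean(log(dn)))`: the kernel length scale adapts to the
#' typical cell spacing. `lambda = 3` was calibrated across many single-cell
#' datasets and is kept as the default.
#'
#' @param dn positive nearest-neighbor distances.
#' @param lambda additive constant on the log scale.
#' @export
length_scale_heuristic <- function(dn, lambda = 3) {
  if (any(dn <= 0)) stop("all nearest-neighbor distances must be positive")
  exp(lambda + mean(log(dn)))
}

#' Prior mean constant for the log-density Gaussian process
#'
#' The 1st percentile (linear-interpolation convention) of the heuristic log
#' density estimates, minus 10. Far from all data the inferred log-density
#' reverts to this constant, i.e. to a vanishingly small density.
#'
#' @param log_estimates heuristic log-density estimates, one per cell
#'   (see [ml_density_estimate()]).
#' @param offset constant subtracted from the percentile.
#' @export
prior_mean <- function(log_estimates, offset = 10) {
  if (length(log_estimates) == 0L) stop("'log_estimates' must be nonempty")
  unname(quantile(log_estimates, 0.01, type = 7)) - offset
}

# k-means++ seeding: spread initial centers proportionally to squared
# distance from the centers chosen so far.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- cross_dist2(x, x[centers[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, cross_dist2(x, x[centers[j + 1L], , drop = FALSE])[, 1])
  }
  x[centers, , drop = FALSE]
}

#' Select landmark (inducing-point) states
#'
#' k-means centroids with k-means++ initialization; if `k >= nrow(x)` the
#' training states themselves are returned (full, non-sparse model).
#'
#' @param x numeric matrix of cell states.
#' @param k number of landmarks.
#' @param seed integer seed fixing both the k-means++ draw and Lloyd updates.
#' @param iter_max maximum k-means iterations.
#' @return matrix of landmark locations (`k x d'`).
#' @export
select_landmarks <- function(x, k, seed = 0L, iter_max = 50L) {
  x <- as_state_matrix(x)
  stopifnot(k >= 1)
  if (k >= nrow(x)) return(unname(x))
  with_seed(seed, {
    init <- kmeanspp_init(x, k)
    km <- suppressWarnings(
      kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    unname(km$centers)
  })
}

#' Numerical rank of the landmark covariance matrix
#'
#' Eigen-based rank of the `k x k` Matern-5/2 covariance of the landmark set,
#' at relative tolerance `tol`. A rank below `k` means the landmark skeleton's
#' capacity is exhausted at this length scale: adding landmarks in the same
#' region cannot add resolvable detail, and a warning is raised.
#'
#' @param landmarks landmark location matrix.
#' @param length_scale,variance kernel parameters.
#' @param tol relative eigenvalue tolerance.
#' @return integer rank, with attribute `deficient`.
#' @export
covariance_rank_check <- function(landmarks, length_scale, variance = 1,
                                  tol = 1e-8) {
  landmarks <- as.matrix(landmarks)
  k <- nrow(landmarks)
  ev <- eigen(matern52_r(cross_dist(landmarks, landmarks), length_scale, variance),
              symmetric = TRUE, only.values = TRUE)$values
  r <- sum(ev > tol * max(ev))
  if (r < k)
    warning(sprintf("landmark covariance rank %d < %d landmarks: model complexity is exhausted at this length scale", r, k))
  structure(as.integer(r), deficient = r < k)
}

#' Ridge-regression initialization of the latent coefficients
#'
#' Closed-form minimizer of `||v - L y||^2 + ||y||^2` where `v` are the
#' centered heuristic log-density estimates and `L` the model's low-rank
#' factor; the unit ridge shrinks toward the smoother true density.
#'
#' @param v centered target vector (length n).
#' @param L factor matrix (`n x k`).
#' @return length-k coefficient vector.
#' @export
initialize_latent <- function(v, L) {
  L <- as.matrix(L)
  if (length(v) != nrow(L)) stop("dimension mismatch between 'v' and 'L'")
  a <- crossprod(L) + diag(ncol(L))
  drop(solve(a, crossprod(L, v)))
}

# Cholesky (lower) with escalating diagonal jitter; returns factor and the
# jitter finally used.
chol_jitter <- function(k_mat, jitter = 1e-6, max_jitter = 1e-2) {
  v <- mean(diag(k_mat))
  j <- jitter
  repeat {
    ch <- tryCatch(chol(k_mat + diag(j * v, nrow(k_mat))), error = function(e) NULL)
    if (!is.null(ch)) return(list(lower = t(ch), jitter = j))
    if (j >= max_jitter) stop("covariance factorization failed even at maximum jitter")
    j <- j * 10
    message(sprintf("covariance factorization failed; escalating jitter to %g", j))
  }
}

#' Gaussian-process trend over a 1-D ordering
#'
#' Posterior-mean GP regression of `values` on `ordering` (for example gene
#' expression on pseudotime) with a Matern-5/2 kernel and i.i.d. observation
#' noise. With `landmarks` set, a subset-of-regressors approximation keeps the
#' cost linear in the number of cells, which makes scanning thousands of genes
#' practical.
#'
#' @param ordering numeric vector (e.g. pseudotime).
#' @param values numeric vector, same length.
#' @param length_scale,variance Matern-5/2 kernel parameters.
#' @param noise observation-noise variance.
#' @param mean prior mean; defaults to `mean(values)`.
#' @param landmarks optional number of inducing points (quantile-spaced along
#'   `ordering`) or an explicit numeric vector of inducing locations.
#' @return an object of class `gp_trend`; evaluate with `predict()`.
#' @export
gp_trend <- function(ordering, values, length_scale = 1, variance = 1,
                     noise = 0.01, mean = NULL, landmarks = NULL) {
  if (length(ordering) != length(values)) stop("'ordering' and 'values' lengths differ")
  if (!all(is.finite(ordering))) stop("'ordering' must be finite")
  stopifnot(noise > 0)
  mean <- mean %||% base::mean(values)
  x <- matrix(ordering, ncol = 1)
  yc <- values - mean
  if (!is.null(landmarks) && length(landmarks) == 1L && landmarks < length(values)) {
    landmarks <- unname(quantile(ordering, seq(0, 1, length.out = landmarks), type = 7))
  }
  if (is.null(landmarks) || length(landmarks) >= length(values)) {
    k_xx <- matern52_r(cross_dist(x, x), length_scale, variance)
    alpha <- solve(k_xx + diag(noise, length(yc)), yc)
    z <- x
  } else {
    z <- matrix(landmarks, ncol = 1)
    k_zx <- matern52_r(cross_dist(z, x), length_scale, variance)
    k_zz <- matern52_r(cross_dist(z, z), length_scale, variance)
    sigma <- tcrossprod(k_zx) + noise * (k_zz + diag(1e-8 * variance, nrow(z)))
    alpha <- solve(sigma, k_zx %*% yc)
  }
  structure(list(inducing = z, alpha = drop(alpha), mean = mean,
                 length_scale = length_scale, variance = variance, noise = noise),
            class = "gp_trend")
}

#' @param object a `gp_trend` fit.
#' @param newdata numeric vector of evaluation points.
#' @param ... unused.
#' @rdname gp_trend
#' @export
predict.gp_trend <- function(object, newdata, ...) {
  q <- matrix(newdata, ncol = 1)
  k <- matern52_r(cross_dist(q, object$inducing), object$length_scale, object$variance)
  drop(object$mean + k %*% object$alpha)
}
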