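# Nearest-neighbor distances and the Poisson point-process nearest-neighbor
# likelihood linking them to density.

# Exact k-nearest-neighbor search by blockwise exhaustive scan. Ties are
# broken by cell index (order() is stable). Returns distances and indices.
knn_exact <- function(x, k = 1L, block = 1024L) {
  n <- nrow(x)
  if (k >= n) stop("'k' must be smaller than the number of cells")
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(x[rows, , drop = FALSE], x)
    d2[cbind(seq_along(rows), rows)] <- Inf  # no self-neighbors
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  list(index = idx, dist = dst)
}

#' Nearest-neighbor distances in the cell-state space
#'
#' Distance from every cell to its nearest other cell (exact, exhaustive
#' search). Duplicated coordinates give zero distances, at which the
#' nearest-neighbor likelihood is undefined; two policies are offered:
#' `"epsilon"` (default) replaces zeros by the smallest positive observed
#' distance times `dedup_factor`, with a warning; `"distinct"` uses the
#' distance to the nearest *distinct coordinate*, which is invariant under
#' exact replication of cells. Distances within relative rounding error of
#' zero are treated as zero.
#'
#' @param x numeric matrix of cell states, cells in rows.
#' @param duplicates zero-distance policy, see above.
#' @param dedup_factor multiplier applied to the smallest positive distance
#'   under the `"epsilon"` policy.
#' @return numeric vector of positive distances, one per cell.
#' @export
compute_nn_distances <- function(x, duplicates = c("epsilon", "distinct"),
                                 dedup_factor = 1e-3) {
  duplicates <- match.arg(duplicates)
  x <- as_state_matrix(x)
  if (nrow(x) < 2L) stop("at least 2 cells are required")
  if (duplicates == "distinct") {
    key <- do.call(paste, c(as.data.frame(x), sep = "\r"))
    ux <- x[!duplicated(key), , drop = FALSE]
    if (nrow(ux) < 2L) stop("fewer than 2 distinct states")
    dn_u <- knn_exact(ux, 1L)$dist[, 1]
    return(zero_clean(dn_u)[match(key, key[!duplicated(key)])])
  }
  dn <- zero_clean(knn_exact(x, 1L)$dist[, 1])
  if (any(dn == 0)) {
    pos <- dn[dn > 0]
    if (length(pos) == 0L) stop("all cells are duplicated at a single state")
    warning(sprintf("%d zero nearest-neighbor distance(s) from duplicated coordinates replaced by %g",
                    sum(dn == 0), min(pos) * dedup_factor))
    dn[dn == 0] <- min(pos) * dedup_factor
  }
  dn
}

# Snap distances within floating-point fuzz of zero (relative to the largest
# observed distance) to exactly zero.
zero_clean <- function(dn) {
  thr <- 1e-8 * max(dn)
  dn[dn < thr] <- 0
  dn
}

#' Volume of a d-dimensional ball
#'
#' `pi^(d/2) r^d / Gamma(d/2 + 1)`, the ball volume entering the
#' nearest-neighbor distribution. `log_ball_volume()` evaluates its logarithm
#' stably for large `d`.
#'
#' @param r positive radius (vectorized).
#' @param d positive integer dimension.
#' @export
ball_volume <- function(r, d) {
  stopifnot(all(r > 0), d >= 1)
  exp(log_ball_volume(r, d))
}

#' @rdname ball_volume
#' @export
log_ball_volume <- function(r, d) {
  stopifnot(all(r > 0), d >= 1)
  (d / 2) * log(pi) + d * log(r) - lgamma(d / 2 + 1)
}

#' Log-density of the nearest-neighbor distribution
#'
#' For a homogeneous Poisson point process of intensity `rho` in `d`
#' dimensions, the distance to the nearest neighbor has density
#' `exp(-rho * b(r, d)) * rho * db(r, d)/dr` where `b(r, d)` is the ball
#' volume. Returns the logarithm, stably.
#'
#' @param r positive distance (vectorized).
#' @param rho positive process intensity (density).
#' @param d positive integer dimension.
#' @export
nn_log_pdf <- function(r, rho, d) {
  stopifnot(all(r > 0), rho > 0, d >= 1)
  log_db_dr <- log(d) + (d / 2) * log(pi) + (d - 1) * log(r) - lgamma(d / 2 + 1)
  -rho * ball_volume(r, d) + log(rho) + log_db_dr
}

#' Heuristic maximum-likelihood density from one nearest-neighbor distance
#'
#' The prior-free maximizer of the nearest-neighbor likelihood,
#' `(d - 1) * Gamma(d/2 + 1) / (d * dn^d * pi^(d/2))`. The formula vanishes at
#' `d = 1`, so `d >= 2` is required. These per-cell estimates are noisy and
#' serve as the initialization and mean heuristic of the Gaussian-process
#' model, not as final densities.
#'
#' @param dn positive nearest-neighbor distance (vectorized).
#' @param d integer dimension, at least 2.
#' @param log return the log estimate (stable for large `d`).
#' @export
ml_density_estimate <- function(dn, d, log = FALSE) {
  stopifnot(all(dn > 0))
  if (d < 2) stop("'d' must be at least 2: the estimate degenerates at d = 1")
  lg <- log(d - 1) - log(d) - d * log(dn) - (d / 2) * log(pi) + lgamma(d / 2 + 1)
  if (log) lg else exp(lg)
}

#' Reciprocal k-nearest-neighbor distance baseline
#'
#' The common 1/kNN-distance density proxy, provided as a comparison baseline
#' only: per cell, the reciprocal of the distance to its k-th nearest distinct
#' neighbor.
#'
#' @param x numeric matrix of cell states, cells in rows.
#' @param k positive integer, smaller than the number of cells.
#' @export
knn_inverse_baseline <- function(x, k = 30L) {
  x <- as_state_matrix(x)
  stopifnot(k >= 1, k < nrow(x))
  1 / knn_exact(x, as.integer(k))$dist[, k]
}
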