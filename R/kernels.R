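# Matern-5/2 covariance: exactly twice differentiable, so the inferred
# log-density is smooth but not arbitrarily so.

# Kernel value as a function of distance r >= 0.
matern52_r <- function(r, length_scale, variance = 1) {
  u <- sqrt(5) * r / length_scale
  variance * (1 + u + u^2 / 3) * exp(-u)
}

# d/dr of matern52_r; zero at r = 0 (smooth maximum).
matern52_dr <- function(r, length_scale, variance = 1) {
  u <- r / length_scale
  -(5 / 3) * variance * (u / length_scale) * (1 + sqrt(5) * u) * exp(-sqrt(5) * u)
}

#' Matern-5/2 covariance between states
#'
#' Evaluates `variance * (1 + sqrt(5) u + 5 u^2 / 3) * exp(-sqrt(5) u)` with
#' `u = ||a - b|| / length_scale`. With matrix inputs the full cross-covariance
#' matrix is returned.
#'
#' @param a,b numeric vectors (single states) or matrices (states in rows).
#'   `b = NULL` means `b = a`.
#' @param length_scale positive kernel length scale, in coordinate units.
#' @param variance positive kernel variance (value at zero lag).
#' @return a scalar for vector inputs, otherwise a `nrow(a) x nrow(b)` matrix.
#' @examples
#' matern52(c(0, 0), c(0, 0), length_scale = 2)       # the variance, 1
#' matern52(0, 1, length_scale = 1)                   # ~0.524
#' @export
matern52 <- function(a, b = NULL, length_scale, variance = 1) {
  stopifnot(length_scale > 0, variance > 0)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(b)) b <- a else if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(a) != ncol(b)) stop("'a' and 'b' must have the same dimensionality")
  k <- matern52_r(cross_dist(a, b), length_scale, variance)
  if (length(k) == 1L) k[1] else k
}

# Kernel of a fitted model evaluated between query states and landmarks.
# Product models multiply a state kernel and a time kernel.
model_kernel <- function(object, query, time = NULL) {
  k <- matern52_r(cross_dist(query, object$landmarks),
                  object$kernel$length_scale, object$kernel$variance)
  if (!is.null(object$time_kernel)) {
    if (is.null(time)) stop("this model requires a 'time' at which to evaluate")
    kt <- matern52_r(abs(outer(rep(time, nrow(query)), object$landmark_times, "-")),
                     object$time_kernel$length_scale, 1)
    k <- k * kt
  }
  k
}
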