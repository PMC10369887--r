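# Shared fixtures, all generated in code under fixed seeds.

# Brute-force all-pairs k-nearest-neighbor oracle (independent of the
# package's blockwise search).
brute_knn <- function(x, k = 1L) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  out <- t(vapply(seq_len(nrow(x)), function(i) sort(d[i, ])[seq_len(k)],
                  numeric(k)))
  matrix(out, nrow = nrow(x))
}

# Three tight, well-separated planar clusters with known centers.
three_cluster_states <- function(n_per = 30, seed = 42) {
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x <- do.call(rbind, lapply(1:3, function(k)
      cbind(rnorm(n_per, centers[k, 1], 0.5), rnorm(n_per, centers[k, 2], 0.5))))
    list(states = x, centers = centers, cluster = rep(1:3, each = n_per))
  })
}

# Small seeded single-Gaussian sample with exact truth.
gaussian_fixture <- function(n = 800, dim = 2, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * dim), n, dim)
  list(states = x, truth = -rowSums(x^2) / 2 - (dim / 2) * log(2 * pi))
}
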