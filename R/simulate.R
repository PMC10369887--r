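# Seeded Gaussian-mixture simulators with exact ground-truth densities, plus
# a paired expression/chromatin toy generator for the scoring modules. Every
# generator is a pure function of its arguments and seed; truth evaluators
# are closed-form (no sampling).

new_gmm <- function(weights, means, covs) {
  weights <- weights / sum(weights)
  chols <- lapply(covs, function(s) {
    ch <- tryCatch(chol(s), error = function(e)
      stop("mixture covariance is not positive definite: ", conditionMessage(e)))
    ch
  })
  structure(list(weights = weights, means = means, covs = covs, chols = chols),
            class = "gmm_truth")
}

#' Exact log-density of a Gaussian-mixture ground truth
#'
#' Closed-form mixture log-density (log-sum-exp over components, Cholesky
#' solves per component); the oracle against which fitted densities are
#' benchmarked.
#'
#' @param gmm a `gmm_truth` object from one of the simulators.
#' @param x matrix of evaluation states.
#' @export
gmm_log_density <- function(gmm, x) {
  x <- as_state_matrix(x)
  d <- ncol(x)
  comp <- vapply(seq_along(gmm$weights), function(k) {
    r <- gmm$chols[[k]]
    xc <- t(x) - gmm$means[k, ]
    z <- forwardsolve(t(r), xc)
    log(gmm$weights[k]) - (d / 2) * log(2 * pi) - sum(log(diag(r))) -
      0.5 * colSums(z^2)
  }, numeric(nrow(x)))
  comp <- matrix(comp, nrow = nrow(x))
  mx <- apply(comp, 1, max)
  setNames(mx + log(rowSums(exp(comp - mx))), rownames(x))
}

sample_gmm <- function(gmm, n) {
  counts <- drop(stats::rmultinom(1, n, gmm$weights))
  d <- ncol(gmm$means)
  x <- matrix(NA_real_, n, d)
  pos <- 0L
  for (k in seq_along(counts)) {
    if (counts[k] == 0L) next
    z <- matrix(rnorm(counts[k] * d), counts[k], d)
    x[pos + seq_len(counts[k]), ] <- z %*% gmm$chols[[k]] +
      rep(gmm$means[k, ], each = counts[k])
    pos <- pos + counts[k]
  }
  rownames(x) <- paste0("cell_", seq_len(n))
  x
}

# Orthonormal basis whose first column is v/||v||.
basis_along <- function(v) {
  d <- length(v)
  q <- qr.Q(qr(cbind(v, matrix(rnorm(d * (d - 1)), d))))
  if (sum(q[, 1] * v) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate a differentiation-tree Gaussian mixture with exact truth
#'
#' Emulates a branching differentiation landscape as a tree of velocity
#' vectors: each child vector is a perturbed copy of its parent's, rescaled
#' to the common step length so the tree keeps a uniform pace. Every edge is
#' covered by overlapping anisotropic Gaussians strung along the velocity
#' (`segments_per_edge` of them), forming continuous "tubes" of cell states.
#' Principal standard deviations decay exponentially away from the velocity
#' direction, giving the low intrinsic dimensionality characteristic of
#' cell-state manifolds, and each edge carries a log-normal compactness
#' factor so the landscape spans several orders of magnitude in density —
#' dense pools and rare transitional stretches.
#'
#' @param n total number of cells.
#' @param dim ambient dimensionality (10-20 is typical).
#' @param depth tree depth (levels of edges).
#' @param branching children per node.
#' @param step length of every velocity vector.
#' @param perturb_sd sd of the child-velocity perturbation (before
#'   rescaling to `step`).
#' @param decay exponential decay rate of the off-velocity principal sds.
#' @param scale_sd sd of the per-edge log compactness factor.
#' @param width_ratio tube cross-section sd relative to `step`.
#' @param segments_per_edge overlapping Gaussians per edge.
#' @param seed integer seed fixing every draw.
#' @return list with `states`, `truth` (a `gmm_truth`) and the generating
#'   `spec`.
#' @export
simulate_tree_gmm <- function(n = 5000, dim = 10, depth = 4, branching = 2,
                              step = 3, perturb_sd = 1, decay = 2,
                              scale_sd = 1.2, width_ratio = 0.25,
                              segments_per_edge = 2, seed = 0L) {
  stopifnot(n >= 1, dim >= 2, depth >= 1, branching >= 1, step > 0,
            perturb_sd > 0, decay > 0, width_ratio > 0,
            segments_per_edge >= 1)
  with_seed(seed, {
    u <- rnorm(dim); u <- u / sqrt(sum(u^2))
    edges <- list(list(pos = rep(0, dim), v = step * u))
    level <- edges
    for (dd in seq_len(depth - 1L)) {
      nxt <- list()
      for (nd in level) {
        for (b in seq_len(branching)) {
          v <- nd$v + rnorm(dim, sd = perturb_sd)
          v <- v / sqrt(sum(v^2)) * step
          nxt[[length(nxt) + 1L]] <- list(pos = nd$pos + nd$v, v = v)
        }
      }
      edges <- c(edges, nxt)
      level <- nxt
    }
    means <- NULL
    covs <- list()
    for (nd in edges) {
      s1 <- step * width_ratio * exp(rnorm(1, 0, scale_sd))
      sds <- pmax(s1 * exp(-decay * (seq_len(dim) - 1)), 1e-3 * s1)
      q <- basis_along(nd$v)
      sig <- q %*% diag(sds^2) %*% t(q)
      for (m in seq_len(segments_per_edge)) {
        means <- rbind(means,
                       nd$pos + nd$v * (m - 0.5) / segments_per_edge)
        covs[[length(covs) + 1L]] <- sig
      }
    }
    k <- nrow(means)
    truth <- new_gmm(rep(1 / k, k), means, covs)
    states <- sample_gmm(truth, n)
    list(states = states, truth = truth,
         spec = list(n = n, dim = dim, depth = depth, branching = branching,
                     step = step, perturb_sd = perturb_sd, decay = decay,
                     scale_sd = scale_sd, width_ratio = width_ratio,
                     segments_per_edge = segments_per_edge, seed = seed))
  })
}

#' Simulate a discrete-cluster Gaussian mixture with exact truth
#'
#' Randomly placed means with randomly oriented covariances produce mostly
#' isolated clusters, the contrasting regime to the differentiation tree.
#' As in real cell-state manifolds, each cluster is intrinsically
#' low-dimensional (principal sds decay exponentially) and clusters differ in
#' overall compactness (`scale_sd`), so the landscape spans several orders of
#' magnitude in density.
#'
#' @param n total cells.
#' @param n_components number of clusters.
#' @param dim ambient dimensionality.
#' @param separation sd of the component-mean placement, in units of the
#'   typical within-cluster principal sd (~1).
#' @param decay exponential decay rate of the principal sds.
#' @param scale_sd sd of the per-cluster log compactness factor.
#' @param seed integer seed.
#' @return list with `states`, `truth` and `spec`.
#' @export
simulate_cluster_gmm <- function(n = 5000, n_components = 15, dim = 20,
                                 separation = 5, decay = 0.3, scale_sd = 0.6,
                                 seed = 0L) {
  stopifnot(n_components >= 1, dim >= 2)
  with_seed(seed, {
    means <- matrix(rnorm(n_components * dim, sd = separation), n_components, dim)
    covs <- lapply(seq_len(n_components), function(k) {
      q <- qr.Q(qr(matrix(rnorm(dim * dim), dim, dim)))
      sds <- exp(rnorm(1, 0, scale_sd)) *
        pmax(exp(-decay * (seq_len(dim) - 1)), 0.02)
      q %*% diag(sds^2) %*% t(q)
    })
    w <- rgamma(n_components, shape = 5)
    truth <- new_gmm(w, means, covs)
    states <- sample_gmm(truth, n)
    list(states = states, truth = truth,
         spec = list(n = n, n_components = n_components, dim = dim,
                     separation = separation, decay = decay,
                     scale_sd = scale_sd, seed = seed))
  })
}

#' Simulate a drifting time-series mixture with per-timepoint truth
#'
#' A base Gaussian mixture whose component means translate linearly along
#' fixed per-component drift vectors; each timepoint contributes an equal
#' number of cells and has an exact `gmm_truth`.
#'
#' @param n_per_time cells per timepoint.
#' @param timepoints numeric vector of measurement times (at least 2).
#' @param dim ambient dimensionality.
#' @param n_components mixture components.
#' @param drift drift-vector length per unit time (0 = stationary process).
#' @param seed integer seed.
#' @return list with `states`, `times`, `truths` (list of `gmm_truth` named
#'   by timepoint) and `spec`.
#' @export
simulate_time_series <- function(n_per_time = 400,
                                 timepoints = seq(0, 1, by = 0.25),
                                 dim = 10, n_components = 3, drift = 2,
                                 seed = 0L) {
  stopifnot(length(timepoints) >= 2, n_per_time >= 2)
  with_seed(seed, {
    means0 <- matrix(rnorm(n_components * dim, sd = 3), n_components, dim)
    covs <- lapply(seq_len(n_components), function(k) {
      # low intrinsic dimensionality and per-component compactness diversity,
      # as in the other generators, so that a few hundred cells per timepoint
      # support an informative density fit
      q <- qr.Q(qr(matrix(rnorm(dim * dim), dim, dim)))
      sds <- exp(rnorm(1, 0, 0.5)) * pmax(exp(-0.7 * (seq_len(dim) - 1)), 0.02)
      q %*% diag(sds^2) %*% t(q)
    })
    dirs <- t(vapply(seq_len(n_components), function(k) {
      u <- rnorm(dim); u / sqrt(sum(u^2)) * drift
    }, numeric(dim)))
    truths <- list(); states <- NULL; times <- NULL
    for (t in timepoints) {
      g <- new_gmm(rep(1 / n_components, n_components), means0 + dirs * t, covs)
      truths[[as.character(t)]] <- g
      s <- sample_gmm(g, n_per_time)
      rownames(s) <- paste0("t", t, "_", rownames(s))
      states <- rbind(states, s)
      times <- c(times, rep(t, n_per_time))
    }
    list(states = states, times = times, truths = truths,
         spec = list(n_per_time = n_per_time, timepoints = timepoints,
                     dim = dim, n_components = n_components, drift = drift,
                     seed = seed))
  })
}

#' Simulate paired expression and chromatin data with a low-density corridor
#'
#' A 1-D latent pseudotime with dense end states and a sparse mid-trajectory
#' corridor, embedded in a 2-D state space. One driver gene ramps steeply
#' inside the corridor; background genes ramp equally steeply but inside the
#' dense regions, or stay flat. Peaks are programmed as primed (open from the
#' trajectory start, rising mid-way), lineage-specific (opening only late) or
#' background (constitutive); accessibility tracks the driver's activation so
#' all programmed peaks correlate with it.
#'
#' @param n cells.
#' @param n_genes total genes (1 driver + ramping + flat background genes).
#' @param n_ramp_bg background genes with ramps in dense regions.
#' @param n_primed,n_lineage,n_background_peaks peak counts per class.
#' @param corridor pseudotime interval of low density.
#' @param depth mean fragment count of a fully open peak per cell.
#' @param seed integer seed.
#' @return list with `states`, `pseudotime`, `expression`,
#'   `peak_accessibility` (smooth), `peak_counts` (integer), `peak_class`,
#'   `driver_gene`, `corridor` and `spec`.
#' @export
simulate_expression_and_peaks <- function(n = 250, n_genes = 25, n_ramp_bg = 10,
                                          n_primed = 4, n_lineage = 4,
                                          n_background_peaks = 20,
                                          corridor = c(0.35, 0.65),
                                          depth = 20, seed = 0L) {
  stopifnot(n_genes >= n_ramp_bg + 1, n >= 50)
  with_seed(seed, {
    # dense pools at both trajectory ends, plus a handful of bridge cells
    # crossing the sparse corridor
    lo <- rbeta(n, 1.5, 9) * corridor[1]
    hi <- 1 - rbeta(n, 1.5, 9) * (1 - corridor[2])
    s <- ifelse(runif(n) < 0.5, lo, hi)
    bridge <- seq_len(max(3L, round(0.04 * n)))
    s[bridge] <- runif(length(bridge), corridor[1], corridor[2])
    states <- cbind(10 * s, rnorm(n, sd = 0.3))
    rownames(states) <- paste0("cell_", seq_len(n))

    ramp <- function(center, width) stats::plogis((s - center) / width)
    genes <- matrix(rnorm(n * n_genes, sd = 0.02), n, n_genes)
    mid <- mean(corridor)
    genes[, 1] <- genes[, 1] + ramp(mid, 0.04)  # the corridor driver
    # background ramps sit inside the dense pools, away from the corridor
    bg_centers <- runif(n_ramp_bg, 0, 1)
    bg_centers <- ifelse(bg_centers < 0.5,
                         0.04 + bg_centers * 0.3 * corridor[1],
                         corridor[2] + 0.55 * (1 - corridor[2]) +
                           (bg_centers - 0.5) * 0.6 * (1 - corridor[2]))
    for (j in seq_len(n_ramp_bg))
      genes[, j + 1] <- genes[, j + 1] + ramp(bg_centers[j], 0.04)
    colnames(genes) <- c("gene_driver",
                         paste0("gene_ramp", seq_len(n_ramp_bg)),
                         paste0("gene_flat", seq_len(n_genes - n_ramp_bg - 1)))

    n_peaks <- n_primed + n_lineage + n_background_peaks
    acc <- matrix(0, n, n_peaks)
    cls <- c(rep("primed", n_primed), rep("lineage_specific", n_lineage),
             rep("background", n_background_peaks))
    for (p in seq_len(n_peaks)) {
      base <- switch(cls[p],
                     primed = 0.45 + 0.35 * ramp(mid, 0.1),
                     lineage_specific = 0.8 * ramp(0.7, 0.05),
                     background = rep(0.3, n))
      # closed chromatin yields no fragments at all
      base[base < 0.02] <- 0
      acc[, p] <- ifelse(base > 0, pmax(base + rnorm(n, sd = 0.01), 0), 0)
    }
    colnames(acc) <- paste0("peak_", seq_len(n_peaks))
    counts <- matrix(rpois(n * n_peaks, lambda = acc * depth), n, n_peaks,
                     dimnames = dimnames(acc))
    rownames(genes) <- rownames(acc) <- rownames(states)

    list(states = states, pseudotime = s, expression = genes,
         peak_accessibility = acc, peak_counts = counts,
         peak_class = setNames(cls, colnames(acc)),
         driver_gene = "gene_driver", corridor = corridor,
         spec = list(n = n, n_genes = n_genes, n_ramp_bg = n_ramp_bg,
                     n_primed = n_primed, n_lineage = n_lineage,
                     n_background_peaks = n_background_peaks,
                     corridor = corridor, depth = depth, seed = seed))
  })
}
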