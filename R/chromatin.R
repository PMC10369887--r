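# Chromatin accessibility scoring: TF-IDF normalization, gene-peak links
# with an empirical permutation null, Poisson peak-openness calls, primed
# versus lineage-specific peak classification and scores, and in-silico
# ChIP-style TF binding scores.

#' TF-IDF normalization of a peak count matrix
#'
#' Term frequency = count over the cell's total; inverse document frequency =
#' `log(1 + N / (1 + n_p))` with `N` cells and `n_p` cells in which peak p is
#' nonzero (log-scaled, +1-smoothed variant). Up-weights peaks that are highly
#' accessible in few cells. Dense and `Matrix` sparse inputs are supported.
#'
#' @param counts cells-by-peaks nonnegative count matrix.
#' @return normalized matrix of the same shape and class family.
#' @export
tfidf_normalize <- function(counts) {
  if (any(counts < 0)) stop("'counts' must be nonnegative")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) stop("all-zero cells cannot be TF-IDF normalized")
  n_cells <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  idf <- log(1 + n_cells / (1 + df))
  if (inherits(counts, "Matrix")) {
    Matrix::Diagonal(x = 1 / totals) %*% counts %*% Matrix::Diagonal(x = idf)
  } else {
    (counts / totals) * rep(idf, each = n_cells)
  }
}

#' Gene-peak correlation with an empirical permutation null
#'
#' Pearson correlation between a gene's expression and each candidate peak's
#' accessibility across metacells. Significance comes from an empirical null:
#' the metacell labels of the gene's expression are permuted `B` times within
#' the gene and `p = (1 + #{|r_perm| >= |r|}) / (B + 1)`. Pairs with
#' `corr >= min_corr` and `p <= max_p` are flagged as linked.
#'
#' @param expr metacells-by-genes expression matrix (column names = genes).
#' @param access metacells-by-peaks accessibility matrix (column names =
#'   peaks), same metacells.
#' @param pairs data.frame with columns `gene` and `peak` naming candidate
#'   pairs (e.g. peaks within a window around each gene).
#' @param B number of permutations (at least 99).
#' @param seed permutation seed.
#' @param min_corr,max_p retention thresholds.
#' @return data.frame `gene, peak, corr, p, linked`.
#' @export
gene_peak_correlation <- function(expr, access, pairs, B = 999L, seed = 0L,
                                  min_corr = 0.1, max_p = 0.1) {
  expr <- as.matrix(expr); access <- as.matrix(access)
  if (nrow(expr) != nrow(access)) stop("'expr' and 'access' must share metacells")
  if (B < 99L) stop("at least 99 permutations are required")
  pairs$gene <- as.character(pairs$gene); pairs$peak <- as.character(pairs$peak)
  out <- pairs[, c("gene", "peak")]
  out$corr <- NA_real_; out$p <- NA_real_
  with_seed(seed, {
    for (g in unique(pairs$gene)) {
      rows <- which(pairs$gene == g)
      e <- expr[, g]
      if (sd(e) == 0) stop(sprintf("expression of gene '%s' is constant", g))
      a <- access[, pairs$peak[rows], drop = FALSE]
      if (any(apply(a, 2, sd) == 0))
        stop("a candidate peak has constant accessibility")
      r <- drop(cor(e, a))
      perms <- vapply(seq_len(B), function(b) sample(e), numeric(length(e)))
      rp <- abs(cor(a, perms))  # peaks x B
      out$corr[rows] <- r
      out$p[rows] <- (1 + rowSums(rp >= abs(r))) / (B + 1)
    }
  })
  out$linked <- out$corr >= min_corr & out$p <= max_p
  out
}

#' Poisson peak-openness calls for a cell type
#'
#' The background rate is `lambda = total fragments / effective genome
#' length`, with the effective length `num_peaks * 5000`. A peak with `n`
#' fragments is open if the upper-tail Poisson probability of observing more
#' than `n` fragments is below `alpha`.
#'
#' @param counts per-peak fragment counts aggregated over the cell type's
#'   cells (named vector).
#' @param num_peaks number of peaks defining the effective genome length
#'   (default `length(counts)`).
#' @param alpha openness significance level.
#' @return named logical vector, `TRUE` = open.
#' @export
peak_openness <- function(counts, num_peaks = length(counts), alpha = 1e-2) {
  if (any(counts < 0)) stop("'counts' must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("zero total fragments")
  lambda <- total / (num_peaks * 5000)
  p_upper <- ppois(counts, lambda, lower.tail = FALSE)  # P(X > n)
  setNames(p_upper < alpha, names(counts))
}

#' Classify linked peaks as primed or lineage-specific
#'
#' Among peaks that are linked to a gene and relevant to the lineage under
#' study, a peak already open in the reference (stem) cell type is `primed`;
#' one closed there is `lineage_specific`. All other peaks are `excluded`.
#'
#' @param links a [gene_peak_correlation()] table.
#' @param lineage_relevant character vector of lineage-relevant peak ids
#'   (e.g. from an external differential-accessibility screen).
#' @param reference_open named logical vector of [peak_openness()] calls in
#'   the reference cell type.
#' @return `links` with an added `class` column.
#' @export
classify_peaks <- function(links, lineage_relevant, reference_open) {
  cls <- rep("excluded", nrow(links))
  eligible <- links$linked & links$peak %in% lineage_relevant
  open <- reference_open[links$peak]
  if (any(eligible & is.na(open)))
    stop("openness call missing for a lineage-relevant linked peak")
  cls[eligible & open] <- "primed"
  cls[eligible & !open] <- "lineage_specific"
  links$class <- cls
  links
}

#' Per-cell primed or lineage-specific accessibility score of a gene
#'
#' Correlation-weighted average of the accessibility of the gene's peaks of
#' the requested class: `sum_p a_ip c_gp / sum_p c_gp`. A gene without peaks
#' of that class yields `NA` (not zero), with a message.
#'
#' @param access cells-by-peaks accessibility matrix (typically imputed,
#'   TF-IDF normalized; column names = peaks).
#' @param links a classified link table ([classify_peaks()]).
#' @param gene gene id.
#' @param class `"primed"` or `"lineage_specific"`.
#' @return per-cell numeric scores (or `NA`s).
#' @export
accessibility_scores <- function(access, links, gene,
                                 class = c("primed", "lineage_specific")) {
  class <- match.arg(class)
  access <- as.matrix(access)
  sel <- links$gene == gene & links$class == class
  if (!any(sel)) {
    message(sprintf("gene '%s' has no %s peaks; returning NA", gene, class))
    return(rep(NA_real_, nrow(access)))
  }
  w <- links$corr[sel]
  drop(access[, links$peak[sel], drop = FALSE] %*% w) / sum(w)
}

#' Accessibility score matrix over many genes
#'
#' Applies [accessibility_scores()] to every gene present in the link table,
#' returning a cells-by-genes matrix (columns of all-`NA` for genes without
#' peaks of the class).
#'
#' @inheritParams accessibility_scores
#' @export
accessibility_score_matrix <- function(access, links,
                                       class = c("primed", "lineage_specific")) {
  class <- match.arg(class)
  genes <- unique(links$gene)
  out <- vapply(genes, function(g)
    suppressMessages(accessibility_scores(access, links, g, class)),
    numeric(nrow(access)))
  matrix(out, nrow = nrow(access), dimnames = list(rownames(access), genes))
}

#' In-silico ChIP-style TF binding scores
#'
#' Combines motif match strength with expression-accessibility correlation:
#' per TF, motif scores are scaled by the TF's maximum score and each peak's
#' maximum accessibility, min-max normalized across the TF's peaks, and
#' multiplied by the TF-expression/peak-accessibility correlation. The sign of
#' the correlation is preserved (negative = repressive); magnitudes below
#' `min_score` are set to exactly 0. A TF with a degenerate min-max (single
#' peak or constant scaled scores) gets all-zero scores with a warning.
#'
#' @param correlations peaks-by-TFs matrix of expression-accessibility
#'   (Spearman) correlations.
#' @param motif_scores peaks-by-TFs matrix of motif match scores.
#' @param max_access per-peak maximum accessibility across cell types.
#' @param min_score minimum retained magnitude (default 0.15).
#' @return peaks-by-TFs matrix with entries in `[-1, 1]`.
#' @export
insilico_chip <- function(correlations, motif_scores, max_access,
                          min_score = 0.15) {
  correlations <- as.matrix(correlations); motif_scores <- as.matrix(motif_scores)
  if (!all(dim(correlations) == dim(motif_scores)))
    stop("'correlations' and 'motif_scores' shapes differ")
  if (length(max_access) != nrow(motif_scores))
    stop("'max_access' must have one entry per peak")
  x <- matrix(0, nrow(motif_scores), ncol(motif_scores),
              dimnames = dimnames(motif_scores))
  for (j in seq_len(ncol(motif_scores))) {
    scaled <- motif_scores[, j] / max(motif_scores[, j]) * max_access
    rng <- range(scaled)
    if (nrow(motif_scores) < 2L || rng[1] == rng[2]) {
      warning(sprintf("TF %d has a degenerate min-max; scores set to 0", j))
      next
    }
    x[, j] <- correlations[, j] * (scaled - rng[1]) / (rng[2] - rng[1])
  }
  x[abs(x) < min_score] <- 0
  x
}
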