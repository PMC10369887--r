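# Density-weighted gene change scores: nominate genes whose expression
# changes fastest inside low-density (transitory) cell states.

#' Local expression variability per cell and gene
#'
#' For each cell and gene, the maximum over the cell's k nearest neighbors of
#' the absolute expression difference divided by the state-space distance to
#' that neighbor — the steepest local expression gradient.
#'
#' @param expr cells-by-genes expression matrix (typically imputed).
#' @param states cell-state matrix used for the neighbor graph (same cells).
#' @param k neighbors per cell (default 15).
#' @return cells-by-genes matrix of local variabilities.
#' @export
local_variability <- function(expr, states, k = 15L) {
  expr <- as.matrix(expr)
  states <- as_state_matrix(states, "states")
  if (nrow(expr) != nrow(states)) stop("'expr' and 'states' must cover the same cells")
  nn <- knn_exact(states, as.integer(k))
  if (any(nn$dist == 0))
    stop("zero neighbor distances (duplicated states); deduplicate first")
  out <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(k)) {
    cand <- abs(expr - expr[nn$index[, j], , drop = FALSE]) / nn$dist[, j]
    out <- pmax(out, cand)
  }
  out
}

#' Density-weighted gene change scores
#'
#' Sums each gene's local variability over a selected cell subset, weighting
#' every cell by the reciprocal of its cell-state density, so that expression
#' change concentrated in sparsely populated (transitory) states scores
#' highest.
#'
#' @param variability cells-by-genes matrix from [local_variability()].
#' @param log_density per-cell log-densities from a [cell_density()] fit.
#' @param subset indices of the cells of interest (default all).
#' @return named numeric vector of per-gene scores.
#' @export
change_scores <- function(variability, log_density,
                          subset = seq_len(nrow(variability))) {
  if (length(subset) == 0L) stop("'subset' must be nonempty")
  if (length(log_density) != nrow(variability))
    stop("'log_density' must have one value per cell")
  w <- exp(-log_density[subset])
  colSums(variability[subset, , drop = FALSE] * w)
}

#' Flag driver genes above the 95th score percentile
#'
#' Genes with change scores strictly above the 95th percentile
#' (linear-interpolation convention), sorted by decreasing score. With fewer
#' than 20 genes the percentile is not meaningful: all genes are returned
#' sorted, unflagged, with a warning.
#'
#' @param scores named per-gene scores ([change_scores()]).
#' @param percentile gating percentile.
#' @return data.frame with columns `gene`, `score`, `driver`, sorted by
#'   decreasing score.
#' @export
select_driver_genes <- function(scores, percentile = 0.95) {
  ord <- order(scores, decreasing = TRUE)
  out <- data.frame(gene = names(scores)[ord] %||% as.character(ord),
                    score = unname(scores[ord]))
  if (length(scores) < 20L) {
    warning("fewer than 20 genes: percentile gating skipped")
    out$driver <- FALSE
    return(out)
  }
  thr <- unname(quantile(scores, percentile, type = 7))
  out$driver <- out$score > thr
  if (!any(out$driver))
    warning("no gene strictly exceeds the score percentile (tied scores?)")
  out
}
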