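# Branch selection from fate probabilities, the pseudotime-to-state
# trajectory curve, the joint (pseudotime x real-time) density and marginal
# cell-type proportions over time.

#' Fate-probability branch threshold over pseudotime
#'
#' On a pseudotime grid (default 500 points spanning the observed range), the
#' threshold at grid time t is the running maximum over the grid of the 99th
#' percentile (linear interpolation) of the fate probabilities of all cells
#' with pseudotime at or below t; it is non-decreasing by construction.
#'
#' @param pseudotime per-cell pseudotime.
#' @param fate_probability per-cell probability of the fate of interest, in
#'   `[0, 1]`.
#' @param grid_points number of grid points.
#' @param percentile percentile of the fate probabilities.
#' @return object of class `branch_threshold` with `grid` and `threshold`;
#'   evaluate at cell pseudotimes with `predict()`.
#' @export
branch_threshold <- function(pseudotime, fate_probability, grid_points = 500L,
                             percentile = 0.99) {
  if (length(pseudotime) == 0L) stop("no cells supplied")
  if (length(pseudotime) != length(fate_probability)) stop("length mismatch")
  if (any(fate_probability < 0 | fate_probability > 1))
    stop("'fate_probability' must lie in [0, 1]")
  grid <- seq(min(pseudotime), max(pseudotime), length.out = grid_points)
  q <- vapply(grid, function(g) {
    below <- fate_probability[pseudotime <= g]
    if (length(below) == 0L) -Inf else unname(quantile(below, percentile, type = 7))
  }, numeric(1))
  structure(list(grid = grid, threshold = cummax(q)), class = "branch_threshold")
}

#' @param object a `branch_threshold`.
#' @param newdata pseudotimes at which to evaluate; each is mapped to the next
#'   larger grid point (clamped to the final grid point beyond the grid).
#' @param ... unused.
#' @rdname branch_threshold
#' @export
predict.branch_threshold <- function(object, newdata, ...) {
  i <- findInterval(newdata, object$grid, left.open = TRUE) + 1L
  i[i > length(object$grid)] <- length(object$grid)
  object$threshold[i]
}

#' Select the cells of a fate branch
#'
#' Cells whose fate probability exceeds the branch threshold evaluated at
#' their pseudotime minus `epsilon`. Increasing `epsilon` only ever adds
#' cells.
#'
#' @param pseudotime,fate_probability per-cell values.
#' @param threshold a [branch_threshold()] object (computed from the same
#'   cells when `NULL`).
#' @param epsilon slack below the threshold still accepted (default 0.01).
#' @return integer vector of selected cell indices.
#' @export
select_branch_cells <- function(pseudotime, fate_probability, threshold = NULL,
                                epsilon = 0.01) {
  threshold <- threshold %||% branch_threshold(pseudotime, fate_probability)
  which(fate_probability > predict(threshold, pseudotime) - epsilon)
}

#' Pseudotime-to-state trajectory curve
#'
#' Maps pseudotime to each state-space coordinate with an independent GP
#' trend per dimension (Matern-5/2, length scale 1 on pseudotime in `[0, 1]`,
#' observation-noise variance 0.01, mean = the branch average of the
#' coordinate), giving a continuous curve through the cell-state space.
#'
#' @param states state matrix of the branch cells.
#' @param pseudotime their pseudotimes; rescaled to `[0, 1]` if outside.
#' @param length_scale,variance,noise GP settings per dimension.
#' @param landmarks optional inducing-point count passed to [gp_trend()].
#' @return object of class `trajectory_curve`; `predict()` at pseudotimes
#'   returns a matrix of states.
#' @export
trajectory_curve <- function(states, pseudotime, length_scale = 1,
                             variance = 1, noise = 0.01, landmarks = NULL) {
  states <- as_state_matrix(states, "states")
  if (nrow(states) != length(pseudotime)) stop("length mismatch")
  if (nrow(states) < 10L) stop("at least 10 branch cells are required")
  rescaled <- FALSE
  if (min(pseudotime) < 0 || max(pseudotime) > 1) {
    pseudotime <- (pseudotime - min(pseudotime)) / diff(range(pseudotime))
    rescaled <- TRUE
  }
  trends <- lapply(seq_len(ncol(states)), function(mdim)
    gp_trend(pseudotime, states[, mdim], length_scale = length_scale,
             variance = variance, noise = noise, landmarks = landmarks))
  structure(list(trends = trends, dim = ncol(states), rescaled = rescaled),
            class = "trajectory_curve")
}

#' @param object a `trajectory_curve`.
#' @param newdata pseudotimes in `[0, 1]`.
#' @param ... unused.
#' @rdname trajectory_curve
#' @export
predict.trajectory_curve <- function(object, newdata, ...) {
  vapply(object$trends, function(tr) predict(tr, newdata),
         numeric(length(newdata)))
}

#' Assign a cell type to each point of a trajectory
#'
#' For each pseudotime grid point, evaluates every cell type's density model
#' at the trajectory state and returns the label with the largest density.
#' Ties are broken by label order (a message reports them).
#'
#' @param curve a [trajectory_curve()].
#' @param celltype_densities named list of `cell_density` fits, one per type.
#' @param s_grid pseudotime grid (default 200 points on `[0, 1]`).
#' @return character vector of labels, one per grid point.
#' @export
assign_celltypes <- function(curve, celltype_densities,
                             s_grid = seq(0, 1, length.out = 200L)) {
  if (length(celltype_densities) == 0L) stop("no cell-type density models given")
  labels <- names(celltype_densities) %||%
    paste0("type_", seq_along(celltype_densities))
  pts <- predict(curve, s_grid)
  dens <- vapply(celltype_densities, function(f) unname(predict(f, pts)),
                 numeric(length(s_grid)))
  dens <- matrix(dens, nrow = length(s_grid))
  ties <- apply(dens, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sprintf("%d grid point(s) had tied densities; first label in order wins",
                    sum(ties)))
  labels[apply(dens, 1, which.max)]
}

#' Joint pseudotime-by-real-time log-density along a trajectory
#'
#' Evaluates a time-continuous density model along the trajectory curve on a
#' pseudotime grid (default 200 points) crossed with a real-time grid
#' (default 500 points between each pair of adjacent measured timepoints).
#'
#' @param curve a [trajectory_curve()].
#' @param model a [cell_density_time()] fit.
#' @param s_grid pseudotime grid.
#' @param t_grid real-time grid; `NULL` builds the default from the model's
#'   measured timepoints.
#' @param points_between grid points per adjacent timepoint interval.
#' @return list of class `joint_density_grid` with `s_grid`, `t_grid` and the
#'   `log_density` matrix (pseudotime rows, time columns).
#' @export
trajectory_density <- function(curve, model,
                               s_grid = seq(0, 1, length.out = 200L),
                               t_grid = NULL, points_between = 500L) {
  if (is.null(t_grid)) {
    ut <- sort(unique(model$times))
    t_grid <- unique(unlist(lapply(seq_len(length(ut) - 1L), function(i)
      seq(ut[i], ut[i + 1L], length.out = points_between + 1L))))
  }
  pts <- predict(curve, s_grid)
  ld <- predict_time_grid(model, pts, t_grid)
  structure(list(s_grid = s_grid, t_grid = t_grid, log_density = ld),
            class = "joint_density_grid")
}

#' Marginal cell-type proportions over real time
#'
#' Integrates the joint density over the pseudotime segments annotated with
#' each cell type (trapezoidal rule) and normalizes across cell types at every
#' time point, so each time's proportions sum to one.
#'
#' @param grid a [trajectory_density()] result.
#' @param annotation per-pseudotime-grid-point cell type labels
#'   ([assign_celltypes()]).
#' @return matrix of proportions, times in rows, cell types in columns.
#' @export
marginal_proportions <- function(grid, annotation) {
  if (length(annotation) != length(grid$s_grid))
    stop("'annotation' must have one label per pseudotime grid point")
  labels <- unique(annotation)
  # Work on a per-time shifted scale so exp() cannot overflow; the shift
  # cancels in the normalization.
  shift <- apply(grid$log_density, 2, max)
  dens <- exp(sweep(grid$log_density, 2, shift))
  mass <- vapply(labels, function(h) {
    ind <- as.numeric(annotation == h)
    apply(dens * ind, 2, function(col) trapz(grid$s_grid, col))
  }, numeric(ncol(dens)))
  mass <- matrix(mass, ncol = length(labels),
                 dimnames = list(NULL, labels))
  tot <- rowSums(mass)
  if (any(tot == 0)) stop("zero total trajectory mass at a time point")
  sweep(mass, 1, tot, "/")
}
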