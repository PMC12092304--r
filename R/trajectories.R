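#' Fit LOESS trajectories of expression against amyloid density
#'
#' For each gene, a local-linear LOESS (degree 1, tricube weights, no
#' robustness iterations, exact `surface = "direct"` prediction) of
#' normalized expression on the spot-level amyloid density, with the
#' configured span. Predictions are evaluated on `grid_size` evenly spaced
#' density values over the observed range and z-standardized per gene
#' across the grid; genes with zero prediction variance map to the
#' all-zero row.
#'
#' @param expr genes x spots normalized expression.
#' @param density per-spot amyloid intensity (0-255); spots with
#'   non-finite density are dropped.
#' @param span LOESS span in `(0, 1]` (default 0.75).
#' @param grid_size number of density evaluation points (default 100).
#' @param group tag recorded on the result (trajectories are fitted within
#'   one comparison group at a time).
#' @return a `trajectory_set` list: `genes`, `grid`, `predictions`
#'   (genes x grid, standardized), `cluster` (NA until
#'   [cluster_trajectories()]), `group`.
#' @export
fit_density_trajectories <- function(expr, density, span = 0.75,
                                     grid_size = 100L, group = NA_character_) {
  if (!(span > 0 && span <= 1)) stop_invalid("span must lie in (0, 1]")
  ok <- is.finite(density)
  n <- sum(ok)
  n_min <- max(10, ceiling(span * n))
  if (n < 10 || n < n_min)
    stop_invalid("need at least ", max(10, n_min),
                 " spots with finite density for local fits, got ", n)
  density <- density[ok]
  expr <- expr[, ok, drop = FALSE]
  grid <- seq(min(density), max(density), length.out = grid_size)
  genes <- rownames(expr)
  pred <- matrix(0, length(genes), grid_size,
                 dimnames = list(genes, NULL))
  for (g in genes) {
    y <- expr[g, ]
    if (stats::sd(y) == 0) next  # degenerate: all-zero standardized row
    fit <- stats::loess(y ~ density, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    yp <- stats::predict(fit, newdata = data.frame(density = grid))
    s <- stats::sd(yp)
    pred[g, ] <- if (is.finite(s) && s > 0) (yp - mean(yp)) / s else 0
  }
  structure(list(genes = genes, grid = grid, predictions = pred,
                 cluster = stats::setNames(rep(NA_integer_, length(genes)),
                                           genes),
                 group = group),
            class = "trajectory_set")
}

#' Cluster standardized expression trajectories
#'
#' Agglomerative hierarchical clustering (complete linkage) on Euclidean
#' distances between the standardized prediction rows, cut at `k` clusters
#' or at `cut_height`. Labels are renumbered by descending cluster size
#' (ties broken by first occurrence), and per-cluster mean trajectories
#' are attached.
#'
#' @param traj a [fit_density_trajectories()] result.
#' @param k number of clusters (ignored when `cut_height` given).
#' @param cut_height optional dendrogram cut height.
#' @return the `trajectory_set` with `cluster` labels, `cluster_means`
#'   (clusters x grid) and `hclust` attached.
#' @export
cluster_trajectories <- function(traj, k = NULL, cut_height = NULL) {
  if (!inherits(traj, "trajectory_set")) stop_invalid("traj must be a trajectory_set")
  n <- length(traj$genes)
  if (n < 2L) stop_invalid("need at least two genes to cluster")
  if (is.null(cut_height)) {
    if (is.null(k) || k < 1) stop_invalid("k must be >= 1")
    if (k > n) stop_invalid("k exceeds the number of genes (", n, ")")
  }
  hc <- stats::hclust(stats::dist(traj$predictions, method = "euclidean"),
                      method = "complete")
  lab <- if (is.null(cut_height)) stats::cutree(hc, k = k)
         else stats::cutree(hc, h = cut_height)
  sizes <- table(lab)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  lab <- relab[as.character(lab)]
  names(lab) <- traj$genes
  means <- do.call(rbind, lapply(sort(unique(lab)), function(cl)
    colMeans(traj$predictions[lab == cl, , drop = FALSE])))
  rownames(means) <- sort(unique(lab))
  traj$cluster <- lab
  traj$cluster_means <- means
  traj$hclust <- hc
  traj
}
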