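# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force step-up BH adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Explicit position-by-position weighted KS running sum (exponent 1).
es_oracle <- function(ranks, set) {
  ord <- names(sort(ranks, decreasing = TRUE))
  vals <- sort(ranks, decreasing = TRUE)
  N <- length(ord); m <- sum(ord %in% set)
  W <- sum(abs(vals[ord %in% set]))
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- if (ord[i] %in% set) rs + abs(vals[i]) / W else rs - 1 / (N - m)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# Direct tricube local-linear regression at each grid point: the q =
# floor(span * n) nearest neighbors in x, weights (1 - (d/dmax)^3)^3,
# weighted degree-1 least squares.
tricube_local_fit <- function(x, y, grid, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d, partial = q)[q]
    w <- pmax(1 - pmin(d / dmax, 1)^3, 0)^3
    use <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[use] - x0), y[use], w[use])
    fit$coefficients[1]
  }, 0)
}

# Euclidean-radius neighbor oracle on physical coordinates: spots whose
# center distance is (roughly) pitch for order 1, and in
# {sqrt(3), 2} * pitch for order 2.
euclid_neighbors <- function(grid, spot_id, order, pitch) {
  i <- match(spot_id, grid$spot_id)
  d <- sqrt((grid$x - grid$x[i])^2 + (grid$y - grid$y[i])^2)
  radii <- if (order == 1) pitch else c(sqrt(3) * pitch, 2 * pitch)
  hit <- rep(FALSE, nrow(grid))
  for (r in radii) hit <- hit | abs(d - r) < 1e-6 * pitch
  grid$spot_id[hit & grid$spot_id != spot_id]
}

# Small two-group spot table for downsampling tests.
make_units <- function(sizes_by_sample, groups_by_sample) {
  samples <- rep(names(sizes_by_sample), sizes_by_sample)
  data.frame(unit = seq_along(samples), sample = samples,
             group = groups_by_sample[samples],
             stringsAsFactors = FALSE)
}

# Adjusted Rand index between two labelings.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}
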