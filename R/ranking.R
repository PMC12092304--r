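#' Signed probabilistic fold change
#'
#' `PFC = (-log10 adjusted p) * log2 fold change`; the adjusted p-value is
#' floored at 1e-300 before logging (a zero triggers a warning). Base 10 is
#' a reporting choice: percentile ranks are invariant to the log base.
#'
#' @param adj_p adjusted p-values in `(0, 1]`.
#' @param lfc log2 fold changes.
#' @return signed PFC values.
#' @export
signed_pfc <- function(adj_p, lfc) {
  if (length(adj_p) != length(lfc)) stop_invalid("adj_p and lfc lengths differ")
  if (any(adj_p <= 0, na.rm = TRUE))
    warning("adjusted p-values of 0 floored at 1e-300", call. = FALSE)
  if (any(adj_p > 1, na.rm = TRUE)) stop_invalid("adjusted p-values above 1")
  (-log10(pmax(adj_p, 1e-300))) * lfc
}

#' Percentile ranks of PFC within a table
#'
#' `100 * rank(pfc, ties = "average") / n`, so the strongest positive gene
#' sits at 100 and ties share percentiles.
#'
#' @param pfc signed PFC values.
#' @return percentiles in `(0, 100]`.
#' @export
pfc_percentile <- function(pfc) {
  100 * rank(pfc, ties.method = "average") / length(pfc)
}

#' Combine two comparisons by average PFC percentile
#'
#' Restricts both tables to their shared genes, assigns PFC percentile
#' ranks within each table, averages the two percentiles, and returns the
#' `top_n` genes by combined score (descending). Genes absent from either
#' table are excluded rather than imputed.
#'
#' @param a,b data.frames with `gene` and `pfc` columns (or `adj_p` +
#'   `lfc`, from which PFC is computed).
#' @param top_n number of genes returned (default all shared genes).
#' @return data.frame: `gene`, `percentile_a`, `percentile_b`, `combined`.
#' @export
percentile_combine <- function(a, b, top_n = NULL) {
  a <- ensure_pfc(a); b <- ensure_pfc(b)
  shared <- intersect(a$gene, b$gene)
  if (!length(shared)) stop_invalid("the tables share no genes")
  a <- a[match(shared, a$gene), ]; b <- b[match(shared, b$gene), ]
  pa <- pfc_percentile(a$pfc); pb <- pfc_percentile(b$pfc)
  out <- data.frame(gene = shared, percentile_a = pa, percentile_b = pb,
                    combined = (pa + pb) / 2, stringsAsFactors = FALSE)
  out <- out[order(-out$combined), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

ensure_pfc <- function(tab) {
  if (!"pfc" %in% colnames(tab)) {
    if (!all(c("adj_p", "lfc") %in% colnames(tab)))
      stop_invalid("table needs a 'pfc' column or 'adj_p' + 'lfc'")
    tab$pfc <- signed_pfc(tab$adj_p, tab$lfc)
  }
  tab
}

#' Rank genes by divergence of PFC between two comparisons
#'
#' Divergence score is `pfc_a - pfc_b`; genes are ranked by absolute
#' score, with opposite-sign PFC pairs ranked above same-sign pairs of
#' equal |score|. Swapping the tables negates all scores.
#'
#' @param a,b DE tables with `gene` and `pfc` (or `adj_p` + `lfc`).
#' @param top_n rows returned (default all shared genes).
#' @return data.frame: `gene`, `pfc_a`, `pfc_b`, `divergence`,
#'   `opposite_sign`.
#' @export
divergence_rank <- function(a, b, top_n = NULL) {
  a <- ensure_pfc(a); b <- ensure_pfc(b)
  shared <- intersect(a$gene, b$gene)
  if (!length(shared)) stop_invalid("the tables share no genes")
  pa <- a$pfc[match(shared, a$gene)]
  pb <- b$pfc[match(shared, b$gene)]
  out <- data.frame(gene = shared, pfc_a = pa, pfc_b = pb,
                    divergence = pa - pb,
                    opposite_sign = sign(pa) * sign(pb) < 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$divergence), -out$opposite_sign), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

# Weighted (exponent 1) Kolmogorov-Smirnov running-sum enrichment score of
# a gene set within a ranking. `stats` must be sorted descending;
# `in_set` flags the set members in that order.
running_sum_es <- function(stats_sorted, in_set) {
  n <- length(stats_sorted)
  m <- sum(in_set)
  if (m == 0L || m == n) stop_invalid("gene set must be a proper subset of the ranking")
  w <- abs(stats_sorted) * in_set
  denom_hit <- sum(w)
  if (denom_hit == 0) w[in_set] <- 1 / m else w <- w / denom_hit
  steps <- w - (!in_set) / (n - m)
  rs <- cumsum(steps)
  unname(rs[which.max(abs(rs))])
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Weighted KS running-sum enrichment (weight exponent 1) of each set in a
#' signed ranking (typically PFC). The null draws `n_perm` uniform random
#' gene sets of matching size; NES is the ES divided by the mean |null ES|
#' of matching sign, and the two-sided p-value comes from same-sign null
#' tail counts with +1 smoothing. Sets with fewer than 3 members mapped to
#' the ranking are skipped with a warning; a set covering the whole
#' ranking is rejected. BH adjustment across scored sets.
#'
#' @param ranks named numeric vector, gene -> signed ranking metric.
#' @param sets named list of gene-id vectors.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame: `set_name`, `size`, `es`, `nes`, `p`, `adj_p`.
#' @export
preranked_enrichment <- function(ranks, sets, n_perm = 10000L, seed = 1L) {
  if (is.null(names(ranks))) stop_invalid("ranks must be a named vector")
  ord <- order(ranks, decreasing = TRUE)
  stats_sorted <- ranks[ord]
  gene_order <- names(ranks)[ord]
  n <- length(ranks)
  rows <- list()
  with_local_seed(seed, {
    for (nm in names(sets)) {
      members <- intersect(sets[[nm]], gene_order)
      m <- length(members)
      if (m < 3L) {
        warning("set '", nm, "' has fewer than 3 genes in the ranking; skipped",
                call. = FALSE)
        next
      }
      if (m >= n)
        stop_invalid("set '", nm, "' covers the whole ranking; ES undefined")
      in_set <- gene_order %in% members
      es <- running_sum_es(stats_sorted, in_set)
      null_es <- vapply(seq_len(n_perm), function(i) {
        flag <- logical(n)
        flag[sample.int(n, m)] <- TRUE
        running_sum_es(stats_sorted, flag)
      }, 0)
      same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same))
             else NA_real_
      # two-sided magnitude tail over the full null, +1 smoothing: uniform
      # under a random ranking since |ES| is exchangeable with |null ES|
      p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
      rows[[nm]] <- data.frame(set_name = nm, size = m, es = es, nes = nes,
                               p = p, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      adj_p = numeric(0)))
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted Spearman correlation
#'
#' Rank-transforms `x`, `y` and each covariate, residualizes the x- and
#' y-ranks on the covariate ranks by least squares, and reports the
#' Pearson correlation of the residuals with a t-distribution p-value on
#' `n - 2 - c` degrees of freedom. With no covariates this reduces
#' exactly to the plain Spearman correlation.
#'
#' @param x,y per-sample values.
#' @param covariates optional per-sample matrix or data.frame.
#' @return list: `rho`, `p`, `n`, `df`.
#' @export
adjusted_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y lengths differ")
  cv <- if (is.null(covariates)) matrix(numeric(0), n, 0)
        else as.matrix(as.data.frame(covariates))
  if (nrow(cv) != n) stop_invalid("covariates must have one row per sample")
  c_ <- ncol(cv)
  if (n < c_ + 3) stop_invalid("need at least covariates + 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("x or y is constant: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  if (c_ > 0) {
    rc <- apply(cv, 2, rank)
    Z <- cbind(1, rc)
    rx <- stats::.lm.fit(Z, rx)$residuals
    ry <- stats::.lm.fit(Z, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - c_
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(rho = rho, p = p, n = n, df = df)
}
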