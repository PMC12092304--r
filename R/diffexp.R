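#' Downsampling constraints for spot/cell comparisons
#'
#' Caps applied before spot-level testing: no sample may contribute more
#' than `max_sample_share` of its comparison group, groups may not differ
#' by more than `max_group_fold` in size, and no group may exceed
#' `max_group_size` units.
#'
#' @param max_sample_share maximum within-group share of one sample.
#' @param max_group_fold maximum group-size fold difference.
#' @param max_group_size maximum units per group.
#' @return a `downsample_constraints` list.
#' @export
downsample_constraints <- function(max_sample_share = 0.5,
                                   max_group_fold = 3,
                                   max_group_size = 3000L) {
  if (max_sample_share <= 0 || max_sample_share > 1)
    stop_invalid("max_sample_share must lie in (0, 1]")
  if (max_group_fold < 1) stop_invalid("max_group_fold must be >= 1")
  if (max_group_size < 1) stop_invalid("max_group_size must be >= 1")
  structure(list(max_sample_share = max_sample_share,
                 max_group_fold = max_group_fold,
                 max_group_size = as.integer(max_group_size)),
            class = "downsample_constraints")
}

#' Check the downsampling constraints on a unit table
#'
#' @param units data.frame with `unit`, `sample`, `group`.
#' @param constraints a [downsample_constraints()].
#' @return `TRUE` when all constraints hold (single-sample groups are
#'   exempt from the share cap), else `FALSE`.
#' @export
satisfies_downsample <- function(units, constraints = downsample_constraints()) {
  sizes <- table(units$group)
  if (length(sizes) != 2L) return(FALSE)
  if (any(sizes > constraints$max_group_size)) return(FALSE)
  if (max(sizes) > constraints$max_group_fold * min(sizes)) return(FALSE)
  for (g in names(sizes)) {
    u <- units[units$group == g, ]
    ns <- table(u$sample)
    if (length(ns) > 1L && max(ns) / sum(ns) > constraints$max_sample_share)
      return(FALSE)
  }
  TRUE
}

#' Balanced downsampling of a two-group comparison
#'
#' Uniform random subsampling applied in the order: (i) within each
#' multi-sample group, the largest sample is iteratively capped at
#' `floor(share * group total)` until no sample exceeds the share cap;
#' (ii) each group is capped at the maximum group size; (iii) the larger
#' group is capped at `fold` times the smaller. Because later caps can
#' re-violate the share cap, the three steps repeat until all constraints
#' hold (each pass strictly shrinks the table, so this terminates).
#' Single-sample groups are exempt from the share cap, which they can
#' never satisfy. Deterministic for a given seed.
#'
#' @param units data.frame with columns `unit` (id), `sample`, `group`
#'   (exactly two non-empty levels).
#' @param constraints a [downsample_constraints()].
#' @param seed integer seed.
#' @return the retained subset of `units` (same columns, original order).
#' @export
balance_downsample <- function(units, constraints = downsample_constraints(),
                               seed = 1L) {
  stopifnot(all(c("unit", "sample", "group") %in% colnames(units)))
  groups <- unique(units$group)
  if (length(groups) != 2L) stop_invalid("exactly two groups are required")
  if (any(table(factor(units$group, groups)) == 0L))
    stop_invalid("a comparison group is empty")
  keep <- rep(TRUE, nrow(units))
  with_local_seed(seed, {
    repeat {
      changed <- FALSE
      # (i) per-sample share cap within each multi-sample group
      for (g in groups) {
        repeat {
          gi <- which(keep & units$group == g)
          ns <- table(units$sample[gi])
          if (length(ns) <= 1L) break
          tot <- length(gi)
          worst <- names(ns)[which.max(ns)]
          if (max(ns) / tot <= constraints$max_sample_share) break
          target <- floor(constraints$max_sample_share * tot)
          si <- gi[units$sample[gi] == worst]
          drop <- sample(si, length(si) - target)
          keep[drop] <- FALSE
          changed <- TRUE
        }
      }
      # (ii) per-group size cap
      for (g in groups) {
        gi <- which(keep & units$group == g)
        if (length(gi) > constraints$max_group_size) {
          drop <- sample(gi, length(gi) - constraints$max_group_size)
          keep[drop] <- FALSE
          changed <- TRUE
        }
      }
      # (iii) fold cap on the larger group
      n1 <- sum(keep & units$group == groups[1])
      n2 <- sum(keep & units$group == groups[2])
      big <- if (n1 >= n2) groups[1] else groups[2]
      nb <- max(n1, n2); ns_ <- min(n1, n2)
      if (nb > constraints$max_group_fold * ns_) {
        gi <- which(keep & units$group == big)
        target <- floor(constraints$max_group_fold * ns_)
        drop <- sample(gi, length(gi) - target)
        keep[drop] <- FALSE
        changed <- TRUE
      }
      if (!changed) break
    }
  })
  units[keep, , drop = FALSE]
}

#' Filter genes by detection fraction and name prefix
#'
#' Detection is `count > 0`. `pseudobulk`: detected in at least 1% of
#' either group. `hurdle`: at least 1% of both groups and 10% of either.
#' `hd`: at least 1% of either group. Genes whose symbol starts with RPS,
#' RPL, MT or HB (case-sensitive) are always excluded.
#'
#' @param counts genes x units matrix (raw counts or normalized expression;
#'   only positivity is used).
#' @param groups per-unit group labels (two levels).
#' @param mode filtering rule.
#' @param prefix_exclude symbol prefixes removed before testing.
#' @return character vector of genes to test.
#' @export
gene_filter <- function(counts, groups,
                        mode = c("pseudobulk", "hurdle", "hd"),
                        prefix_exclude = c("RPS", "RPL", "MT", "HB")) {
  mode <- match.arg(mode)
  lv <- unique(groups)
  if (length(lv) != 2L) stop_invalid("exactly two groups are required")
  det1 <- rowMeans(counts[, groups == lv[1], drop = FALSE] > 0)
  det2 <- rowMeans(counts[, groups == lv[2], drop = FALSE] > 0)
  keep <- switch(mode,
    pseudobulk = det1 >= 0.01 | det2 >= 0.01,
    hurdle = (det1 >= 0.01 & det2 >= 0.01) & (det1 >= 0.10 | det2 >= 0.10),
    hd = det1 >= 0.01 | det2 >= 0.01)
  g <- rownames(counts)[keep]
  for (pfx in prefix_exclude) g <- g[!startsWith(g, pfx)]
  g
}

#' Design of a two-group covariate-adjusted comparison
#'
#' @param group metadata column holding the two-level comparison factor.
#' @param covariates named character vector, covariate column ->
#'   `"continuous"` (standardized within the analysis subset) or
#'   `"categorical"`.
#' @param random_effect sample-id column fitted as a fixed covariate (the
#'   package approximates the mixed model with fixed sample effects).
#' @param ref optional reference (baseline) group level.
#' @return a `design_spec` list.
#' @export
design_spec <- function(group = "group", covariates = character(0),
                        random_effect = NULL, ref = NULL) {
  if (length(covariates) &&
      (is.null(names(covariates)) || !all(nzchar(names(covariates)))))
    stop_invalid("covariates must be a named vector: column -> kind")
  if (!all(covariates %in% c("continuous", "categorical")))
    stop_invalid("covariate kinds must be 'continuous' or 'categorical'")
  structure(list(group = group, covariates = covariates,
                 random_effect = random_effect, ref = ref),
            class = "design_spec")
}

# Build a standardized model frame from metadata + design; returns the
# frame, the group factor, and covariate column names (incl. sample-id
# fixed effect when requested).
build_model_frame <- function(meta, design) {
  grp <- meta[[design$group]]
  if (is.null(grp)) stop_invalid("metadata lacks group column '", design$group, "'")
  lv <- unique(as.character(grp))
  if (length(lv) != 2L) stop_invalid("group must have exactly two levels, got ", length(lv))
  if (!is.null(design$ref)) lv <- c(design$ref, setdiff(lv, design$ref))
  grp <- factor(as.character(grp), levels = lv)
  covs <- names(design$covariates)
  mf <- meta[, covs, drop = FALSE]
  cont <- covs[design$covariates == "continuous"]
  mf <- standardize_covariates(mf, cont)
  for (nm in covs[design$covariates == "categorical"])
    mf[[nm]] <- factor(mf[[nm]])
  if (!is.null(design$random_effect)) {
    mf[[design$random_effect]] <- factor(meta[[design$random_effect]])
    covs <- c(covs, design$random_effect)
  }
  mf$group <- grp
  list(frame = mf, group = grp, covariates = covs)
}

# Error with the names of aliased model-matrix columns, if any.
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop_invalid("design is collinear; aliased terms: ",
                 paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' Sum counts to donor-level pseudobulk
#'
#' @param counts genes x units integer matrix.
#' @param donors per-unit donor ids.
#' @return genes x donors integer matrix.
#' @export
pseudobulk_sum <- function(counts, donors) {
  pb <- t(rowsum(t(counts), group = donors))
  storage.mode(pb) <- "integer"
  pb
}

#' Donor-level pseudobulk negative-binomial test
#'
#' Sums raw counts by donor and fits the DESeq2 negative-binomial GLM
#' (Wald test on the group coefficient, local dispersion-trend fit,
#' `independentFiltering = FALSE` and no outlier-based p-value removal so
#' every filtered gene receives a p-value). Continuous covariates are
#' standardized across donors. Fold changes are unshrunk, level 2 vs
#' level 1 (reference).
#'
#' @param counts genes x units raw integer counts.
#' @param donors per-unit donor ids.
#' @param meta per-unit metadata (donor-level columns are collapsed by
#'   donor).
#' @param design a [design_spec()].
#' @param genes tested gene list (e.g. from [gene_filter()]); default all.
#' @return a `de_result` data.frame: `gene`, `lfc`, `p`, `adj_p`,
#'   `significant`, `tested`, `n_group1`, `n_group2`.
#' @export
pseudobulk_nb_test <- function(counts, donors, meta, design,
                               genes = rownames(counts)) {
  pb <- pseudobulk_sum(counts[genes, , drop = FALSE], donors)
  # donor-level metadata: first row per donor, donor-level columns only
  dm <- meta[!duplicated(donors), c(design$group, names(design$covariates)),
             drop = FALSE]
  rownames(dm) <- donors[!duplicated(donors)]
  dm <- dm[colnames(pb), , drop = FALSE]
  bm <- build_model_frame(dm, design)
  if (any(table(bm$group) < 2L))
    stop_invalid("each group needs at least 2 donors")
  covs <- setdiff(bm$covariates, character(0))
  fml <- stats::reformulate(c(covs, "group"))
  X <- stats::model.matrix(fml, data = bm$frame)
  check_full_rank(X)
  cd <- bm$frame
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = pb, colData = cd,
                                        design = fml)
  dds <- tryCatch(
    DESeq2::DESeq(dds, fitType = "local", quiet = TRUE,
                  minReplicatesForReplace = Inf),
    error = function(e)
      DESeq2::DESeq(dds, fitType = "mean", quiet = TRUE,
                    minReplicatesForReplace = Inf))
  lv <- levels(bm$group)
  res <- DESeq2::results(dds, contrast = c("group", lv[2], lv[1]),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  out <- data.frame(gene = rownames(res),
                    lfc = res$log2FoldChange,
                    p = res$pvalue,
                    adj_p = res$padj,
                    stringsAsFactors = FALSE)
  finalize_de(out, n1 = sum(bm$group == lv[1]), n2 = sum(bm$group == lv[2]),
              comparison = paste(lv[2], "vs", lv[1], "(pseudobulk NB)"))
}

# Shared DEResult finishing: significance invariant, tested flag, columns.
finalize_de <- function(out, n1, n2, comparison, lfc_cut = log2(1.5),
                        alpha = 0.05) {
  out$tested <- !is.na(out$p)
  if (is.null(out$adj_p) || all(is.na(out$adj_p)))
    out$adj_p <- rep(NA_real_, nrow(out))
  out$adj_p[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out$adj_p[!out$tested] <- NA_real_
  out$significant <- out$tested & !is.na(out$adj_p) &
    out$adj_p < alpha & abs(out$lfc) >= lfc_cut
  out$n_group1 <- n1
  out$n_group2 <- n2
  attr(out, "comparison") <- comparison
  class(out) <- c("de_result", "data.frame")
  out[, c("gene", "lfc", "p", "adj_p", "significant", "tested",
          "n_group1", "n_group2")]
}

#' Normalize counts to log1p of library-size-scaled values
#'
#' Counts are scaled per unit to the median library size and
#' log1p-transformed (natural log), the package's normalization for
#' spot-level tests, marker detection and trajectories.
#'
#' @param counts genes x units raw counts.
#' @return genes x units numeric matrix.
#' @export
normalize_log1p <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  sf <- stats::median(lib) / lib
  log1p(t(t(counts) * sf))
}

#' Two-part (hurdle) differential-expression test
#'
#' Per gene, a logistic regression of detection (`expr > 0`) on the design
#' and a Gaussian linear model of expression among detected units are each
#' compared with their group-free nulls by likelihood-ratio tests; the
#' combined statistic is the sum of the two chi-squares with summed
#' degrees of freedom. A component that is inestimable (all units
#' detected or none; too few detected units for the linear fit)
#' contributes 0 with 0 df, so e.g. a fully detected gene is tested by the
#' continuous component alone. The log2 fold change is the difference of
#' group means of normalized expression divided by log 2, independent of
#' the model fits. BH adjustment across tested genes.
#'
#' @param expr genes x units normalized expression ([normalize_log1p()]).
#' @param meta per-unit metadata.
#' @param design a [design_spec()] (sample id via `random_effect` is
#'   fitted as a fixed covariate).
#' @param genes tested gene list; default all rows.
#' @return a `de_result` data.frame (see [pseudobulk_nb_test()]).
#' @export
hurdle_test <- function(expr, meta, design, genes = rownames(expr)) {
  bm <- build_model_frame(meta, design)
  covs <- bm$covariates
  X1 <- stats::model.matrix(stats::reformulate(c(covs, "group")),
                            data = bm$frame)
  check_full_rank(X1)
  X0 <- X1[, colnames(X1) != paste0("group", levels(bm$group)[2]),
           drop = FALSE]
  grp <- bm$group
  lv <- levels(grp)
  i1 <- grp == lv[1]; i2 <- grp == lv[2]
  ln2 <- log(2)
  res <- matrix(NA_real_, length(genes), 2,
                dimnames = list(genes, c("lfc", "p")))
  for (g in genes) {
    y <- expr[g, ]
    det <- y > 0
    chi <- 0; df <- 0L
    nd <- sum(det)
    if (nd > 0L && nd < length(y)) {
      f1 <- tryCatch(suppressWarnings(
        stats::glm.fit(X1, det, family = stats::binomial())),
        error = function(e) NULL)
      f0 <- tryCatch(suppressWarnings(
        stats::glm.fit(X0, det, family = stats::binomial())),
        error = function(e) NULL)
      if (!is.null(f1) && !is.null(f0)) {
        ddf <- f1$rank - f0$rank
        if (ddf > 0L) {
          chi <- chi + max(f0$deviance - f1$deviance, 0)
          df <- df + ddf
        }
      }
    }
    if (nd > ncol(X1) + 1L) {
      yd <- y[det]
      c1 <- stats::.lm.fit(X1[det, , drop = FALSE], yd)
      c0 <- stats::.lm.fit(X0[det, , drop = FALSE], yd)
      ddf <- c1$rank - c0$rank
      rss1 <- sum(c1$residuals^2); rss0 <- sum(c0$residuals^2)
      if (ddf > 0L && rss1 > 0) {
        chi <- chi + nd * log(rss0 / rss1)
        df <- df + ddf
      }
    }
    p <- if (df > 0L) stats::pchisq(chi, df, lower.tail = FALSE) else NA_real_
    res[g, ] <- c((mean(y[i2]) - mean(y[i1])) / ln2, p)
  }
  out <- data.frame(gene = genes, lfc = res[, "lfc"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  finalize_de(out, n1 = sum(i1), n2 = sum(i2),
              comparison = paste(lv[2], "vs", lv[1], "(hurdle)"))
}

#' Negative-binomial test for protein (ADT-style) counts
#'
#' Per protein, a negative-binomial GLM of isotype-normalized counts on
#' group plus covariates (Wald test on the group coefficient; Poisson
#' fallback when the NB fit does not converge). Non-integer input is
#' rounded with a warning. Proteins detected in under 1% of both groups
#' are untested. Reported fold change is the log2 ratio of group means
#' with a pseudocount of 1; significance requires adjusted p < 0.05 and
#' |lfc| > log2(1.5).
#'
#' @param protein_counts proteins x units matrix of normalized counts.
#' @param meta per-unit metadata.
#' @param design a [design_spec()] (e.g. covariates CDR and region).
#' @param min_pct minimum detection fraction in either group (default
#'   0.01).
#' @return a `de_result` data.frame.
#' @export
protein_nb_test <- function(protein_counts, meta, design, min_pct = 0.01) {
  if (any(protein_counts %% 1 != 0)) {
    warning("non-integer protein counts rounded before NB fitting",
            call. = FALSE)
    protein_counts <- round(protein_counts)
  }
  bm <- build_model_frame(meta, design)
  X <- stats::model.matrix(stats::reformulate(c(bm$covariates, "group")),
                           data = bm$frame)
  check_full_rank(X)
  grp <- bm$group; lv <- levels(grp)
  i1 <- grp == lv[1]; i2 <- grp == lv[2]
  det1 <- rowMeans(protein_counts[, i1, drop = FALSE] > 0)
  det2 <- rowMeans(protein_counts[, i2, drop = FALSE] > 0)
  testable <- det1 >= min_pct | det2 >= min_pct
  coef_name <- paste0("group", lv[2])
  proteins <- rownames(protein_counts)
  lfc <- log2((rowMeans(protein_counts[, i2, drop = FALSE]) + 1) /
              (rowMeans(protein_counts[, i1, drop = FALSE]) + 1))
  p <- rep(NA_real_, length(proteins))
  df_mm <- as.data.frame(X[, -1, drop = FALSE])
  for (k in which(testable)) {
    y <- protein_counts[k, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ ., data = df_mm)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ ., data = df_mm, family = stats::poisson())),
        error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (coef_name %in% rownames(sm)) p[k] <- sm[coef_name, 4]
  }
  out <- data.frame(gene = proteins, lfc = lfc, p = p,
                    stringsAsFactors = FALSE)
  out <- finalize_de(out, n1 = sum(i1), n2 = sum(i2),
                     comparison = paste(lv[2], "vs", lv[1], "(protein NB)"))
  out$significant <- out$tested & !is.na(out$adj_p) & out$adj_p < 0.05 &
    abs(out$lfc) > log2(1.5)
  out
}

#' One-versus-rest marker detection
#'
#' Per cluster, a Wilcoxon rank-sum test of in-cluster vs all other units
#' on genes detected in more than `min_pct` of the cluster (after prefix
#' exclusion); BH adjustment within cluster; positive-LFC markers only
#' when `only_pos`. The amyloid-niche contrast profile used for
#' rich-cluster comparisons is `min_pct = 0.1`, `only_pos = FALSE`,
#' `lfc_floor = log2(1.5)`.
#'
#' @param expr genes x units normalized expression.
#' @param clusters per-unit cluster labels.
#' @param min_pct in-cluster detection fraction a gene must strictly
#'   exceed.
#' @param only_pos keep positive-LFC markers only.
#' @param lfc_floor minimum |lfc| to report.
#' @param prefix_exclude gene-symbol prefixes never tested.
#' @return named list (one data.frame per cluster): `gene`, `lfc`, `p`,
#'   `adj_p`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(expr, clusters, min_pct = 0.25, only_pos = TRUE,
                         lfc_floor = 0.25,
                         prefix_exclude = c("RPS", "RPL", "MT", "HB")) {
  cl <- as.character(clusters)
  ids <- sort(unique(cl))
  if (length(ids) < 2L) stop_invalid("need at least two clusters")
  genes <- rownames(expr)
  for (pfx in prefix_exclude) genes <- genes[!startsWith(genes, pfx)]
  ln2 <- log(2)
  out <- list()
  for (k in ids) {
    inn <- cl == k
    if (sum(inn) < 2L) {
      warning("cluster ", k, " is a singleton; skipped", call. = FALSE)
      next
    }
    pct_in <- rowMeans(expr[genes, inn, drop = FALSE] > 0)
    pct_out <- rowMeans(expr[genes, !inn, drop = FALSE] > 0)
    test_g <- genes[pct_in > min_pct]
    if (!length(test_g)) {
      out[[k]] <- data.frame(gene = character(0), lfc = numeric(0),
                             p = numeric(0), adj_p = numeric(0),
                             pct_in = numeric(0), pct_out = numeric(0))
      next
    }
    lfc <- (rowMeans(expr[test_g, inn, drop = FALSE]) -
            rowMeans(expr[test_g, !inn, drop = FALSE])) / ln2
    p <- vapply(test_g, function(g)
      stats::wilcox.test(expr[g, inn], expr[g, !inn])$p.value, 0)
    tab <- data.frame(gene = test_g, lfc = lfc, p = p,
                      adj_p = stats::p.adjust(p, method = "BH"),
                      pct_in = pct_in[test_g], pct_out = pct_out[test_g],
                      stringsAsFactors = FALSE)
    if (only_pos) tab <- tab[tab$lfc > 0, , drop = FALSE]
    tab <- tab[abs(tab$lfc) > lfc_floor, , drop = FALSE]
    out[[k]] <- tab[order(tab$p), , drop = FALSE]
  }
  out
}
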