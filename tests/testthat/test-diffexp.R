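test_that("balanced downsampling reaches the documented fixed points", {
  # both caps bind at 3,000 = min(3,000, 3 x 1,000)
  u <- make_units(c(a1 = 2000, a2 = 2000, a3 = 2000, a4 = 2000, b1 = 1000),
                  c(a1 = "g1", a2 = "g1", a3 = "g1", a4 = "g1", b1 = "g2"))
  r <- balance_downsample(u, seed = 3)
  expect_equal(sort(as.integer(table(r$group)), decreasing = TRUE),
               c(3000L, 1000L))

  # 900/100 two-sample group iterates to (100, 100)
  u2 <- make_units(c(a = 900, b = 100, c = 500, d = 500),
                   c(a = "g1", b = "g1", c = "g2", d = "g2"))
  r2 <- balance_downsample(u2, seed = 4)
  g1 <- r2[r2$group == "g1", ]
  expect_equal(as.integer(table(g1$sample)), c(100L, 100L))

  # single-sample group: share rule skipped
  u3 <- make_units(c(a = 500, b = 300), c(a = "g1", b = "g2"))
  r3 <- balance_downsample(u3, seed = 5)
  expect_equal(nrow(r3), 800L)

  # deterministic under fixed seed; output is a subset of input
  r4 <- balance_downsample(u2, seed = 4)
  expect_identical(r2, r4)
  expect_true(all(r2$unit %in% u2$unit))

  expect_error(balance_downsample(make_units(c(a = 5), c(a = "g1"))),
               "two groups")
})

test_that("downsampling output always satisfies all three constraints", {
  set.seed(77)
  cons <- downsample_constraints()
  for (i in 1:60) {
    n_s1 <- sample(1:4, 1); n_s2 <- sample(1:4, 1)
    sizes <- c(sample(10:4000, n_s1, replace = TRUE),
               sample(10:4000, n_s2, replace = TRUE))
    names(sizes) <- paste0("s", seq_along(sizes))
    grp <- setNames(rep(c("g1", "g2"), c(n_s1, n_s2)), names(sizes))
    out <- balance_downsample(make_units(sizes, grp), cons, seed = i)
    expect_true(satisfies_downsample(out, cons))
  }
})

test_that("gene filtering applies detection rules and prefix exclusions", {
  counts <- rbind(
    gene_all0 = rep(0L, 200),
    `MT-CO1` = rep(5L, 200),
    MTOR = rep(5L, 200),
    RPS6 = rep(5L, 200),
    lowboth = c(rep(1L, 1), rep(0L, 99), rep(1L, 1), rep(0L, 99)),
    asym = c(rep(1L, 4), rep(0L, 96), rep(1L, 12), rep(0L, 88)),
    weak = c(rep(1L, 2), rep(0L, 98), rep(1L, 8), rep(0L, 92)))
  groups <- rep(c("x", "y"), each = 100)

  expect_false("gene_all0" %in% gene_filter(counts, groups, "pseudobulk"))
  # literal case-sensitive prefixes: MT-CO1, MTOR, RPS6 all excluded
  expect_length(intersect(c("MT-CO1", "MTOR", "RPS6"),
                          gene_filter(counts, groups, "pseudobulk")), 0)
  # hurdle: 1% of both groups AND 10% of either
  hur <- gene_filter(counts, groups, "hurdle")
  expect_true("asym" %in% hur)    # 4% / 12%
  expect_false("weak" %in% hur)   # 2% / 8%
  expect_true("lowboth" %in% gene_filter(counts, groups, "hd"))  # 1% either
  expect_false("lowboth" %in% hur)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  set.seed(41)
  pool <- c(0.001, 0.008, 0.02, 0.049, 0.05, 0.2, 0.5, 0.51, 0.9, 1)
  for (n in 1:8) {
    for (rep in 1:25) {
      p <- sample(pool, n, replace = TRUE)
      expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
    }
  }
})

test_that("pseudobulk NB test recovers planted effects and rejects bad designs", {
  p <- synth_params(n_genes = 400, n_niche_genes = 0, n_group_genes = 30,
                    group_lfc = 2, spots_per_donor = 300)
  co <- simulate_cohort(p, seed = 13)
  des <- design_spec("group", c(sex = "categorical", age = "continuous",
                                gdna_pct = "continuous"))
  genes <- gene_filter(co$counts, co$meta$group, "pseudobulk")
  de <- pseudobulk_nb_test(co$counts, co$meta$sample_id, co$meta, des,
                           genes = genes)
  gg <- co$truth_genes$group_genes$gene
  expect_gt(mean(de$significant[de$gene %in% gg]), 0.9)
  # direction: planted-up genes estimated positive
  up <- co$truth_genes$group_genes$gene[co$truth_genes$group_genes$lfc > 0]
  expect_true(all(de$lfc[match(up, de$gene)] > 0))
  expect_true(all(de$adj_p >= de$p - 1e-12, na.rm = TRUE))
  expect_true(all(de$tested))

  # collinear design is rejected with the aliased term named
  meta_bad <- co$meta
  meta_bad$age2 <- meta_bad$age
  des_bad <- design_spec("group", c(age = "continuous", age2 = "continuous"))
  expect_error(
    pseudobulk_nb_test(co$counts[genes[1:10], ], co$meta$sample_id, meta_bad,
                       des_bad, genes = genes[1:10]),
    "collinear")

  # fewer than 2 donors in a group is an error
  one <- co$meta$sample_id %in% c("D01", "D07")
  expect_error(
    pseudobulk_nb_test(co$counts[genes[1:10], one],
                       co$meta$sample_id[one], co$meta[one, ], des,
                       genes = genes[1:10]),
    "2 donors")
})

test_that("a gene identical across donors shows no effect", {
  # equal counts, balanced library sizes: lfc ~ 0, p ~ 1
  donors <- rep(sprintf("D%d", 1:6), each = 10)
  counts <- matrix(50L, 5, 60,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:60)))
  set.seed(2)
  counts[2:5, ] <- matrix(rnbinom(4 * 60, mu = 30, size = 5), 4, 60)
  meta <- data.frame(sample_id = donors,
                     group = rep(c("a", "b"), each = 30))
  # suppress DESeq2's small-fixture dispersion-fit note (5 genes only)
  de <- suppressWarnings(
    pseudobulk_nb_test(counts, donors, meta, design_spec("group")))
  # small residual lfc from median-of-ratios size factors over the noisy genes
  expect_lt(abs(de$lfc[de$gene == "g1"]), 0.1)
  expect_gt(de$p[de$gene == "g1"], 0.3)
})

test_that("pseudobulk NB approaches the Poisson GLM in the low-dispersion limit", {
  set.seed(19)
  n_donor <- 12
  donors <- paste0("D", 1:n_donor)
  grp <- rep(c("a", "b"), each = n_donor / 2)
  lib <- rlnorm(n_donor, log(5e4), 0.2)
  G <- 150
  base <- rlnorm(G, log(1e-3), 0.8)
  mu <- base %o% lib
  counts <- matrix(rpois(length(mu), mu), G, n_donor,
                   dimnames = list(paste0("g", 1:G), donors))
  meta <- data.frame(sample_id = donors, group = grp)
  de <- pseudobulk_nb_test(counts, donors, meta, design_spec("group"))

  # Poisson GLM oracle with the same median-of-ratios size factors
  logsf <- log(DESeq2::estimateSizeFactorsForMatrix(counts))
  x <- as.integer(grp == "b")
  oracle <- t(vapply(seq_len(G), function(i) {
    f <- glm(counts[i, ] ~ x + offset(logsf), family = poisson())
    s <- summary(f)$coefficients
    c(lfc = s["x", 1] / log(2), p = s["x", 4])
  }, c(lfc = 0, p = 0)))
  expect_lt(median(abs(de$lfc - oracle[, "lfc"])), 0.02)
  expect_gt(cor(qnorm(pmax(de$p, 1e-12) / 2), qnorm(pmax(oracle[, "p"], 1e-12) / 2)), 0.98)
})

test_that("hurdle test combines discrete and continuous evidence correctly", {
  set.seed(23)
  n <- 400
  grp <- rep(c("a", "b"), each = n / 2)
  meta <- data.frame(group = grp)
  des <- design_spec("group")

  # fully detected gene: combined test equals the continuous LRT alone
  y <- rnorm(n, 5, 1)
  expr <- matrix(y, 1, n, dimnames = list("g1", NULL))
  h <- hurdle_test(expr, meta, des)
  rss1 <- sum(.lm.fit(cbind(1, grp == "b"), y)$residuals^2)
  rss0 <- sum(.lm.fit(cbind(rep(1, n)), y)$residuals^2)
  p_cont <- pchisq(n * log(rss0 / rss1), 1, lower.tail = FALSE)
  expect_equal(h$p, p_cont, tolerance = 1e-12)

  # detection difference with equal positive means: discrete part drives it
  det <- c(runif(n / 2) < 0.8, runif(n / 2) < 0.2)
  y2 <- ifelse(det, rnorm(n, 5, 0.5), 0)
  h2 <- hurdle_test(matrix(y2, 1, n, dimnames = list("g2", NULL)), meta, des)
  expect_lt(h2$p, 1e-6)

  # gene never detected: untested (no estimable component)
  h3 <- hurdle_test(matrix(0, 1, n, dimnames = list("g3", NULL)), meta, des)
  expect_false(h3$tested)

  # lfc is the log2-scaled difference of group means, model-independent
  expect_equal(h$lfc, (mean(y[grp == "b"]) - mean(y[grp == "a"])) / log(2))
})

test_that("protein NB test flags planted effects and skips absent proteins", {
  set.seed(29)
  n <- 600
  grp <- rep(c("ctrl", "trt"), each = n / 2)
  cdr <- runif(n, 0.2, 0.8)
  meta <- data.frame(group = grp, cdr = cdr)
  prot <- rbind(
    absent = rep(0, n),
    null1 = rnbinom(n, mu = 20, size = 3),
    planted = c(rnbinom(n / 2, mu = 10, size = 3),
                rnbinom(n / 2, mu = 30, size = 3)))
  des <- design_spec("group", c(cdr = "continuous"))
  expect_warning(res <- protein_nb_test(prot + 0.4, meta, des), "rounded")
  res <- suppressWarnings(protein_nb_test(prot, meta, des))
  expect_false(res$tested[res$gene == "absent"])
  expect_true(res$significant[res$gene == "planted"])
  expect_false(isTRUE(res$significant[res$gene == "null1"]))
  expect_gt(res$lfc[res$gene == "planted"], log2(1.5))
})

test_that("marker detection is one-versus-rest with detection gating", {
  set.seed(37)
  n <- 300
  cl <- rep(c("A", "B", "C"), each = n / 3)
  G <- 30
  expr <- matrix(rexp(G * n, 2), G, n,
                 dimnames = list(paste0("g", 1:G), NULL))
  # marker: expressed only in cluster A at 60% detection
  expr["g1", ] <- ifelse(cl == "A" & runif(n) < 0.6, rexp(n, 0.5), 0)
  # gating: only 10% detection in every cluster
  expr["g2", ] <- ifelse(runif(n) < 0.1, 5, 0)
  mk <- find_markers(expr, cl, min_pct = 0.25)
  expect_equal(mk$A$gene[1], "g1")
  expect_false("g2" %in% mk$A$gene)
  # prefix exclusion applies
  rownames(expr)[3] <- "RPS4"
  mk2 <- find_markers(expr, cl)
  expect_false(any(vapply(mk2, function(t) "RPS4" %in% t$gene, TRUE)))

  # two identical clusters: no significant markers
  expr0 <- matrix(rexp(G * 200, 1), G, 200,
                  dimnames = list(paste0("g", 1:G), NULL))
  mk0 <- find_markers(expr0, rep(c("A", "B"), each = 100), min_pct = 0,
                      only_pos = FALSE, lfc_floor = 0)
  expect_equal(sum(unlist(lapply(mk0, function(t) t$adj_p < 0.05))), 0)

  expect_error(find_markers(expr, rep("A", n)), "two clusters")
})
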