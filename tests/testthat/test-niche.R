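test_that("spot signal averages the density raster over the capture disc", {
  g <- make_spot_grid(3, 3, 100, 55)
  zero <- density_raster(matrix(0L, 150, 150), 2)
  full <- density_raster(matrix(255L, 150, 150), 2)
  expect_equal(unname(spot_signal(zero, g)), rep(0, 9))
  expect_equal(unname(spot_signal(full, g)), rep(255, 9))

  # half-covered spot: vertical edge through the spot center
  px <- matrix(0L, 300, 300)
  px[, 1:150] <- 255L
  half <- density_raster(px, 1)
  g1 <- make_spot_grid(1, 1, 100, 55)
  g1$x <- 150; g1$y <- 150
  v <- spot_signal(half, g1)
  expect_lt(abs(v - 127.5), 3)  # +/- 1 px quantization on the disc edge

  # unreliable spots get NA
  g$reliable_ab[5] <- FALSE
  s <- spot_signal(zero, g)
  expect_true(is.na(s[5]))
  # disc fully outside the raster warns and yields NA
  g2 <- make_spot_grid(1, 1, 100, 55)
  g2$x <- 5000; g2$y <- 5000
  expect_warning(s2 <- spot_signal(zero, g2), "outside")
  expect_true(is.na(s2))
})

test_that("richness calls are strictly above the threshold", {
  expect_true(classify_rich(184))
  expect_false(classify_rich(183))
  expect_false(classify_rich(0))
  expect_false(classify_rich(NA_real_))
  expect_error(classify_rich(100, threshold = 300), "0, 255")
})

test_that("hex neighbors agree with the Euclidean oracle", {
  g <- make_spot_grid(20, 20, 100, 55)
  center <- g$spot_id[g$array_row == 10 & g$array_col == 10]
  n1 <- hex_neighbors(g, center, 1)
  n2 <- hex_neighbors(g, center, 2)
  expect_length(n1, 6)
  expect_length(n2, 12)
  i <- match(center, g$spot_id)
  d1 <- sqrt((g$x[match(n1, g$spot_id)] - g$x[i])^2 +
             (g$y[match(n1, g$spot_id)] - g$y[i])^2)
  expect_equal(d1, rep(100, 6), tolerance = 1e-9)
  d2 <- sort(unique(round(sqrt((g$x[match(n2, g$spot_id)] - g$x[i])^2 +
                               (g$y[match(n2, g$spot_id)] - g$y[i])^2), 6)))
  expect_equal(d2, round(c(sqrt(3) * 100, 200), 6))

  # random interior spots against the brute-force oracle
  set.seed(5)
  interior <- g$spot_id[g$array_row %in% 3:16 & g$array_col %in% 3:16]
  for (s in sample(interior, 25)) {
    expect_setequal(hex_neighbors(g, s, 1), euclid_neighbors(g, s, 1, 100))
    expect_setequal(hex_neighbors(g, s, 2), euclid_neighbors(g, s, 2, 100))
  }

  # corner of a 2x2 grid has at most 3 first-order neighbors
  g4 <- make_spot_grid(2, 2, 100, 55)
  expect_lte(length(hex_neighbors(g4, g4$spot_id[1], 1)), 3)
  expect_error(hex_neighbors(g, "nope", 1), "unknown")
})

test_that("niche assembly yields the 19-spot hex ball and partitions spots", {
  g <- make_spot_grid(64, 64, 100, 55)
  center <- g$spot_id[g$array_row == 30 & g$array_col == 30]
  ann <- assemble_niche(g, rich = center,
                        allowed_regions = unique(g$region))
  niche <- ann$spot_id[ann$niche_class %in% c("rich", "neighbor")]
  expect_length(niche, 19)
  # every niche spot is within 200 um of the rich spot at 100 um pitch
  i <- match(center, g$spot_id); j <- match(niche, g$spot_id)
  dmax <- max(sqrt((g$x[j] - g$x[i])^2 + (g$y[j] - g$y[i])^2))
  expect_equal(dmax, 200, tolerance = 1e-9)

  # classes partition the grid
  expect_equal(sum(table(ann$niche_class)), nrow(g))
  expect_setequal(unique(ann$niche_class), c("rich", "neighbor", "outside"))

  # no rich spots: everything outside
  ann0 <- assemble_niche(g, rich = character(0))
  expect_true(all(ann0$niche_class == "outside"))
})

test_that("vascular spots and their immediate neighbors are excluded", {
  g <- make_spot_grid(30, 30, 100, 55)
  center <- g$spot_id[g$array_row == 15 & g$array_col == 15]
  vasc <- hex_neighbors(g, center, 1)[1]
  ann <- assemble_niche(g, rich = center, vascular = vasc,
                        allowed_regions = unique(g$region))
  excluded <- ann$spot_id[ann$niche_class == "excluded"]
  expect_true(vasc %in% excluded)
  expect_true(all(hex_neighbors(g, vasc, 1) %in% excluded))
  # the rich spot itself is adjacent to the vascular spot -> excluded
  expect_equal(ann$niche_class[match(center, ann$spot_id)], "excluded")

  # a vascular spot two steps away leaves the rich spot in the niche
  far_vasc <- g$spot_id[g$array_row == 15 & g$array_col == 20]
  ann2 <- assemble_niche(g, rich = center, vascular = far_vasc,
                         allowed_regions = unique(g$region))
  expect_equal(ann2$niche_class[match(center, ann2$spot_id)], "rich")

  # idempotence: re-assembling from the output classes changes nothing
  rich2 <- ann2$spot_id[ann2$niche_class == "rich"]
  ann3 <- assemble_niche(g, rich = rich2, vascular = far_vasc,
                         allowed_regions = unique(g$region))
  expect_identical(ann2$niche_class, ann3$niche_class)

  # unreliable spots are excluded, never rich
  g$reliable_ab[match(center, g$spot_id)] <- FALSE
  ann4 <- assemble_niche(g, rich = center, allowed_regions = unique(g$region))
  expect_equal(ann4$niche_class[match(center, ann4$spot_id)], "excluded")
})

test_that("neighbor membership respects allowed regions", {
  g <- make_spot_grid(10, 10, 100, 55,
                      region_layout = c("layer III", "meninges"))
  # rich spot near the region boundary: meningeal spots never join the niche
  center <- g$spot_id[g$array_row == 4 & g$array_col == 5]
  ann <- assemble_niche(g, rich = center,
                        allowed_regions = GM_REGIONS)
  niche <- ann$spot_id[ann$niche_class %in% c("rich", "neighbor")]
  expect_true(all(g$region[match(niche, g$spot_id)] == "layer III"))
})

test_that("enriched-spot calling honors quantile and z-score rules per region", {
  g <- make_spot_grid(10, 10, 100, 55)
  g$region <- "layer III"
  set.seed(9)
  ab <- data.frame(spot_id = g$spot_id, microglia = sample(1:100),
                   stringsAsFactors = FALSE)

  rule <- enrichment_rule("microglia", "layer III", "top_quantile", q = 0.05)
  sel <- enriched_spots(ab, g, rule)
  expect_setequal(sel, ab$spot_id[order(-ab$microglia)][1:5])

  rule_all <- enrichment_rule("microglia", "layer III", "top_quantile", q = 1)
  expect_setequal(enriched_spots(ab, g, rule_all), g$spot_id)

  # constant abundances with the z-rule select nothing (sd = 0 convention)
  ab2 <- ab; ab2$microglia <- 5
  rz <- enrichment_rule("microglia", "layer III", "z_score", z = 3)
  expect_length(enriched_spots(ab2, g, rz), 0)

  # ties at the quantile boundary are all included
  ab3 <- ab; ab3$microglia <- rep(c(1, 9), c(90, 10))
  r10 <- enrichment_rule("microglia", "layer III", "top_quantile", q = 0.05)
  expect_length(enriched_spots(ab3, g, r10), 10)

  # per-sample evaluation: selections made within each sample separately
  g2 <- g; g2$sample_id <- rep(c("A", "B"), each = 50)
  g2$spot_id <- paste0(g2$sample_id, "_", seq_len(100))
  ab4 <- data.frame(spot_id = g2$spot_id,
                    microglia = c(1:50, 1001:1050))
  sel2 <- enriched_spots(ab4, g2, rule)
  expect_length(sel2, 6)  # top 5% of 50 = ceiling to 3 per sample
  expect_equal(sum(startsWith(sel2, "A")), 3)

  # absent region contributes nothing (message, not error)
  rule_wm <- enrichment_rule("microglia", "white matter", "top_quantile")
  expect_message(out <- enriched_spots(ab, g, rule_wm), "absent")
  expect_length(out, 0)
})

test_that("nuclei proximity analysis bins at the strict 20 um cutoff", {
  px <- matrix(0L, 100, 100)
  px[40:60, 40:60] <- 1L  # plaque block, 1 um/px
  m <- mask_raster(px, 1)

  # distances are between pixel centers: the rightmost plaque center column
  # is 59.5, so nuclei in pixel columns 79 / 80 sit at 19 / 20 um exactly
  nuc <- data.frame(
    x = c(50, 50, 78.2, 79.2, 5, 5),
    y = c(50, 50, 50, 50, 5, 95),
    cell_type = c("myeloid", "myeloid", "myeloid", "neuron", "neuron",
                  "neuron"))
  res <- nuclei_near_plaques(nuc, m, cutoff = 20)
  tab <- res$table
  # inside -> 0; 19 um -> near; exactly 20 um -> far (strict cutoff)
  expect_equal(res$distances[1], 0)
  expect_equal(res$distances[3], 19)
  expect_equal(res$distances[4], 20)
  expect_equal(tab$n_near[tab$cell_type == "myeloid"], 3L)
  expect_equal(tab$n_far[tab$cell_type == "myeloid"], 0L)
  expect_equal(tab$frac_near[tab$cell_type == "myeloid"], 1.0)

  # empty mask: all distances infinite, near bin empty, ratio missing
  res0 <- nuclei_near_plaques(nuc, mask_raster(matrix(0L, 100, 100), 1))
  expect_true(all(is.infinite(res0$distances)))
  expect_true(all(is.na(res0$table$frac_near)))

  # uniform nuclei: near-bin composition matches overall composition
  set.seed(17)
  nuc2 <- data.frame(x = runif(10000, 0, 100), y = runif(10000, 0, 100),
                     cell_type = sample(c("a", "b"), 10000, TRUE))
  r2 <- nuclei_near_plaques(nuc2, m, cutoff = 20)
  expect_gt(r2$p_value, 0.01)
  expect_lt(abs(r2$table$frac_near[1] - 0.5), 0.05)
})

test_that("default enrichment rule table covers the documented cell types", {
  rules <- default_enrichment_rules()
  expect_true(all(vapply(rules, inherits, TRUE, "enrichment_rule")))
  expect_equal(rules$microglia$q, 0.05)
  expect_equal(rules$oligodendrocytes$allowed_regions, "white matter")
  expect_equal(rules$microglia_cluster$mode, "z_score")
  expect_equal(rules$microglia_cluster$z, 3)
  # layer I excluded from atlas rules
  expect_false("layer I" %in% rules$microglia$allowed_regions)
})
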