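#!/usr/bin/env Rscript
# Simulate the synthetic immunization cohort used throughout the analysis:
# 6 control + 6 immunized donors, 2,000 spots each, a 2,000-gene panel with
# 50 plaque-niche-responsive genes (peak LFC 2, 50 um decay) and 100
# group-responsive genes (|LFC| 1.5), plus per-donor plaque fields.
# Everything downstream regenerates this cohort deterministically from
# SEED, so the scripts are independently runnable; only small summary
# tables are written here.

library(plaqniche)

SEED <- 20260923L
dir.create("results", showWarnings = FALSE)

params <- synth_params()
cohort <- simulate_cohort(params, seed = SEED)

cat("cohort:", nrow(cohort$meta), "spots,", nrow(cohort$counts), "genes,",
    length(unique(cohort$meta$sample_id)), "donors\n")

donor_summary <- do.call(rbind, lapply(names(cohort$truths), function(d) {
  tr <- cohort$truths[[d]]
  idx <- cohort$meta$sample_id == d
  data.frame(
    donor = d,
    group = unique(cohort$meta$group[idx]),
    n_spots = sum(idx),
    n_plaques = nrow(tr$plaques),
    n_vascular = sum(tr$plaques$class == "vascular"),
    median_radius_um = round(stats::median(tr$plaques$radius), 1),
    mean_libsize = round(mean(colSums(cohort$counts[, idx]))),
    frac_spots_on_plaque = round(mean(cohort$meta$dist_to_plaque[idx] == 0), 3))
}))
write_tsv_table(donor_summary, "results/01_donor_summary.tsv")
print(donor_summary, row.names = FALSE)

# Rasterize one donor's field and quantify amyloid coverage and
# microglial colocalization in its gray matter
donor1 <- cohort$grid[cohort$grid$sample_id == "D01", ]
ras <- make_tissue_raster(donor1, params, seed = SEED + 1L)
region_all <- mask_raster(matrix(1L, nrow(ras$ab_mask$pixels),
                                 ncol(ras$ab_mask$pixels)),
                          ras$ab_mask$pixel_size)
parts <- partition_vascular(ras$ab_mask, ras$vascular_labels)
imaging <- data.frame(
  donor = "D01",
  ab_coverage = area_coverage(ras$ab_mask, region_all),
  cortical_ab_coverage = area_coverage(parts$cortical, region_all),
  iba1_on_cortical_ab = colocalization_fraction(ras$iba1_mask,
                                                parts$cortical, region_all))
write_tsv_table(imaging, "results/01_imaging_quantification.tsv")
cat(sprintf("D01 amyloid coverage %.2f%%; IBA1 on cortical amyloid %.1f%%\n",
            100 * imaging$ab_coverage, 100 * imaging$iba1_on_cortical_ab))

write_tsv_table(cohort$truth_genes$group_genes, "results/01_planted_group_genes.tsv")
write_tsv_table(cohort$truth_genes$niche_genes, "results/01_planted_niche_genes.tsv")
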