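#!/usr/bin/env Rscript
# Covariate-adjusted differential expression on the simulated cohort via
# both routes: donor-level pseudobulk negative binomial (immunized vs
# control) and spot-level hurdle tests after balanced downsampling.
# Reports recovery of the planted group program.

library(plaqniche)

SEED <- 20260923L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(synth_params(), seed = SEED)
counts <- cohort$counts
meta <- cohort$meta
planted <- cohort$truth_genes$group_genes$gene

des_pb <- design_spec("group", c(sex = "categorical", age = "continuous",
                                 gdna_pct = "continuous"))
genes_pb <- gene_filter(counts, meta$group, "pseudobulk")
de_pb <- pseudobulk_nb_test(counts, meta$sample_id, meta, des_pb,
                            genes = genes_pb)
sig_pb <- de_pb$gene[de_pb$significant]
cat(sprintf("pseudobulk NB: %d genes tested, %d significant (adj p < 0.05, |LFC| >= log2 1.5)\n",
            sum(de_pb$tested), length(sig_pb)))
cat(sprintf("  planted group genes recovered: %d/%d (%.0f%%); false discoveries: %d\n",
            sum(planted %in% sig_pb), length(planted),
            100 * mean(planted %in% sig_pb),
            sum(!sig_pb %in% c(planted, cohort$truth_genes$niche_genes$gene))))

# spot-level hurdle route after balanced downsampling
units <- data.frame(unit = meta$spot_id, sample = meta$sample_id,
                    group = meta$group)
kept <- balance_downsample(units, downsample_constraints(), seed = SEED)
cat(sprintf("downsampled to %s spots per group\n",
            paste(table(kept$group), collapse = " / ")))
sub <- kept$unit
meta_sub <- meta[match(sub, meta$spot_id), ]
expr <- normalize_log1p(counts[, sub])
genes_h <- gene_filter(counts[, sub], meta_sub$group, "hurdle")
des_h <- design_spec("group", c(sex = "categorical", age = "continuous",
                                gdna_pct = "continuous", cdr = "continuous"))
de_h <- hurdle_test(expr, meta_sub, des_h, genes = genes_h)
sig_h <- de_h$gene[de_h$significant]
cat(sprintf("hurdle: %d genes tested, %d significant; planted recovery %.0f%%\n",
            sum(de_h$tested), length(sig_h), 100 * mean(planted %in% sig_h)))

ord_pb <- de_pb[order(de_pb$adj_p), ]
ord_h <- de_h[order(de_h$adj_p), ]
write_tsv_table(utils::head(ord_pb, 100), "results/03_pseudobulk_top100.tsv")
write_tsv_table(utils::head(ord_h, 100), "results/03_hurdle_top100.tsv")
summary_tab <- data.frame(
  route = c("pseudobulk_nb", "hurdle"),
  n_tested = c(sum(de_pb$tested), sum(de_h$tested)),
  n_significant = c(length(sig_pb), length(sig_h)),
  planted_recovered = c(sum(planted %in% sig_pb), sum(planted %in% sig_h)),
  planted_total = length(planted))
write_tsv_table(summary_tab, "results/03_de_summary.tsv")
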