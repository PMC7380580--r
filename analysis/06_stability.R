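#!/usr/bin/env Rscript
# Longitudinal stability: correlate the selected log ratio between
# consecutive weekly time points within subjects, pooled and per group,
# for both the microbial and the metabolite table.
#
# Reads:  results/microbes_rarefied.tsv, results/metabolites.tsv,
#         results/metadata_filtered.tsv, results/selected_sets.tsv
# Writes: results/stability_pairs.tsv, results/stability_stats.tsv

library(fermentomics)

table <- read_count_table("results/microbes_rarefied.tsv")
metab <- read_count_table("results/metabolites.tsv")
meta <- read_sample_metadata("results/metadata_filtered.tsv")
pair <- read_feature_sets("results/selected_sets.tsv")
groups <- stats::setNames(meta$consumption_label, meta$SampleID)

mic_series <- compute_log_ratio(table, pair, groups = groups)
mic_pairs <- consecutive_pairs(mic_series, meta)
mic_all <- stability_correlation(mic_pairs)
mic_grp <- stability_correlation(mic_pairs, by = "group")

# metabolite stability: ratio of the upper to lower half of metabolites
# ranked by their group differential is a simple analogous statistic; use
# the planted CLA-like metabolite against the remaining panel
metab <- metab[intersect(rownames(metab), meta$SampleID), ]
met_pair <- feature_set_pair("CLA_like",
                             setdiff(colnames(metab), "CLA_like"))
met_series <- compute_log_ratio(metab, met_pair,
                                groups = groups[rownames(metab)])
met_pairs <- consecutive_pairs(met_series, meta)
met_all <- stability_correlation(met_pairs)

mic_all$table <- "microbes"; mic_grp$table <- "microbes"
met_all$table <- "metabolites"
out <- rbind(mic_all, mic_grp, met_all)
utils::write.table(out, "results/stability_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
mic_pairs$table <- "microbes"; met_pairs$table <- "metabolites"
utils::write.table(rbind(mic_pairs, met_pairs),
                   "results/stability_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("microbial log ratio: %d pairs, Spearman rho = %.3f (p = %.3g), slope = %.2f\n",
            mic_all$n_pairs, mic_all$spearman_rho, mic_all$p,
            mic_all$ols_slope))
for (i in seq_len(nrow(mic_grp))) {
  cat(sprintf("  %s: rho = %.3f (n = %d)\n", mic_grp$group[i],
              mic_grp$spearman_rho[i], mic_grp$n_pairs[i]))
}
cat(sprintf("metabolite log ratio: %d pairs, Spearman rho = %.3f (p = %.3g)\n",
            met_all$n_pairs, met_all$spearman_rho, met_all$p))
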