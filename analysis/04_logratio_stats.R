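#!/usr/bin/env Rscript
# Compare consumers and nonconsumers on the selected feature-set log
# ratio (Welch t, Cohen's D), on the planted CLA-like metabolite
# (rank-sum), and on a ratio-by-group contingency table (chi-square).
#
# Reads:  results/microbes_rarefied.tsv, results/metabolites.tsv,
#         results/metadata_filtered.tsv, results/selected_sets.tsv
# Writes: results/logratio_series.tsv, results/group_stats.tsv

library(fermentomics)

table <- read_count_table("results/microbes_rarefied.tsv")
meta <- read_sample_metadata("results/metadata_filtered.tsv")
pair <- read_feature_sets("results/selected_sets.tsv")
groups <- stats::setNames(meta$consumption_label, meta$SampleID)

series <- compute_log_ratio(table, pair, groups = groups)
utils::write.table(
  data.frame(SampleID = names(series$values), log_ratio = series$values,
             group = as.character(series$group)),
  "results/logratio_series.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

wt <- welch_t(series)
cat(sprintf("log ratio (top 20 / bottom 20): t = %.4f, df = %.2f, p = %.3g, Cohen's D = %.4f\n",
            wt$t, wt$df, wt$p, wt$cohens_d))

metab <- read_count_table("results/metabolites.tsv")
metab <- metab[intersect(rownames(metab), meta$SampleID), ]
g <- groups[rownames(metab)]
cla <- metab[, "CLA_like"]
rs <- rank_sum(cla[g == "consumer"], cla[g == "nonconsumer"])
cat(sprintf("CLA-like metabolite, consumer vs nonconsumer rank-sum: U = %.0f, p = %.3g\n",
            rs$statistic, rs$p))

hi <- series$values > stats::median(series$values)
tab2 <- table(ifelse(hi, "high_ratio", "low_ratio"),
              as.character(series$group))
cs <- chi_square(as.matrix(tab2))
cat(sprintf("high/low ratio x group chi-square = %.2f, df = %d, p = %.3g\n",
            cs$chi2, cs$df, cs$p))

stats_out <- data.frame(
  statistic = c("welch_t", "welch_df", "welch_p", "cohens_d",
                "cla_rank_sum_U", "cla_rank_sum_p", "chi2", "chi2_p"),
  value = c(wt$t, wt$df, wt$p, wt$cohens_d, rs$statistic, rs$p,
            cs$chi2, cs$p))
utils::write.table(stats_out, "results/group_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
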