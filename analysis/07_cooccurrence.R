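#!/usr/bin/env Rscript
# Microbe-metabolite integration: fit the conditional-probability
# factorization, export the biplot ordination, rank microbes cooccurring
# with the CLA-like metabolite, and correlate biplot axis 1 with the
# consumption differentials.
#
# Reads:  results/microbes_rarefied.tsv, results/metabolites.tsv,
#         results/differentials.tsv
# Writes: results/conditionals.tsv, results/ordination.txt,
#         results/cla_cooccurrence.tsv, results/axis1_vs_differentials.tsv

library(fermentomics)

table <- read_count_table("results/microbes_rarefied.tsv")
metab <- read_count_table("results/metabolites.tsv")

model <- fit_cooccurrence(table, metab, d = 2, epochs = 2000,
                          learning_rate = 0.05, seed = 1)
utils::write.table(
  data.frame(featureid = rownames(model$conditional), model$conditional,
             check.names = FALSE),
  "results/conditionals.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

bp <- cooccurrence_biplot(model, n_axes = 2, orient_by = "CLA_like")
write_ordination(bp, "results/ordination.txt")
cat(sprintf("biplot: axis variance proportions %s\n",
            paste(sprintf("%.3f", bp$proportion_explained), collapse = ", ")))

top <- rank_cooccurring_microbes(model, "CLA_like", top_n = 50)
diffs <- utils::read.delim("results/differentials.tsv")
top$consumer_differential <-
  diffs$consumer[match(top$feature, diffs$featureid)]
utils::write.table(top, "results/cla_cooccurrence.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("of the top 50 CLA-like cooccurring microbes, %d have a positive consumer differential\n",
            sum(top$consumer_differential > 0)))

ranks <- structure(list(differentials = cbind(
  consumer = stats::setNames(diffs$consumer, diffs$featureid))),
  class = "differential_ranks")
rownames(ranks$differentials) <- diffs$featureid
ax <- axis_vs_differentials(bp, ranks, "consumer")
utils::write.table(
  data.frame(pearson_r = ax$r, p = ax$p, n = ax$n),
  "results/axis1_vs_differentials.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("axis 1 vs consumption differentials: Pearson r = %.3f (p = %.3g, n = %d)\n",
            ax$r, ax$p, ax$n))
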