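#!/usr/bin/env Rscript
# Apply the study's filtering rules to the generated cohort: participant
# demographic bounds, consumption labeling, replicate deduplication, the
# 1,500-read sample cutoff, the 5-read feature-total rule, and rarefaction
# to 1,500 reads/sample.
#
# Reads:  results/microbes.tsv, results/metadata.tsv
# Writes: results/microbes_rarefied.tsv, results/metadata_filtered.tsv

library(fermentomics)

table <- read_count_table("results/microbes.tsv")
meta <- read_sample_metadata("results/metadata.tsv")

crit <- filter_criteria(min_reads = 1500, rarefaction_depth = 1500,
                        min_feature_total = 5)

meta <- filter_participants(meta, crit)
audit <- attr(meta, "audit")
meta <- classify_consumption(meta)
meta <- meta[meta$consumption_label != "unknown", ]
meta <- dedup_replicates(meta)

table <- table[intersect(rownames(table), meta$SampleID), , drop = FALSE]
table <- filter_table(table, crit)
table <- rarefy(table, depth = crit$rarefaction_depth, seed = 1)
meta <- meta[meta$SampleID %in% rownames(table), ]

write_count_table(table, "results/microbes_rarefied.tsv")
write_sample_metadata(meta, "results/metadata_filtered.tsv")

cat("participant exclusions by rule:\n")
print(audit, row.names = FALSE)
cat(sprintf("retained %d samples x %d features at depth %d\n",
            nrow(table), ncol(table), crit$rarefaction_depth))
cat(sprintf("consumers: %d samples, nonconsumers: %d samples\n",
            sum(meta$consumption_label == "consumer"),
            sum(meta$consumption_label == "nonconsumer")))
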