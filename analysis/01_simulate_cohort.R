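#!/usr/bin/env Rscript
# Generate the synthetic study: a two-group fermented-food cohort with the
# longitudinal design (115 subjects split over two groups, up to 4 weekly
# time points), a metagenome-like feature pool, and a paired metabolite
# table with one planted CLA-like consumer-enriched metabolite.
#
# Writes: results/microbes.tsv, results/metabolites.tsv,
#         results/metadata.tsv, results/truth_differentials.tsv

library(fermentomics)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(
  n_subjects_per_group = 57,   # ~115 subjects total
  n_timepoints = 4,            # weekly samples over 4 weeks
  n_microbes = 153,            # metagenome-like feature pool
  n_metabolites = 60,
  n_latent = 1,
  effect_scale = 1,
  seed = 1
)
sim <- simulate_cohort(cfg)
met <- simulate_metabolites(sim)

write_count_table(sim$counts, "results/microbes.tsv")
write_count_table(met$counts, "results/metabolites.tsv")
write_sample_metadata(sim$metadata, "results/metadata.tsv")
utils::write.table(
  data.frame(featureid = names(sim$truth$beta_true),
             beta_true = sim$truth$beta_true),
  "results/truth_differentials.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d samples x %d microbes; %d metabolites; enriched: %s\n",
            nrow(sim$counts), ncol(sim$counts), ncol(met$counts),
            met$enriched_metabolite_id))
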