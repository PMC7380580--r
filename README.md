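# fermentomics

Compositional multi-omics analysis of fermented-food cohorts: a tested
re-implementation of the workflow used to compare the gut microbiomes of
fermented-food consumers and nonconsumers, exercised end-to-end on
synthetic cohorts with planted ground truth.

Sequencing counts are compositional — they say nothing about total
microbial load — so every stage of this pipeline works with quantities
that are invariant to per-sample totals:

* **Cohort and table filtering**: the study's participant rules (age
  strictly between 19 and 70, BMI/height/weight outlier bounds,
  antibiotic exclusion, replicate deduplication by read count), the
  1,500-read sample cutoff, feature-total and relative-abundance
  filters, exclusion lists, and seeded rarefaction.
* **Differential ranking**: a regularized multinomial log-linear
  regression, `counts_i ~ Multinomial(n_i, softmax(X_i B))` with a
  normal prior on `B`, fitted by Adam in ALR coordinates and reported as
  CLR differentials (each covariate's differentials sum to zero; only
  their ordering is identified). A predictive score
  `Q² = 1 − MAE(model)/MAE(baseline)` compares it to an intercept-only
  baseline on held-out samples.
* **Feature-set log ratios**: `ln(Σ numerator / Σ denominator)` per
  sample for the top-k vs bottom-k ranked features, compared between
  groups with Welch's t, pooled-SD Cohen's D, rank-sum, and chi-square
  tests.
* **Permutation null**: the selected log ratio is validated against
  1,000 random nonoverlapping feature selections; the add-one p-value
  `rank/(B+1)` is displayed truncated to 4 decimals (rank 16 → 0.0159,
  rank 2 → 0.0019).
* **Longitudinal stability**: Spearman correlation of log ratios between
  consecutive weekly time points within subjects, pooled and per group.
* **Microbe–metabolite cooccurrence**: a low-rank factorization of the
  conditional probability `P(metabolite | microbe read) =
  softmax(U_i·V + bias)`, with SVD biplots, ranked cooccurrence lists,
  and the correlation of biplot axis 1 with the differentials.

A synthetic-data module generates two-group longitudinal cohorts with
multinomial counts, lognormal library sizes, AR(1) subject stability,
shared microbe–metabolite latent factors, and one planted "CLA-like"
metabolite enriched in consumers — so every stage is testable without
access to any real cohort.

## Worked example

The `analysis/` directory holds the numbered pipeline; each script reads
the previous script's outputs from `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # 456 samples x 153 microbes + 60 metabolites
Rscript analysis/02_filter_cohort.R      # filters + rarefaction to 1,500
Rscript analysis/03_rank_differentials.R
Rscript analysis/04_logratio_stats.R
Rscript analysis/05_permutation_null.R
Rscript analysis/06_stability.R
Rscript analysis/07_cooccurrence.R
```

Output of the seeded run (every script is deterministic, so these lines
regenerate verbatim):

```
differentials: 153 features; Spearman vs planted truth: 0.874
Q2 vs intercept-only baseline (10 held-out samples): 0.0720
log ratio (top 20 / bottom 20): t = 21.4925, df = 444.26, p = 9.04e-71, Cohen's D = 2.0236
CLA-like metabolite, consumer vs nonconsumer rank-sum: U = 39808, p = 9.5e-24
Permutation test: observed |stat| = 21.4925, rank 16 of 1000 permutations, p = 0.0159
microbial log ratio: 338 pairs, Spearman rho = 0.787 (p = 2.15e-72), slope = 0.76
  consumer: rho = 0.578 (n = 167)   nonconsumer: rho = 0.487 (n = 171)
metabolite log ratio: 340 pairs, Spearman rho = 0.629 (p = 8.6e-39)
of the top 50 CLA-like cooccurring microbes, 45 have a positive consumer differential
axis 1 vs consumption differentials: Pearson r = 0.357 (p = 5.98e-06, n = 153)
```

Reading it: the fitted differentials rank the planted group effects
nearly correctly (Spearman 0.874); the selected top-20/bottom-20 log
ratio separates the groups strongly and ranks 16th against 1,000 random
feature selections (p = 0.0159); log ratios are stable week to week
within subjects (per-group rho ≈ 0.5–0.6, metabolites more volatile than
microbes); and the planted CLA-like metabolite cooccurs predominantly
with consumer-associated microbes.

Use `simulate --preset`-style settings through `preset_16s()` /
`preset_metagenome()` (3,100- and 153-feature pools) and
`simulation_config()` for everything else. The methods vignette
(`vignettes/fermentomics-methods.Rmd`) documents the model, the
generator's assumptions, and every numerical decision.

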