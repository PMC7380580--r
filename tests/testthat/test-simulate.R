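test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_subjects_per_group = 5, n_timepoints = 3,
                           n_microbes = 30, n_metabolites = 10, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$beta_true, b$truth$beta_true)
  ma <- simulate_metabolites(a)
  mb <- simulate_metabolites(b)
  expect_identical(ma$counts, mb$counts)
  expect_identical(ma$cooccurrence_true, mb$cooccurrence_true)
})

test_that("counts sum to the drawn library size and metadata is aligned", {
  cfg <- simulation_config(n_subjects_per_group = 8, n_timepoints = 2,
                           n_microbes = 40, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_identical(rownames(sim$counts), sim$metadata$SampleID)
  expect_true(all(sim$metadata$read_count > 0))
  expect_identical(unname(rowSums(sim$counts)),
                   as.numeric(sim$metadata$read_count))
  expect_equal(nrow(sim$counts), 2 * 8 * 2)  # one sample per subject-time
  # planted differential is centered; groups cover exactly two labels
  expect_lt(abs(mean(sim$truth$beta_true)), 1e-12)
  expect_setequal(unique(sim$truth$group_assignment), c(0L, 1L))
})

test_that("degenerate stability settings freeze each subject's composition", {
  cfg <- simulation_config(n_subjects_per_group = 3, n_timepoints = 3,
                           n_microbes = 25, subject_stability = 1,
                           timepoint_sd = 0, transient_latent_sd = 0,
                           library_size_log_mean = log(2e5),
                           library_size_log_sd = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  rel <- sim$counts / rowSums(sim$counts)
  for (s in unique(sim$metadata$subject)) {
    rows <- rel[sim$metadata$subject == s, , drop = FALSE]
    # expected compositions identical; deviations are multinomial noise only
    expect_lt(max(abs(sweep(rows, 2, colMeans(rows)))), 0.005)
  }
})

test_that("zero variance parameters give one composition per group", {
  cfg <- simulation_config(n_subjects_per_group = 3, n_timepoints = 2,
                           n_microbes = 20, subject_sd = 0, timepoint_sd = 0,
                           transient_latent_sd = 0, effect_scale = 1,
                           library_size_log_mean = log(3e5),
                           library_size_log_sd = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  rel <- sim$counts / rowSums(sim$counts)
  for (g in 0:1) {
    rows <- rel[sim$metadata$group == g, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, colMeans(rows)))), 0.005)
  }
})

test_that("with no planted effect per-feature group tests reject at alpha", {
  # latent-free cohorts so features are independent; pooled over seeds the
  # rejection fraction concentrates near the nominal 5%
  fr <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_subjects_per_group = 30, n_timepoints = 1,
                             n_microbes = 80, effect_scale = 0,
                             latent_fraction = 0, seed = 40 + s)
    sim <- simulate_cohort(cfg)
    rel <- sim$counts / rowSums(sim$counts)
    g <- sim$metadata$group
    pv <- apply(rel, 2, function(x)
      suppressWarnings(stats::wilcox.test(x[g == 1], x[g == 0])$p.value))
    mean(pv < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.10)
})

test_that("planted differentials drive CLR fold changes (direct oracle)", {
  cfg <- simulation_config(n_subjects_per_group = 100, n_timepoints = 1,
                           n_microbes = 150, effect_scale = 1, seed = 7)
  sim <- simulate_cohort(cfg)
  lmx <- log(sim$counts + 0.5)
  clr <- lmx - rowMeans(lmx)
  g <- sim$metadata$group
  lfc <- colMeans(clr[g == 1, , drop = FALSE]) -
    colMeans(clr[g == 0, , drop = FALSE])
  expect_gt(cor(lfc, sim$truth$beta_true, method = "spearman"), 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_microbes = 1), "at least 2")
  expect_error(simulation_config(n_timepoints = 0), "integers >= 1")
  expect_error(simulation_config(effect_scale = -1), ">= 0")
  expect_error(simulation_config(subject_stability = 1.2), "\\[0, 1\\]")
})

test_that("metabolite table pairs with the cohort and honors the null", {
  cfg <- simulation_config(n_subjects_per_group = 25, n_timepoints = 1,
                           n_microbes = 30, n_metabolites = 12,
                           effect_scale = 0, planted_metabolite_effect = 0,
                           seed = 21)
  sim <- simulate_cohort(cfg)
  met <- simulate_metabolites(sim)
  expect_identical(rownames(met$counts), rownames(sim$counts))
  expect_true(all(met$counts >= 0))
  expect_identical(met$enriched_metabolite_id, "CLA_like")
  # no planted effect: designated metabolite shows no group difference
  g <- sim$metadata$group
  x <- met$counts[, "CLA_like"]
  expect_gt(rank_sum(x[g == 1], x[g == 0])$p, 0.05)
  # mismatched truth is rejected
  other <- simulate_cohort(simulation_config(n_subjects_per_group = 25,
                                             n_microbes = 31, seed = 3))
  expect_error(simulate_metabolites(sim$counts, other$truth),
               "do not match")
})

test_that("a planted enrichment is detected with high power (MC oracle)", {
  hits <- vapply(1:100, function(r) {
    cfg <- simulation_config(n_subjects_per_group = 50, n_timepoints = 1,
                             n_microbes = 40, n_metabolites = 10,
                             effect_scale = 0, planted_metabolite_effect = 2,
                             seed = 400 + r)
    sim <- simulate_cohort(cfg)
    met <- simulate_metabolites(sim)
    g <- sim$metadata$group
    x <- met$counts[, "CLA_like"]
    rank_sum(x[g == 1], x[g == 0])$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("a single latent dimension plants a rank-1 affinity", {
  cfg <- simulation_config(n_subjects_per_group = 10, n_timepoints = 1,
                           n_microbes = 20, n_metabolites = 8,
                           n_latent = 1, seed = 6)
  sim <- simulate_cohort(cfg)
  met <- simulate_metabolites(sim)
  sv <- svd(met$cooccurrence_true)$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("presets expose the two feature-pool sizes", {
  expect_equal(preset_16s(seed = 1)$n_microbes, 3100L)
  expect_equal(preset_metagenome(seed = 1)$n_microbes, 153L)
})
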