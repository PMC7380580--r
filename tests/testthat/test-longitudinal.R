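test_that("consecutive pairing follows subjects through time", {
  meta <- data.frame(
    SampleID = c("a.1", "a.2", "a.3", "b.1", "b.2", "c.1"),
    subject = c("a", "a", "a", "b", "b", "c"),
    timepoint = c(1, 2, 3, 1, 2, 1))
  vals <- stats::setNames(c(10, 11, 9, 5, 6, 2), meta$SampleID)
  pairs <- consecutive_pairs(vals, meta)
  # subject a gives (10,11) and (11,9); b gives (5,6); c contributes nothing
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$x[pairs$subject == "a"], c(10, 11))
  expect_equal(pairs$y[pairs$subject == "a"], c(11, 9))
  expect_false(any(pairs$gap_bridged))
  expect_false("c" %in% pairs$subject)
})

test_that("gaps from excluded samples are bridged and flagged", {
  meta <- data.frame(
    SampleID = c("a.1", "a.2", "a.3", "a.4"),
    subject = "a", timepoint = 1:4)
  vals <- stats::setNames(c(1, 2, 4), c("a.1", "a.3", "a.4"))  # a.2 unusable
  pairs <- consecutive_pairs(vals, meta)
  expect_equal(pairs$time_from, c(1, 3))
  expect_equal(pairs$time_to, c(3, 4))
  expect_identical(pairs$gap_bridged, c(TRUE, FALSE))
  # a lone time point per subject is an error
  solo <- stats::setNames(1, "a.1")
  expect_error(consecutive_pairs(solo, meta), "two usable time points")
})

test_that("pair count equals usable time points minus one, per subject", {
  cfg <- simulation_config(n_subjects_per_group = 10, n_timepoints = 4,
                           n_microbes = 30, seed = 19)
  sim <- simulate_cohort(cfg)
  pair <- feature_set_pair(colnames(sim$counts)[1:5],
                           colnames(sim$counts)[6:10])
  ser <- compute_log_ratio(sim$counts, pair, groups = group_labels(sim))
  pairs <- consecutive_pairs(ser, sim$metadata)
  usable <- table(sub("\\.T\\d+$", "", names(ser$values)))
  expect_equal(nrow(pairs), sum(pmax(0, usable - 1)))
  # the study design: 4 weekly samples give 3 pairs per complete subject
  complete <- names(usable)[usable == 4]
  expect_true(all(table(pairs$subject)[complete] == 3))
})

test_that("perfect persistence gives rho 1, slope 1, intercept 0", {
  pairs <- data.frame(x = c(3, 1, 4, 1.5, 9, 2.6), y = c(3, 1, 4, 1.5, 9, 2.6))
  st <- stability_correlation(pairs)
  expect_equal(st$spearman_rho, 1)
  expect_equal(st$ols_slope, 1, tolerance = 1e-12)
  expect_equal(st$ols_intercept, 0, tolerance = 1e-12)
  expect_error(stability_correlation(pairs[1:2, ]), "at least 3")
  expect_error(stability_correlation(data.frame(x = c(1, 1, 1), y = 1:3)),
               "constant")
})

test_that("rho is invariant to strictly monotone transforms", {
  set.seed(30)
  pairs <- data.frame(x = rnorm(20), y = rnorm(20))
  st1 <- stability_correlation(pairs)
  st2 <- stability_correlation(data.frame(x = exp(pairs$x),
                                          y = pairs$y^3 + 5 * pairs$y))
  expect_equal(st1$spearman_rho, st2$spearman_rho)
})

test_that("zero stability yields correlations inside the permutation null", {
  cfg <- simulation_config(n_subjects_per_group = 25, n_timepoints = 3,
                           n_microbes = 40, effect_scale = 0,
                           subject_stability = 0, latent_fraction = 0,
                           seed = 31)
  sim <- simulate_cohort(cfg)
  pair <- feature_set_pair(colnames(sim$counts)[1:8],
                           colnames(sim$counts)[9:16])
  ser <- compute_log_ratio(sim$counts, pair)
  pairs <- consecutive_pairs(ser, sim$metadata)
  st <- stability_correlation(pairs)
  # permutation oracle on the generated pairs
  set.seed(32)
  null_rho <- replicate(500, abs(cor(pairs$x, sample(pairs$y),
                                     method = "spearman")))
  expect_lt(abs(st$spearman_rho), quantile(null_rho, 0.95))
})

test_that("estimated stability increases with the planted stability", {
  rho_at <- function(stab, seed) {
    cfg <- simulation_config(n_subjects_per_group = 15, n_timepoints = 4,
                             n_microbes = 40, effect_scale = 0,
                             subject_stability = stab, latent_fraction = 0,
                             transient_latent_sd = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    pair <- feature_set_pair(colnames(sim$counts)[1:8],
                             colnames(sim$counts)[9:16])
    ser <- compute_log_ratio(sim$counts, pair)
    stability_correlation(consecutive_pairs(ser, sim$metadata))$spearman_rho
  }
  grid <- c(0.1, 0.5, 0.9)
  means <- vapply(grid, function(s) {
    mean(vapply(1:12, function(r) rho_at(s, 500 + 13 * r), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("default study conditions land in the plausible stability band", {
  rhos <- vapply(1:4, function(r) {
    cfg <- simulation_config(n_subjects_per_group = 30, n_timepoints = 4,
                             n_microbes = 80, effect_scale = 1,
                             seed = 600 + r)
    sim <- simulate_cohort(cfg)
    spec <- fast_spec(epochs = 500, seed = 1)
    fit <- fit_differentials(sim$counts, sim$metadata, spec)
    pair <- select_extreme_features(fit, "group", k = 20)
    ser <- compute_log_ratio(sim$counts, pair, groups = group_labels(sim))
    stability_correlation(consecutive_pairs(ser, sim$metadata))$spearman_rho
  }, numeric(1))
  expect_true(all(rhos > 0.3 & rhos < 0.9))
})

test_that("per-group stratification returns one row per group", {
  cfg <- simulation_config(n_subjects_per_group = 10, n_timepoints = 3,
                           n_microbes = 30, seed = 33)
  sim <- simulate_cohort(cfg)
  pair <- feature_set_pair(colnames(sim$counts)[1:6],
                           colnames(sim$counts)[7:12])
  ser <- compute_log_ratio(sim$counts, pair, groups = group_labels(sim))
  pairs <- consecutive_pairs(ser, sim$metadata)
  st <- stability_correlation(pairs, by = "group")
  expect_equal(nrow(st), 2)
  expect_setequal(st$group, c("0", "1"))
})
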